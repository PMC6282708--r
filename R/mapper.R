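#' Convert between CDS-relative (c.) and transcript (n.) coordinates
#'
#' Pure renumbering relative to the CDS bounds; lossless inverse pair.
#' Positions 5' of the CDS become negative c. bases (there is no c.0);
#' positions 3' of the CDS end carry the `*` (cds_end) anchor. Intron offsets
#' pass through unchanged.
#'
#' @param v an `hgvs_variant` of type `c` (for `c_to_n`) or `n` (for
#'   `n_to_c`).
#' @param rec a transcript record (see [fixture_bundle()]); must have a CDS.
#' @return the converted `hgvs_variant`.
#' @export
c_to_n <- function(v, rec) {
  stopifnot(v$type == "c")
  if (is.na(rec$cds_start)) {
    stop_coord(sprintf("%s has no CDS; c. coordinates are undefined", rec$tx_ac))
  }
  conv <- function(p) {
    b <- if (p$anchor == "cds_end") {
      rec$cds_end + p$base
    } else if (p$base > 0L) {
      rec$cds_start + p$base
    } else {
      rec$cds_start + p$base + 1L
    }
    if (b < 1L) stop_bounds(sprintf("position %s lies before the transcript start",
                                    fmt_bo_pos(p, "c")))
    bo_pos(b, p$offset)
  }
  iv <- v$posedit$interval
  variant(v$ac, "n", posedit(bo_interval(conv(iv$start), conv(iv$end)),
                             v$posedit$edit, v$posedit$uncertain))
}

#' @rdname c_to_n
#' @export
n_to_c <- function(v, rec) {
  stopifnot(v$type == "n")
  if (is.na(rec$cds_start)) {
    stop_coord(sprintf("%s has no CDS; c. coordinates are undefined", rec$tx_ac))
  }
  conv <- function(p) {
    b <- p$base
    if (b <= rec$cds_start) {
      bo_pos(b - rec$cds_start - 1L, p$offset)
    } else if (b <= rec$cds_end) {
      bo_pos(b - rec$cds_start, p$offset)
    } else {
      bo_pos(b - rec$cds_end, p$offset, anchor = "cds_end")
    }
  }
  iv <- v$posedit$interval
  variant(v$ac, "c", posedit(bo_interval(conv(iv$start), conv(iv$end)),
                             v$posedit$edit, v$posedit$uncertain))
}

# reverse-complement an edit's alleles for strand flips
orient_edit <- function(e, strand) {
  if (strand > 0L) return(e)
  if (!is.na(e$ref)) e$ref <- revcomp(e$ref)
  if (!is.na(e$alt)) e$alt <- revcomp(e$alt)
  if (!is.na(e$unit)) e$unit <- revcomp(e$unit)
  e
}

#' Project a transcript (n.) variant to the genome
#'
#' Exonic intervals are projected through the per-exon alignment columns.
#' An interval that touches an alignment gap (a transcript-insertion or
#' genome-insertion segment) is widened to the smallest interval whose
#' endpoints sit in aligned (match/mismatch) columns on both sequences, and
#' the allele is recomputed from the full sequences so that the projected
#' variant denotes the same altered molecule; renormalization (by the
#' caller) then restores the preferred edit type. Intronic positions are
#' computed from exon genomic edges. Minus-strand alleles are
#' reverse-complemented. Positions beyond the transcript bounds are refused.
#'
#' @param v an `hgvs_variant` of type `n`.
#' @param rec transcript record.
#' @param provider data provider (for allele recomputation at gaps).
#' @param placement `"primary"` or `"alt"` (pseudoautosomal second
#'   placement).
#' @return an `hgvs_variant` of type `g` on the placement's genomic
#'   accession.
#' @export
n_to_g <- function(v, rec, provider, placement = "primary") {
  stopifnot(v$type == "n")
  iv <- v$posedit$interval
  e <- v$posedit$edit
  txlen <- tx_length(rec)
  for (p in list(iv$start, iv$end)) {
    if (p$base < 1L || p$base > txlen) {
      stop_bounds(sprintf(
        "position %d is outside the bounds of the reference sequence %s (length %d)",
        p$base, rec$tx_ac, txlen))
    }
  }
  g_ac <- placement_g_ac(rec, placement)
  if (iv$start$offset != 0L || iv$end$offset != 0L) {
    return(project_positional_to_g(v, rec, g_ac, placement))
  }
  ib <- nt_interval_ib(v)
  pr <- project_tx_interval(rec, ib[1L], ib[2L], placement)
  if (is.null(pr)) { # interval straddles a splice junction: endpoint-wise
    return(project_positional_to_g(v, rec, g_ac, placement, drop_ref = TRUE))
  }
  if (!pr$gap) {
    e2 <- orient_edit(e, rec$strand)
    iv2 <- if (e$kind == "ins") {
      bo_interval(bo_pos(pr$gs), bo_pos(pr$gs + 1L))
    } else {
      bo_interval(bo_pos(pr$gs + 1L), bo_pos(pr$ge))
    }
    return(variant(g_ac, "g", posedit(iv2, e2, v$posedit$uncertain)))
  }
  # Gap interaction: widen to solid (match/mismatch-anchored) boundaries and
  # recompute the allele. The genomic alternate over the widened region is
  # the transcript's edited content of that region, verbatim (oriented):
  # transcript-insertion bases materialize into the genome, genome-insertion
  # bases are consumed. This verbatim-region semantics is its own inverse,
  # which keeps genome->transcript projection consistent.
  txseq <- get_seq(provider, rec$tx_ac)
  al <- materialize_alleles(txseq, ib[1L], ib[2L], e)
  alt2 <- paste0(substr_ib(txseq, pr$ts, ib[1L]), al$alt, substr_ib(txseq, ib[2L], pr$te))
  gref <- get_seq(provider, g_ac, pr$gs, pr$ge)
  galt <- if (rec$strand < 0L) revcomp(alt2) else alt2
  build_recomputed(g_ac, "g", pr$gs, pr$ge, gref, galt)
}

build_recomputed <- function(ac, type, s, t, ref, alt) {
  if (identical(ref, alt)) {
    iv <- if (t > s) bo_interval(bo_pos(s + 1L), bo_pos(t)) else bo_interval(bo_pos(s), bo_pos(s + 1L))
    return(variant(ac, type, posedit(iv, edit("identity"))))
  }
  if (!nzchar(ref)) {
    return(variant(ac, type, posedit(bo_interval(bo_pos(s), bo_pos(s + 1L)),
                                     edit("ins", alt = alt))))
  }
  iv <- bo_interval(bo_pos(s + 1L), bo_pos(t))
  e <- if (!nzchar(alt)) edit("del", ref = ref) else edit("delins", ref = ref, alt = alt)
  variant(ac, type, posedit(iv, e))
}

# endpoint-wise projection (intronic endpoints, or junction-spanning
# intervals); no allele recomputation
project_positional_to_g <- function(v, rec, g_ac, placement, drop_ref = FALSE) {
  e <- v$posedit$edit
  iv <- v$posedit$interval
  map1 <- function(p) { # 1-based genomic base of a (base, offset) position
    g0 <- g_index_of_tx_base(rec, p$base - 1L, placement)
    if (is.na(g0)) {
      stop_data(sprintf("transcript base %d of %s has no aligned genomic base",
                        p$base, rec$tx_ac))
    }
    g0 + rec$strand * p$offset + 1L
  }
  gs <- map1(iv$start)
  ge <- map1(iv$end)
  if (rec$strand < 0L) { gs2 <- min(gs, ge); ge <- max(gs, ge); gs <- gs2 }
  e2 <- orient_edit(e, rec$strand)
  if (drop_ref) {
    e2$ref <- NA_character_
  }
  variant(g_ac, "g", posedit(bo_interval(bo_pos(gs), bo_pos(ge)), e2, v$posedit$uncertain))
}

#' Project a genomic variant onto a transcript
#'
#' Exonic positions map to offset-0 transcript bases through the alignment
#' columns (gap-touching intervals are widened and their allele recomputed
#' from the transcript side, mirroring [n_to_g()]). Intronic positions take
#' the closest exon edge: the offset is computed against both the upstream
#' exon end and the downstream exon start and the smaller wins, ties going to
#' the upstream exon (a `+` offset).
#'
#' @param v an `hgvs_variant` of type `g` (or `m`).
#' @param rec transcript record.
#' @param provider data provider.
#' @return an `hgvs_variant` of type `n`.
#' @export
g_to_n <- function(v, rec, provider) {
  stopifnot(v$type %in% c("g", "m"))
  placement <- if (identical(v$ac, rec$g_ac)) "primary"
    else if (!is.null(rec$alt) && identical(v$ac, rec$alt$g_ac)) "alt"
    else stop_data(sprintf("%s is not placed on %s", rec$tx_ac, v$ac))
  ex <- placement_exons(rec, placement)
  span <- c(min(ex$g_start), max(ex$g_end))
  ib <- nt_interval_ib(v)
  if (ib[2L] <= span[1L] || ib[1L] >= span[2L]) {
    stop_bounds(sprintf("variant does not overlap transcript %s", rec$tx_ac))
  }
  e <- v$posedit$edit
  pr <- project_g_interval(rec, ib[1L], ib[2L], placement)
  if (!is.null(pr) && !pr$gap) {
    e2 <- orient_edit(e, rec$strand)
    iv2 <- if (e$kind == "ins") {
      bo_interval(bo_pos(pr$ts), bo_pos(pr$ts + 1L))
    } else {
      bo_interval(bo_pos(pr$ts + 1L), bo_pos(pr$te))
    }
    return(variant(rec$tx_ac, "n", posedit(iv2, e2, v$posedit$uncertain)))
  }
  if (!is.null(pr)) {
    # Gap interaction: mirror of n_to_g's verbatim-region semantics -- the
    # transcript alternate over the widened region is the genome's edited
    # content of that region, verbatim (oriented).
    gseq_ac <- placement_g_ac(rec, placement)
    al <- materialize_alleles(get_seq(provider, gseq_ac), ib[1L], ib[2L], e)
    galt2 <- paste0(get_seq(provider, gseq_ac, pr$gs, ib[1L]), al$alt,
                    get_seq(provider, gseq_ac, ib[2L], pr$ge))
    txref <- substr_ib(get_seq(provider, rec$tx_ac), pr$ts, pr$te)
    txalt <- if (rec$strand < 0L) revcomp(galt2) else galt2
    return(build_recomputed(rec$tx_ac, "n", pr$ts, pr$te, txref, txalt))
  }
  # endpoint-wise: at least one endpoint intronic (or spanning exons)
  p1 <- map_g_base_to_n(rec, v$posedit$interval$start$base - 1L, placement)
  p2 <- map_g_base_to_n(rec, v$posedit$interval$end$base - 1L, placement)
  if (rec$strand < 0L) { tmp <- p1; p1 <- p2; p2 <- tmp }
  e2 <- orient_edit(e, rec$strand)
  variant(rec$tx_ac, "n", posedit(bo_interval(p1, p2), e2, v$posedit$uncertain))
}

# n. position (base, offset) of the genomic base with interbase index g0
map_g_base_to_n <- function(rec, g0, placement = "primary") {
  ex <- placement_exons(rec, placement)
  i <- exon_containing_g(rec, g0, placement)
  if (!is.na(i)) {
    cols <- exon_columns_pl(rec, i, placement)
    k <- which(!is.na(cols$gpos) & cols$gpos == g0)
    if (length(k) == 1L && !is.na(cols$txpos[k])) {
      return(bo_pos(cols$txpos[k] + 1L))
    }
    # genome-insertion column: report the nearest upstream transcript base
    k1 <- k
    while (k1 >= 1L && is.na(cols$txpos[k1])) k1 <- k1 - 1L
    if (k1 >= 1L) return(bo_pos(cols$txpos[k1] + 1L))
    return(bo_pos(rec$exons$tx_start[i] + 1L))
  }
  # intronic: closest exon edge, ties to the upstream exon (+ offset)
  n_ex <- nrow(ex)
  for (j in seq_len(n_ex - 1L)) {
    rng <- intron_g_range2(ex, rec$strand, j)
    if (g0 >= rng[1L] && g0 < rng[2L]) {
      if (rec$strand > 0L) {
        d_up <- g0 - rng[1L] + 1L
        d_dn <- rng[2L] - g0
      } else {
        d_up <- rng[2L] - g0
        d_dn <- g0 - rng[1L] + 1L
      }
      if (d_up <= d_dn) {
        return(bo_pos(ex$tx_end[j], d_up)) # last base of upstream exon, +offset
      }
      return(bo_pos(ex$tx_start[j + 1L] + 1L, -d_dn))
    }
  }
  stop_bounds(sprintf("genomic position %d is outside transcript %s", g0 + 1L, rec$tx_ac))
}

intron_g_range2 <- function(ex, strand, j) {
  if (strand > 0L) c(ex$g_end[j], ex$g_start[j + 1L])
  else c(ex$g_end[j + 1L], ex$g_start[j])
}

#' Transcripts spanning a genomic variant
#'
#' @param v an `hgvs_variant` of type `g`/`m`.
#' @param provider data provider.
#' @return character vector of transcript accessions whose genomic span
#'   (either placement) contains the variant interval, sorted
#'   lexicographically; may be empty.
#' @export
relevant_transcripts <- function(v, provider) {
  stopifnot(inherits(v, "hgvs_variant"), v$type %in% c("g", "m"))
  ib <- nt_interval_ib(v)
  hits <- character()
  for (tx_ac in names(provider$transcripts)) {
    rec <- provider$transcripts[[tx_ac]]
    for (pl in c("primary", if (!is.null(rec$alt)) "alt")) {
      if (!identical(v$ac, placement_g_ac(rec, pl))) next
      ex <- placement_exons(rec, pl)
      if (ib[1L] < max(ex$g_end) && ib[2L] > min(ex$g_start)) {
        hits <- c(hits, tx_ac)
        break
      }
    }
  }
  sort(unique(hits))
}

#' Replace a variant's stated reference allele with the actual sequence
#'
#' After projection onto a new sequence, the stated reference may disagree
#' with that sequence (alignment substitution discrepancies, e.g. a known
#' SNP between transcript and genome). This replaces the reference allele of
#' interval-anchored edits with the target sequence's actual bases; the
#' alternate allele is untouched. Intronic transcript positions are left
#' alone (no transcript sequence exists for them).
#'
#' @param v an `hgvs_variant` of type `g`, `m` or `n`.
#' @param provider data provider.
#' @return the variant with its reference allele refreshed.
#' @export
replace_reference <- function(v, provider) {
  stopifnot(v$type %in% c("g", "m", "n"))
  e <- v$posedit$edit
  if (e$kind %in% c("ins", "con", "repeat")) return(v)
  iv <- v$posedit$interval
  if (iv$start$offset != 0L || iv$end$offset != 0L) return(v)
  if (!has_seq(provider, v$ac)) return(v)
  ib <- nt_interval_ib(v)
  ref_here <- get_seq(provider, v$ac, ib[1L], ib[2L])
  if (e$kind == "sub" && identical(ref_here, e$alt)) {
    # reference already carries the alternate base: no change remains
    v$posedit$edit <- edit("identity")
    return(v)
  }
  e$ref <- ref_here
  e$ref_len <- NA_integer_
  v$posedit$edit <- e
  v
}

# ---- assembly-level orchestration -----------------------------------------

#' Project a transcript variant to the genome (validate, map, clean up)
#'
#' The full pipeline: validate (an ERROR-level report aborts the
#' projection), convert c. to n., project through the alignment
#' ([n_to_g()]), replace the reference allele with the genomic sequence, and
#' renormalize on the genome (a variant 3'-normalized on a minus-strand
#' transcript must be re-shifted on the plus strand). For pseudoautosomal
#' transcripts with two genomic placements, `par` selects the X-like
#' (default) or Y-like placement.
#'
#' @param v an `hgvs_variant` of type `c` or `n`.
#' @param provider data provider.
#' @param par `"X"` or `"Y"`.
#' @param config normalization settings for the post-projection cleanup.
#' @return an `hgvs_variant` of type `g`.
#' @export
project_tx_to_genome <- function(v, provider, par = c("X", "Y"),
                                 config = normalizer_config()) {
  par <- match.arg(par)
  stopifnot(v$type %in% c("c", "n"))
  rep <- validate_variant(v, provider)
  if (rep$overall == "ERROR") {
    msgs <- rep$outcomes$message[rep$outcomes$level == "ERROR"]
    if (any(rep$outcomes$criterion[rep$outcomes$level == "ERROR"] == "e1")) {
      stop_bounds(msgs[1L])
    }
    stop_validation(msgs[1L], report = rep)
  }
  rec <- get_transcript(provider, v$ac)
  placement <- if (par == "Y" && !is.null(rec$alt)) "alt" else "primary"
  vn <- if (v$type == "c") c_to_n(v, rec) else v
  vg <- n_to_g(vn, rec, provider, placement)
  vg <- replace_reference(vg, provider)
  normalize_variant(vg, provider, config)
}

#' Project a genomic variant onto a transcript (validate, map, clean up)
#'
#' Pipeline: validate, project through the alignment ([g_to_n()]), replace
#' the reference with the transcript sequence (the transcript base wins at
#' alignment mismatches), renormalize in transcript context, and renumber to
#' c. when the transcript has a CDS.
#'
#' @param v an `hgvs_variant` of type `g`/`m`.
#' @param tx_ac target transcript accession.
#' @param provider data provider.
#' @param config normalization settings.
#' @return an `hgvs_variant` of type `c` (coding transcript) or `n`.
#' @export
project_genome_to_tx <- function(v, tx_ac, provider, config = normalizer_config()) {
  stopifnot(v$type %in% c("g", "m"))
  rep <- validate_variant(v, provider)
  if (rep$overall == "ERROR") {
    msgs <- rep$outcomes$message[rep$outcomes$level == "ERROR"]
    stop_validation(msgs[1L], report = rep)
  }
  rec <- get_transcript(provider, tx_ac)
  vn <- g_to_n(v, rec, provider)
  vn <- replace_reference(vn, provider)
  vn <- normalize_variant(vn, provider, config)
  notice <- attr(vn, "notice")
  out <- if (!is.na(rec$cds_start)) n_to_c(vn, rec) else vn
  attr(out, "notice") <- notice
  out
}
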