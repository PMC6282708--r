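#' Normalizer configuration
#'
#' @param shift_direction `"3p"` (the nomenclature's canonical direction,
#'   default) or `"5p"` (VCF-style left alignment).
#' @param cross_boundaries allow a transcript (`c.`/`n.`) variant to shift
#'   across an exon junction (default off: shifting stops at the junction).
#' @param window_size initial extent, in bases, of the dynamic window used to
#'   fetch reference sequence while shifting; the window doubles whenever the
#'   shifted variant reaches its edge. Must be >= 1.
#' @return a `normalizer_config`.
#' @export
normalizer_config <- function(shift_direction = c("3p", "5p"),
                              cross_boundaries = FALSE,
                              window_size = 20L) {
  shift_direction <- match.arg(shift_direction)
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) stop_coord("window_size must be >= 1")
  structure(list(shift_direction = shift_direction,
                 cross_boundaries = isTRUE(cross_boundaries),
                 window_size = window_size),
            class = "normalizer_config")
}

#' Trim shared allele bases
#'
#' Removes the common prefix, then the common suffix, of the reference and
#' alternate alleles, adjusting the interval. The classic equivalence class on
#' `GCTTTA`: `3_5delTTTinsTT` and `3_4delTTinsT` both trim to a single-base
#' deletion (which 3' shifting then places at 5).
#'
#' @param ref,alt allele strings (explicit; may be empty).
#' @param interval 1-based inclusive interval `c(start, end)` of `ref`; for a
#'   pure insertion pass the two flanking bases.
#' @return list with `ref`, `alt`, `interval`. When the trimmed `ref` is
#'   empty the interval holds the two bases flanking the insertion point;
#'   when both alleles empty out (an identity), the original interval is
#'   returned unchanged.
#' @examples
#' trim_alleles("TTT", "TT", c(3, 5))  # ref "T", alt "", interval c(5, 5)
#' trim_alleles("TT", "T", c(3, 4))    # ref "T", alt "", interval c(4, 4)
#' trim_alleles("A", "A", c(2, 2))     # identity: both empty
#' @export
trim_alleles <- function(ref, alt, interval) {
  ts <- interval[1L] - 1L # interbase
  te <- interval[2L]
  if (!nzchar(ref)) { # already a pure insertion between the stated flanks
    ts <- te <- interval[1L]
  }
  p <- common_prefix_len(ref, alt)
  ref2 <- substr(ref, p + 1L, nchar(ref))
  alt2 <- substr(alt, p + 1L, nchar(alt))
  s <- common_suffix_len(ref2, alt2)
  ref2 <- substr(ref2, 1L, nchar(ref2) - s)
  alt2 <- substr(alt2, 1L, nchar(alt2) - s)
  ts <- ts + p
  te <- te - s
  iv <- if (!nzchar(ref2) && !nzchar(alt2)) {
    interval
  } else if (!nzchar(ref2)) {
    c(ts, ts + 1L) # flanks of the insertion point
  } else {
    c(ts + 1L, te)
  }
  list(ref = ref2, alt = alt2, interval = as.integer(iv))
}

#' Shift an indel to its 3'-most equivalent placement
#'
#' Rotates a trimmed insertion or deletion along the reference while the
#' allele head matches the next reference base (equivalent to comparing
#' reference and altered sequence in a window, but O(shift)). Substitutions
#' and delins variants are not shiftable. Shifting stops at the end of `seq`
#' (or at `wlo`/`whi`, e.g. an exon boundary).
#'
#' @param ref,alt trimmed alleles (at most one non-empty).
#' @param interval 1-based inclusive interval (flanks for insertions), as
#'   produced by [trim_alleles()].
#' @param seq the reference sequence (the shift window provider).
#' @param wlo,whi interbase window bounds within `seq` the variant may not
#'   leave (defaults: the whole sequence).
#' @param direction `"3p"` or `"5p"`.
#' @param window_size initial dynamic-window extent.
#' @return list with `ref`, `alt`, `interval` in the same convention.
#' @examples
#' shift_3prime("T", "", c(3, 3), "GCTTTA")  # deletion placed at 5
#' @export
shift_3prime <- function(ref, alt, interval, seq, wlo = 0L, whi = nchar(seq),
                         direction = "3p", window_size = 20L) {
  fetch <- function(a, b) substr_ib(seq, a, b)
  if (nzchar(ref)) {
    ts <- interval[1L] - 1L
    te <- interval[2L]
  } else {
    ts <- te <- interval[1L]
  }
  out <- shift_alleles_ib(fetch, ref, alt, ts, te, wlo, whi, direction, window_size)
  iv <- if (nzchar(out$ref)) c(out$ts + 1L, out$te) else c(out$ts, out$ts + 1L)
  list(ref = out$ref, alt = out$alt, interval = as.integer(iv))
}

# interbase core; fetch(a, b) returns seq[a, b) (the provider read)
shift_alleles_ib <- function(fetch, ref, alt, ts, te, wlo, whi, direction, window_size) {
  shiftable <- xor(nzchar(ref), nzchar(alt))
  if (!shiftable) return(list(ref = ref, alt = alt, ts = ts, te = te))
  allele <- if (nzchar(ref)) ref else alt
  W <- max(as.integer(window_size), 1L)
  if (direction == "3p") {
    buf <- ""
    buf_at <- te # interbase start of buffer
    repeat {
      if (te >= whi) break
      need <- te - buf_at + 1L
      while (nchar(buf) < need) { # dynamic window: extend and re-fetch
        hi <- min(buf_at + W, whi)
        if (hi <= buf_at + nchar(buf)) break
        buf <- paste0(buf, fetch(buf_at + nchar(buf), hi))
        W <- W * 2L
      }
      if (nchar(buf) < need) break
      nxt <- substr(buf, need, need)
      if (nxt != substr(allele, 1L, 1L)) break
      allele <- paste0(substr(allele, 2L, nchar(allele)), nxt)
      ts <- ts + 1L
      te <- te + 1L
    }
  } else {
    repeat {
      if (ts <= wlo) break
      prev <- fetch(ts - 1L, ts)
      if (prev != substr(allele, nchar(allele), nchar(allele))) break
      allele <- paste0(prev, substr(allele, 1L, nchar(allele) - 1L))
      ts <- ts - 1L
      te <- te - 1L
    }
  }
  if (nzchar(ref)) list(ref = allele, alt = "", ts = ts, te = te)
  else list(ref = "", alt = allele, ts = ts, te = te)
}

#' Re-express trimmed, shifted alleles as the highest-priority edit type
#'
#' Applies the nomenclature's type priority (substitution > deletion >
#' inversion > duplication > conversion > insertion > deletion-insertion):
#' the first kind that exactly represents the change wins. An insertion whose
#' sequence equals the immediately preceding reference bases becomes a
#' duplication; an exact reverse-complement replacement becomes an inversion.
#' Conversions are never emitted.
#'
#' @param ref,alt trimmed/shifted alleles.
#' @param interval as in [trim_alleles()].
#' @param seq reference sequence (consulted for the duplication check).
#' @param wlo interbase lower bound the duplicated unit may not precede.
#' @return list with `edit` (an [hgvs_edit()]) and 1-based `interval`.
#' @examples
#' rewrite_edit("", "A", c(4, 5), "GCTA")  # dup of A at 4
#' @export
rewrite_edit <- function(ref, alt, interval, seq, wlo = 0L) {
  fetch <- function(a, b) substr_ib(seq, a, b)
  if (nzchar(ref)) {
    ts <- interval[1L] - 1L
    te <- interval[2L]
  } else {
    ts <- te <- interval[1L]
  }
  out <- rewrite_edit_ib(fetch, ref, alt, ts, te, wlo)
  out
}

rewrite_edit_ib <- function(fetch, ref, alt, ts, te, wlo) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == 0L && la == 0L) {
    return(list(edit = edit("identity"), interval = c(ts + 1L, te)))
  }
  if (lr == 1L && la == 1L) {
    return(list(edit = edit("sub", ref = ref, alt = alt), interval = c(ts + 1L, te)))
  }
  if (la == 0L) {
    return(list(edit = edit("del", ref = ref), interval = c(ts + 1L, te)))
  }
  if (lr == 0L) {
    if (ts - la >= wlo && fetch(ts - la, ts) == alt) {
      return(list(edit = edit("dup", ref = alt), interval = c(ts - la + 1L, ts)))
    }
    return(list(edit = edit("ins", alt = alt), interval = c(ts, ts + 1L)))
  }
  if (lr > 1L && identical(alt, revcomp(ref))) {
    return(list(edit = edit("inv", ref = ref), interval = c(ts + 1L, te)))
  }
  list(edit = edit("delins", ref = ref, alt = alt), interval = c(ts + 1L, te))
}

# stated-vs-actual allele materialization; interbase interval
materialize_alleles <- function(seq, ts, te, e) {
  ref_here <- substr_ib(seq, ts, te)
  if (!is.na(e$ref) && nzchar(e$ref) && e$kind != "ins" && !identical(e$ref, ref_here)) {
    stop_ref_mismatch(sprintf(
      "stated reference '%s' disagrees with sequence '%s'", e$ref, ref_here))
  }
  switch(e$kind,
    sub = list(ref = ref_here, alt = e$alt),
    del = list(ref = ref_here, alt = ""),
    delins = list(ref = ref_here, alt = e$alt),
    ins = list(ref = "", alt = e$alt),
    dup = list(ref = ref_here, alt = paste0(ref_here, ref_here)),
    inv = list(ref = ref_here, alt = revcomp(ref_here)),
    identity = list(ref = ref_here, alt = ref_here),
    stop_unsupported(sprintf("cannot materialize alleles for a '%s' edit", e$kind))
  )
}

#' Normalize a variant to its canonical HGVS form
#'
#' Composition of allele trimming, 3' shifting (dynamic window, stopping at
#' exon junctions for transcript variants unless `cross_boundaries`) and
#' rewriting into the highest-priority edit type. Idempotent, and
#' allele-preserving: applying the normalized variant to the reference yields
#' the same sequence as the input variant.
#'
#' Intronic transcript variants are normalized in genomic context (through
#' the transcript's alignment, shifting in the transcript's 3' direction)
#' when the provider holds one; otherwise -- and for conversion/repeat edits,
#' which have no normal form here -- the variant is returned unchanged with a
#' `"notice"` attribute. Trimming that empties both alleles yields an
#' identity (`=`) variant over the original interval.
#'
#' @param v an `hgvs_variant` (`g`, `m`, `n` or `c`).
#' @param provider an [fixture_bundle()].
#' @param config a [normalizer_config()].
#' @return the normalized `hgvs_variant`.
#' @examples
#' p <- fixture_bundle(sequences = c(T1 = "GCTTTA"))
#' format_hgvs(normalize_variant(parse_hgvs("T1:g.3delT"), p))  # "T1:g.5del"
#' @export
normalize_variant <- function(v, provider, config = normalizer_config()) {
  stopifnot(inherits(v, "hgvs_variant"))
  if (v$type == "p") {
    return(with_notice(v, "protein variants are not normalized"))
  }
  e <- v$posedit$edit
  if (e$kind %in% c("con", "repeat")) {
    return(with_notice(v, sprintf("'%s' edits have no normal form; returned unchanged", e$kind)))
  }
  rep <- validate_intrinsic(v)
  if (rep$overall == "ERROR") {
    stop_validation("refusing to normalize an intrinsically invalid variant", report = rep)
  }
  if (!is.na(e$ref_len)) { # declared-length ref: resolve against the sequence
    e$ref_len <- NA_integer_
    v$posedit$edit <- e
  }

  if (v$type %in% c("g", "m")) {
    return(normalize_in_seq(v, provider, v$ac, config, wlo = 0L,
                            whi = seq_length(provider, v$ac)))
  }

  # transcript coordinates
  was_c <- v$type == "c"
  rec <- get_transcript(provider, v$ac)
  vn <- if (was_c) c_to_n(v, rec) else v
  iv <- vn$posedit$interval
  if (iv$start$offset != 0L || iv$end$offset != 0L) {
    out <- normalize_intronic(vn, rec, provider, config)
    if (was_c && is.null(attr(out, "notice"))) out <- n_to_c(out, rec)
    else if (was_c) { out2 <- n_to_c(out, rec); attr(out2, "notice") <- attr(out, "notice"); out <- out2 }
    return(out)
  }
  txlen <- tx_length(rec)
  if (config$cross_boundaries) {
    wlo <- 0L
    whi <- txlen
  } else {
    ib <- nt_interval_ib(vn)
    i1 <- exon_containing_tx(rec, ib[1L], ib[1L])
    i2 <- exon_containing_tx(rec, ib[2L], ib[2L])
    wlo <- rec$exons$tx_start[i1]
    whi <- rec$exons$tx_end[i2]
  }
  out <- normalize_in_seq(vn, provider, vn$ac, config, wlo = wlo, whi = whi)
  if (was_c) {
    notice <- attr(out, "notice")
    out <- n_to_c(out, rec)
    attr(out, "notice") <- notice
  }
  out
}

with_notice <- function(v, msg) {
  attr(v, "notice") <- msg
  v
}

# variant interval in interbase coordinates of its own sequence (g or n
# exonic); insertions give an empty interval at the insertion point
nt_interval_ib <- function(v) {
  iv <- v$posedit$interval
  if (v$posedit$edit$kind == "ins") {
    c(iv$start$base, iv$start$base)
  } else {
    c(iv$start$base - 1L, iv$end$base)
  }
}

normalize_in_seq <- function(v, provider, seq_ac, config, wlo, whi) {
  seq <- get_seq(provider, seq_ac)
  ib <- nt_interval_ib(v)
  ts <- ib[1L]
  te <- ib[2L]
  if (ts < wlo || te > whi) {
    # variant extends past the window (e.g. spans an exon junction)
    return(with_notice(v, "variant spans the shift-window boundary; returned unchanged"))
  }
  al <- materialize_alleles(seq, ts, te, v$posedit$edit)
  tr <- trim_alleles_ib(al$ref, al$alt, ts, te)
  if (!nzchar(tr$ref) && !nzchar(tr$alt)) {
    pe <- posedit(v$posedit$interval, edit("identity"))
    return(variant(v$ac, v$type, pe))
  }
  fetch <- function(a, b) substr_ib(seq, a, b)
  sh <- shift_alleles_ib(fetch, tr$ref, tr$alt, tr$ts, tr$te, wlo, whi,
                         config$shift_direction, config$window_size)
  rw <- rewrite_edit_ib(fetch, sh$ref, sh$alt, sh$ts, sh$te, wlo)
  iv <- bo_interval(bo_pos(rw$interval[1L]), bo_pos(rw$interval[2L]))
  variant(v$ac, v$type, posedit(iv, rw$edit))
}

trim_alleles_ib <- function(ref, alt, ts, te) {
  p <- common_prefix_len(ref, alt)
  ref2 <- substr(ref, p + 1L, nchar(ref))
  alt2 <- substr(alt, p + 1L, nchar(alt))
  s <- common_suffix_len(ref2, alt2)
  list(ref = substr(ref2, 1L, nchar(ref2) - s),
       alt = substr(alt2, 1L, nchar(alt2) - s),
       ts = ts + p, te = te - s)
}

# Intronic (offset != 0) transcript variants: normalize on the genome through
# the alignment, with the window clamped to the enclosing intron, shifting in
# the transcript's 3' direction; then map back.
normalize_intronic <- function(vn, rec, provider, config) {
  if (!has_seq(provider, rec$g_ac)) {
    return(with_notice(vn, "no genomic context; intronic variant returned unchanged"))
  }
  iv <- vn$posedit$interval
  intr <- intron_of(rec, iv$start)
  intr2 <- intron_of(rec, iv$end)
  if (is.na(intr) || is.na(intr2) || intr != intr2) {
    return(with_notice(vn, "variant not confined to one intron; returned unchanged"))
  }
  vg <- n_to_g(vn, rec, provider)
  rng <- intron_g_range(rec, intr)
  dir <- config$shift_direction
  if (rec$strand < 0L) dir <- if (dir == "3p") "5p" else "3p"
  cfg2 <- normalizer_config(dir, config$cross_boundaries, config$window_size)
  vg2 <- normalize_in_seq(vg, provider, rec$g_ac, cfg2, wlo = rng[1L], whi = rng[2L])
  if (!is.null(attr(vg2, "notice"))) return(with_notice(vn, attr(vg2, "notice")))
  g_to_n(vg2, rec, provider)
}

# index (in transcript order) of the intron a position with offset != 0 lies
# in; exonic positions return NA
intron_of <- function(rec, pos) {
  if (pos$offset == 0L) {
    # exonic endpoint of a junction-adjacent interval: not intron-confined
    return(NA_integer_)
  }
  b0 <- pos$base - 1L
  i <- exon_containing_tx(rec, b0, b0 + 1L)
  if (is.na(i)) return(NA_integer_)
  if (pos$offset > 0L) {
    if (i >= nrow(rec$exons)) return(NA_integer_)
    i
  } else {
    if (i <= 1L) return(NA_integer_)
    i - 1L
  }
}
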