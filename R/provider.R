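#' Local fixture data provider
#'
#' A read-only, in-memory bundle of reference sequences, transcript records
#' (exon structures, CDS bounds, strand, per-exon transcript-genome alignment
#' segments) and transcript/protein/genome associations. It is the single
#' seam through which the validator, normalizer and mapper reach reference
#' data; an adapter for a transcript-annotation database could attach at the
#' same interface.
#'
#' A transcript record is a list with fields `tx_ac`, `gene`, `strand`
#' (+1/-1), `g_ac`, `exons` (data.frame of interbase `tx_start`, `tx_end`,
#' `g_start`, `g_end`, in transcript order), `segments` (one data.frame of
#' `op`/`len` runs per exon, ops `M` match, `X` mismatch, `TI` transcript
#' base absent from the genome, `GI` genome base absent from the transcript),
#' `cds_start`/`cds_end` (interbase transcript offsets, `NA` for non-coding),
#' and optionally `alt` (a second genomic placement: `g_ac` plus an exon
#' data.frame with `g_start`/`g_end`), used for pseudoautosomal transcripts.
#'
#' All stored coordinates are interbase (0-based, half-open); 1-based numbers
#' exist only inside HGVS strings.
#'
#' @param sequences named character vector, accession to sequence (nucleotide
#'   or protein).
#' @param transcripts named list of transcript records (see Details).
#' @param associations data.frame with columns `tx_ac`, `pro_ac`, `g_ac` (may
#'   be empty).
#' @return an object of class `hgvs_provider`.
#' @export
fixture_bundle <- function(sequences = character(), transcripts = list(),
                           associations = NULL) {
  if (is.null(associations)) {
    associations <- data.frame(tx_ac = character(), pro_ac = character(),
                               g_ac = character(), stringsAsFactors = FALSE)
  }
  prov <- structure(
    list(sequences = sequences, transcripts = transcripts, associations = associations),
    class = "hgvs_provider"
  )
  for (tx in transcripts) check_transcript_record(tx, prov)
  prov
}

#' @export
print.hgvs_provider <- function(x, ...) {
  cat(sprintf("<hgvs_provider: %d sequence(s), %d transcript(s)>\n",
              length(x$sequences), length(x$transcripts)))
  invisible(x)
}

# load-time integrity: exon tiling, segment sums on both sides, sequence
# length reconciliation, CDS bounds, match-column agreement
check_transcript_record <- function(tx, prov) {
  ex <- tx$exons
  segs <- tx$segments
  if (nrow(ex) != length(segs)) stop_data(sprintf("%s: one segment list per exon required", tx$tx_ac))
  if (ex$tx_start[1L] != 0L) stop_data(sprintf("%s: first exon must start at transcript 0", tx$tx_ac))
  if (nrow(ex) > 1L && any(ex$tx_start[-1L] != ex$tx_end[-nrow(ex)])) {
    stop_data(sprintf("%s: exon transcript intervals must be contiguous", tx$tx_ac))
  }
  for (i in seq_len(nrow(ex))) {
    sg <- segs[[i]]
    if (!all(sg$op %in% c("M", "X", "TI", "GI")) || any(sg$len < 1L)) {
      stop_data(sprintf("%s exon %d: malformed alignment segments", tx$tx_ac, i))
    }
    tx_sum <- sum(sg$len[sg$op %in% c("M", "X", "TI")])
    g_sum <- sum(sg$len[sg$op %in% c("M", "X", "GI")])
    if (tx_sum != ex$tx_end[i] - ex$tx_start[i]) {
      stop_data(sprintf("%s exon %d: segment transcript lengths do not reconcile", tx$tx_ac, i))
    }
    if (g_sum != ex$g_end[i] - ex$g_start[i]) {
      stop_data(sprintf("%s exon %d: segment genomic lengths do not reconcile", tx$tx_ac, i))
    }
  }
  # genomic intervals non-overlapping, ordered by strand along transcript order
  if (nrow(ex) > 1L) {
    ok <- if (tx$strand > 0L) all(ex$g_start[-1L] >= ex$g_end[-nrow(ex)])
          else all(ex$g_end[-1L] <= ex$g_start[-nrow(ex)])
    if (!ok) stop_data(sprintf("%s: exon genomic intervals out of strand order", tx$tx_ac))
  }
  txlen <- ex$tx_end[nrow(ex)]
  if (tx$tx_ac %in% names(prov$sequences) && nchar(prov$sequences[[tx$tx_ac]]) != txlen) {
    stop_data(sprintf("%s: exon structure length %d != sequence length %d",
                      tx$tx_ac, txlen, nchar(prov$sequences[[tx$tx_ac]])))
  }
  if (!is.na(tx$cds_start)) {
    if (tx$cds_start < 0L || tx$cds_end > txlen || tx$cds_start >= tx$cds_end) {
      stop_data(sprintf("%s: CDS bounds outside transcript", tx$tx_ac))
    }
  }
  if (!is.null(tx$alt)) {
    if (nrow(tx$alt$exons) != nrow(ex)) {
      stop_data(sprintf("%s: alternate placement must mirror the exon count", tx$tx_ac))
    }
    for (i in seq_len(nrow(ex))) {
      if (tx$alt$exons$g_end[i] - tx$alt$exons$g_start[i] != ex$g_end[i] - ex$g_start[i]) {
        stop_data(sprintf("%s: alternate placement exon %d length differs", tx$tx_ac, i))
      }
    }
  }
  # match columns must agree between stored sequences (when both are present)
  if (tx$tx_ac %in% names(prov$sequences) && tx$g_ac %in% names(prov$sequences)) {
    txseq <- prov$sequences[[tx$tx_ac]]
    for (i in seq_len(nrow(ex))) {
      cols <- exon_columns(tx, i)
      m <- which(cols$op == "M")
      if (length(m) == 0L) next
      tb <- substring(txseq, cols$txpos[m] + 1L, cols$txpos[m] + 1L)
      gb <- get_seq_bases(prov, tx$g_ac, cols$gpos[m])
      if (tx$strand < 0L) gb <- chartr("ACGTN", "TGCAN", gb)
      if (!all(tb == gb)) {
        stop_data(sprintf("%s exon %d: match segment disagrees with stored sequences", tx$tx_ac, i))
      }
    }
  }
  invisible(TRUE)
}

get_seq_bases <- function(provider, ac, pos0) {
  s <- provider$sequences[[ac]]
  substring(s, pos0 + 1L, pos0 + 1L)
}

#' Retrieve a reference sequence slice
#'
#' @param provider an `hgvs_provider`.
#' @param ac accession.
#' @param start,end interbase coordinates (`0 <= start <= end <= length`);
#'   omit both for the full sequence.
#' @return character scalar.
#' @examples
#' p <- fixture_bundle(sequences = c(toy = "GCTTTA"))
#' get_seq(p, "toy", 0, 6)
#' get_seq(p, "toy", 2, 2)  # empty slice
#' @export
get_seq <- function(provider, ac, start = NULL, end = NULL) {
  stopifnot(inherits(provider, "hgvs_provider"))
  if (!ac %in% names(provider$sequences)) {
    stop_data(sprintf("sequence data not available for accession '%s'", ac))
  }
  s <- provider$sequences[[ac]]
  if (is.null(start) && is.null(end)) return(s)
  n <- nchar(s)
  if (start < 0L || end < start || end > n) {
    stop_bounds(sprintf("slice [%s,%s) outside 0..%d for '%s'", start, end, n, ac))
  }
  substr_ib(s, start, end)
}

seq_length <- function(provider, ac) {
  if (!ac %in% names(provider$sequences)) {
    stop_data(sprintf("sequence data not available for accession '%s'", ac))
  }
  nchar(provider$sequences[[ac]])
}

has_seq <- function(provider, ac) ac %in% names(provider$sequences)

#' Retrieve a transcript record
#'
#' @param provider an `hgvs_provider`.
#' @param tx_ac transcript accession.
#' @return the transcript record (see [fixture_bundle()] for the layout).
#' @export
get_transcript <- function(provider, tx_ac) {
  stopifnot(inherits(provider, "hgvs_provider"))
  rec <- provider$transcripts[[tx_ac]]
  if (is.null(rec)) {
    stop_data(sprintf("transcript data not available for accession '%s'", tx_ac))
  }
  rec
}

has_transcript <- function(provider, tx_ac) tx_ac %in% names(provider$transcripts)

tx_length <- function(rec) rec$exons$tx_end[nrow(rec$exons)]

# ---- fixture files ---------------------------------------------------------

#' Write / read a fixture bundle on disk
#'
#' The on-disk form is one JSON manifest (`manifest.json`: transcripts,
#' alignments, associations) plus FASTA for sequences (`sequences_nt.fa` for
#' nucleotide accessions, `sequences_aa.fa` for protein accessions). Both are
#' plain text and human-diffable.
#'
#' @param provider an `hgvs_provider`.
#' @param dir fixture directory.
#' @return `read_fixture()` returns an `hgvs_provider`, validated at load
#'   time; `write_fixture()` returns `dir` invisibly.
#' @export
write_fixture <- function(provider, dir) {
  stopifnot(inherits(provider, "hgvs_provider"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_aa <- names(provider$sequences) %in% provider$associations$pro_ac
  nt <- provider$sequences[!is_aa]
  aa <- provider$sequences[is_aa]
  if (length(nt)) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(nt), file.path(dir, "sequences_nt.fa"))
  }
  if (length(aa)) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(aa), file.path(dir, "sequences_aa.fa"))
  }
  man <- list(
    format_version = 1L,
    transcripts = lapply(provider$transcripts, function(tx) {
      out <- list(
        tx_ac = tx$tx_ac, gene = tx$gene, strand = tx$strand, g_ac = tx$g_ac,
        cds_start = tx$cds_start, cds_end = tx$cds_end,
        exons = lapply(seq_len(nrow(tx$exons)), function(i) {
          list(tx_start = tx$exons$tx_start[i], tx_end = tx$exons$tx_end[i],
               g_start = tx$exons$g_start[i], g_end = tx$exons$g_end[i],
               segments = lapply(seq_len(nrow(tx$segments[[i]])), function(j) {
                 list(op = tx$segments[[i]]$op[j], len = tx$segments[[i]]$len[j])
               }))
        })
      )
      if (!is.null(tx$alt)) {
        out$alt <- list(g_ac = tx$alt$g_ac,
                        g_start = tx$alt$exons$g_start, g_end = tx$alt$exons$g_end)
      }
      out
    }),
    associations = provider$associations
  )
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_data(sprintf("no manifest.json under '%s'", dir))
  man <- jsonlite::read_json(man_path)
  seqs <- character()
  for (f in c("sequences_nt.fa", "sequences_aa.fa")) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      ss <- Biostrings::readBStringSet(p)
      v <- stats::setNames(as.character(ss), names(ss))
      seqs <- c(seqs, v)
    }
  }
  txs <- lapply(man$transcripts, function(m) {
    ex <- do.call(rbind, lapply(m$exons, function(e) {
      data.frame(tx_start = e$tx_start, tx_end = e$tx_end,
                 g_start = e$g_start, g_end = e$g_end)
    }))
    segs <- lapply(m$exons, function(e) {
      do.call(rbind, lapply(e$segments, function(s) data.frame(op = s$op, len = as.integer(s$len))))
    })
    rec <- list(
      tx_ac = m$tx_ac, gene = m$gene, strand = as.integer(m$strand), g_ac = m$g_ac,
      exons = ex, segments = segs,
      cds_start = if (is.null(m$cds_start)) NA_integer_ else as.integer(m$cds_start),
      cds_end = if (is.null(m$cds_end)) NA_integer_ else as.integer(m$cds_end),
      alt = NULL
    )
    if (!is.null(m$alt)) {
      rec$alt <- list(g_ac = m$alt$g_ac,
                      exons = data.frame(g_start = unlist(m$alt$g_start),
                                         g_end = unlist(m$alt$g_end)))
    }
    rec
  })
  names(txs) <- vapply(txs, `[[`, "", "tx_ac")
  assoc <- if (length(man$associations)) {
    do.call(rbind, lapply(man$associations, function(a) {
      data.frame(tx_ac = a$tx_ac %||% NA_character_,
                 pro_ac = a$pro_ac %||% NA_character_,
                 g_ac = a$g_ac %||% NA_character_, stringsAsFactors = FALSE)
    }))
  } else NULL
  fixture_bundle(sequences = seqs, transcripts = txs, associations = assoc)
}
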