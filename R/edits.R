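#' Variant edits
#'
#' An edit is the "change" half of a PosEdit: a tagged record whose `kind` is
#' one of `sub`, `del`, `delins`, `ins`, `dup`, `inv`, `repeat`, `con`,
#' `identity`. The reference allele may be stored as an explicit sequence
#' (`ref`), as a declared length only (`ref_len`, e.g. `del174`), or omitted;
#' the three print and validate differently. `alt` is the alternate allele
#' where the kind has one (`sub`, `ins`, `delins`).
#'
#' @param kind edit kind string.
#' @param ref explicit reference allele, or `NA`.
#' @param alt alternate allele, or `NA`.
#' @param ref_len declared reference length (mutually exclusive with an
#'   explicit `ref`), or `NA`.
#' @param unit,rep_min,rep_max repeat unit sequence and copy-number range
#'   (`rep_max == rep_min` for an exact count).
#' @param source for conversions: the source interval description, kept as the
#'   raw string.
#' @return an object of class `hgvs_edit`.
#' @examples
#' hgvs_edit("sub", ref = "C", alt = "G")
#' hgvs_edit("del", ref_len = 174L)
#' hgvs_edit("dup", ref = "GA")
#' @export
hgvs_edit <- function(kind, ref = NA_character_, alt = NA_character_,
                 ref_len = NA_integer_, unit = NA_character_,
                 rep_min = NA_integer_, rep_max = NA_integer_,
                 source = NA_character_) {
  kinds <- c("sub", "del", "delins", "ins", "dup", "inv", "repeat", "con", "identity")
  if (!kind %in% kinds) stop_coord(sprintf("unknown edit kind '%s'", kind))
  if (!is.na(ref) && !is.na(ref_len)) {
    stop_coord("an explicit ref sequence and a declared ref length are mutually exclusive")
  }
  if (kind == "sub" && (is.na(ref) || is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L)) {
    stop_coord("a substitution requires single-base ref and alt")
  }
  if (kind == "ins" && (is.na(alt) || !nzchar(alt))) {
    stop_coord("an insertion requires a non-empty alt")
  }
  structure(
    list(kind = kind, ref = ref, alt = alt, ref_len = as.integer(ref_len),
         unit = unit, rep_min = as.integer(rep_min), rep_max = as.integer(rep_max),
         source = source),
    class = "hgvs_edit"
  )
}

# internal shorthand (not exported; deliberately shadows utils::edit inside
# the package namespace only)
edit <- hgvs_edit

# Length of the reference allele this edit consumes, given its interval span
# (bases); used by the validator and apply_edit.
edit_ref_length <- function(e, span) {
  switch(e$kind,
    ins = 0L,
    span
  )
}

#' Apply an edit to a sequence
#'
#' The allele-arithmetic oracle: splice an edit into a plain nucleotide string
#' at a 1-based inclusive interval. Insertions take the two flanking bases as
#' their interval (the insert lands between them). Used throughout the test
#' suite to assert that two variant representations denote the same altered
#' sequence.
#'
#' @param seq reference sequence (character scalar).
#' @param interval integer length-2 vector, 1-based inclusive.
#' @param e an `hgvs_edit`.
#' @return the altered sequence.
#' @examples
#' apply_edit("GCTTTA", c(5, 5), hgvs_edit("del"))          # "GCTTA"
#' apply_edit("GCTA", c(4, 5), hgvs_edit("ins", alt = "A")) # "GCTAA"
#' @export
apply_edit <- function(seq, interval, e) {
  stopifnot(inherits(e, "hgvs_edit"))
  s <- as.integer(interval[1L])
  t <- as.integer(interval[2L])
  n <- nchar(seq)
  if (e$kind == "ins") {
    # the right flank may be n+1: an insertion after the final base
    if (s < 1L || t > n + 1L || t != s + 1L) stop_bounds("insertion flanks out of bounds or non-adjacent")
    return(paste0(substr(seq, 1L, s), e$alt, substr(seq, s + 1L, n)))
  }
  if (s < 1L || t > n || s > t) stop_bounds("edit interval outside 1..len(seq)")
  ref_here <- substr(seq, s, t)
  if (!is.na(e$ref) && nzchar(e$ref) && !identical(e$ref, ref_here)) {
    stop_ref_mismatch(sprintf(
      "stated reference '%s' disagrees with sequence '%s' at [%d,%d]",
      e$ref, ref_here, s, t
    ))
  }
  before <- substr(seq, 1L, s - 1L)
  after <- substr(seq, t + 1L, n)
  switch(e$kind,
    sub = paste0(before, e$alt, after),
    del = paste0(before, after),
    delins = paste0(before, e$alt, after),
    dup = paste0(before, ref_here, ref_here, after),
    inv = paste0(before, revcomp(ref_here), after),
    identity = seq,
    stop_unsupported(sprintf("apply_edit does not support '%s' edits", e$kind))
  )
}

# net length change |alt| - |ref| for supported kinds, given interval span
edit_length_change <- function(e, span) {
  switch(e$kind,
    sub = 0L,
    identity = 0L,
    inv = 0L,
    del = -span,
    dup = span,
    ins = nchar(e$alt),
    delins = nchar(e$alt) - span,
    NA_integer_
  )
}
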