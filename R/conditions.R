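#' @title Typed error conditions
#' @description Every failure raised by this package carries a condition class
#'   below `hgvs_error`, so callers can distinguish, e.g., a malformed string
#'   (`hgvs_syntax_error`) from a description the nomenclature allows but this
#'   package does not handle (`hgvs_unsupported_error`).
#' @name hgvs-conditions
#' @details Condition classes:
#' \itemize{
#'   \item `hgvs_syntax_error`: string does not match the grammar; carries a
#'     `position` field (1-based character index where parsing failed).
#'   \item `hgvs_unsupported_error`: syntactically recognizable but out of
#'     scope (uncertain positions, compound/mosaic/chimeric alleles, ISCN).
#'   \item `hgvs_bounds_error`: coordinate outside the reference sequence or
#'     alignment.
#'   \item `hgvs_ref_mismatch_error`: stated reference allele disagrees with
#'     the provider sequence.
#'   \item `hgvs_data_error`: accession/transcript unknown to the provider, or
#'     a fixture bundle failed its load-time integrity checks.
#'   \item `hgvs_validation_error`: raised by strict-mode validation or when an
#'     operation refuses to run on an ERROR-level variant.
#'   \item `hgvs_coord_error`: incompatible coordinate systems (e.g. comparing
#'     a c. position with a g. position, or asking for c. on a non-coding
#'     transcript).
#' }
NULL

hgvs_stop <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "hgvs_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_syntax <- function(message, position = NA_integer_) {
  hgvs_stop("hgvs_syntax_error", message, position = position)
}
stop_unsupported <- function(message) hgvs_stop("hgvs_unsupported_error", message)
stop_bounds <- function(message) hgvs_stop("hgvs_bounds_error", message)
stop_ref_mismatch <- function(message) hgvs_stop("hgvs_ref_mismatch_error", message)
stop_data <- function(message) hgvs_stop("hgvs_data_error", message)
stop_validation <- function(message, report = NULL) {
  hgvs_stop("hgvs_validation_error", message, report = report)
}
stop_coord <- function(message) hgvs_stop("hgvs_coord_error", message)
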