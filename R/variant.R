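#' Sequence variants
#'
#' The universal currency of the package: an accession (`ac`), a coordinate
#' type (`g`, `m`, `n`, `c`, `p`) and a PosEdit (interval + edit + uncertainty
#' flag). The coordinate type constrains the position dialect: intron offsets
#' only on `c`/`n`, UTR anchors (negative and `*` bases) only on `c`, protein
#' intervals only on `p`. Mitochondrial `m` behaves exactly like `g` apart
#' from the printed letter.
#'
#' @param ac reference sequence accession (non-empty).
#' @param type coordinate type, one of `"g"`, `"m"`, `"n"`, `"c"`, `"p"`.
#' @param posedit a [posedit()].
#' @return an object of class `hgvs_variant`; `print()` shows its HGVS string.
#' @examples
#' v <- variant("NM_000059.3", "c",
#'   posedit(bo_interval(bo_pos(201), bo_pos(202)), hgvs_edit("dup", ref = "GA")))
#' format_hgvs(v)
#' @export
variant <- function(ac, type, posedit) {
  if (!is.character(ac) || length(ac) != 1L || !nzchar(ac)) {
    stop_coord("accession must be a non-empty string")
  }
  if (!type %in% c("g", "m", "n", "c", "p")) {
    stop_coord(sprintf("unsupported coordinate type '%s'", type))
  }
  iv <- posedit$interval
  if (type %in% c("g", "m") && inherits(iv, "bo_interval")) {
    for (p in list(iv$start, iv$end)) {
      if (p$offset != 0L || p$anchor != "cds_start" || p$base < 0L) {
        stop_coord("g./m. positions take no intron offsets or UTR anchors")
      }
    }
  }
  if (type == "n" && inherits(iv, "bo_interval")) {
    for (p in list(iv$start, iv$end)) {
      if (p$anchor != "cds_start" || p$base < 0L) {
        stop_coord("n. positions take no UTR anchors")
      }
    }
  }
  if (type == "p" && !inherits(iv, "p_interval") && !is.null(iv)) {
    stop_coord("p. variants require a protein interval")
  }
  structure(list(ac = ac, type = type, posedit = posedit), class = "hgvs_variant")
}

#' @rdname variant
#' @param interval a [bo_interval()] (or `p_interval` for proteins, or `NULL`
#'   for positionless protein forms such as `p.?`).
#' @param edit an [hgvs_edit()] or protein edit.
#' @param uncertain flag; printed as enclosing parentheses on protein
#'   variants (predicted consequences).
#' @export
posedit <- function(interval, edit, uncertain = FALSE) {
  structure(list(interval = interval, edit = edit, uncertain = isTRUE(uncertain)),
            class = "hgvs_posedit")
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat(format_hgvs(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hgvs_variant <- function(x, ...) format_hgvs(x, ...)

# ---- protein positions/edits ----------------------------------------------

# A protein position is (aa, pos): the reference residue (1-letter) and its
# 1-based number, initiator Met = 1.
p_pos <- function(aa, pos) {
  structure(list(aa = aa, pos = as.integer(pos)), class = "p_pos")
}

p_interval <- function(start, end = start) {
  structure(list(start = start, end = end), class = "p_interval")
}

# Protein edits reuse the tagged-record idea with protein-specific kinds:
# sub, identity ("="), del, ins, dup, delins, fs (frameshift, `ter` = stop
# position counting the first changed residue as 1, NA = no stop found),
# ext (stop-loss extension), unknown ("?", e.g. initiator loss).
p_edit <- function(kind, alt = NA_character_, ter = NA_integer_) {
  kinds <- c("sub", "identity", "del", "ins", "dup", "delins", "fs", "ext", "unknown")
  if (!kind %in% kinds) stop_coord(sprintf("unknown protein edit kind '%s'", kind))
  structure(list(kind = kind, alt = alt, ter = as.integer(ter)), class = "hgvs_p_edit")
}

# ---- equality --------------------------------------------------------------

#' Structural equality of two variants
#'
#' Compares accession, type, interval and edit (including explicit vs declared
#' vs absent ref). Formatting settings play no role.
#' @param a,b `hgvs_variant` objects.
#' @return logical.
#' @export
variant_eq <- function(a, b) {
  identical(strip_attrs(a), strip_attrs(b))
}

strip_attrs <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_attrs)
    attributes(x) <- list(names = names(x))
  }
  x
}
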