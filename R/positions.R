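#' Base-offset positions and intervals
#'
#' HGVS transcript coordinates combine a 1-based base number (which skips zero:
#' c.-1 abuts c.1), an intron offset (c.387+32 is 32 bases into the intron
#' following c.387) and, for c. coordinates, an anchor: positions counted from
#' the CDS start (default; negative bases lie in the 5' UTR) or from the CDS
#' end (printed with a leading "*", the 3' UTR). Genomic positions are the
#' degenerate case base-only, offset 0.
#'
#' @param base signed integer, never 0.
#' @param offset signed integer intron offset; 0 means exonic.
#' @param anchor `"cds_start"` (default) or `"cds_end"` (a `*` position).
#' @return `bo_pos()` returns a `bo_pos` object; `bo_interval()` a
#'   `bo_interval` with fields `start` and `end`.
#' @examples
#' compare_positions(bo_pos(87, 2), bo_pos(88, -1))   # -1: c.87+2 < c.88-1
#' bo_interval(bo_pos(-5), bo_pos(1))
#' @export
bo_pos <- function(base, offset = 0L, anchor = c("cds_start", "cds_end")) {
  anchor <- match.arg(anchor)
  base <- as.integer(base)
  offset <- as.integer(offset)
  if (is.na(base) || base == 0L) stop_coord("position base must be a non-zero integer")
  structure(list(base = base, offset = offset, anchor = anchor), class = "bo_pos")
}

#' @rdname bo_pos
#' @param start,end `bo_pos` endpoints; must satisfy `start <= end` under the
#'   total ordering.
#' @export
bo_interval <- function(start, end = start) {
  stopifnot(inherits(start, "bo_pos"), inherits(end, "bo_pos"))
  if (compare_positions(start, end) > 0L) {
    stop_coord(sprintf(
      "interval start (%s) is after its end (%s)",
      format_bo_pos(start, "c"), format_bo_pos(end, "c")
    ))
  }
  structure(list(start = start, end = end), class = "bo_interval")
}

# Construct without the start<=end check (the intrinsic validator reports the
# violation instead of refusing to represent it).
bo_interval_unchecked <- function(start, end = start) {
  structure(list(start = start, end = end), class = "bo_interval")
}

# numeric key giving the total order (anchor, base-with-no-zero, offset)
bo_key <- function(p) {
  b <- p$base
  b <- if (b > 0L) b - 1L else b # collapse the missing zero
  c(if (p$anchor == "cds_end") 1 else 0, b, p$offset)
}

#' Compare two base-offset positions
#'
#' Total order by (anchor, base, offset): all cds_start-anchored positions
#' precede all cds_end ("*") positions; within an anchor, bases order with the
#' nomenclature's missing zero (c.-1 immediately precedes c.1); equal bases
#' order by intron offset, so c.87+2 < c.88-1 within one intron.
#'
#' @param a,b `bo_pos` objects.
#' @return -1, 0 or 1.
#' @export
compare_positions <- function(a, b) {
  if (!inherits(a, "bo_pos") || !inherits(b, "bo_pos")) {
    stop_coord("compare_positions() requires two base-offset positions")
  }
  ka <- bo_key(a)
  kb <- bo_key(b)
  d <- ka - kb
  nz <- which(d != 0)
  if (length(nz) == 0L) return(0L)
  if (d[nz[1L]] < 0) -1L else 1L
}

pos_eq <- function(a, b) compare_positions(a, b) == 0L

# Span in bases of an exonic (offset-0) interval; NA if either end is intronic
# or the ends have different anchors (not computable without CDS/UTR lengths).
interval_span <- function(iv) {
  s <- iv$start
  e <- iv$end
  if (pos_eq(s, e)) return(1L)
  if (s$anchor != e$anchor) return(NA_integer_)
  if (s$offset != 0L || e$offset != 0L) {
    # both endpoints in the same intron stretch on the same side
    if (s$base == e$base && sign(s$offset) == sign(e$offset) && s$offset != 0L) {
      return(abs(e$offset - s$offset) + 1L)
    }
    return(NA_integer_)
  }
  n <- e$base - s$base + 1L
  if (s$base < 0L && e$base > 0L) n <- n - 1L # no position zero
  n
}

# Positions adjacent (end immediately follows start)? NA = cannot tell
# intrinsically (anchor crossing, or exon/intron geometry unknown).
positions_adjacent <- function(s, e) {
  if (s$anchor == e$anchor) {
    if (s$base == e$base) return(e$offset == s$offset + 1L)
    if (s$base == -1L && e$base == 1L && s$offset == 0L && e$offset == 0L) return(TRUE)
    if (e$base == s$base + 1L) {
      if (s$offset == 0L && e$offset == 0L) return(TRUE)
      # s in intron reaching back (+k), e opening next exon, or s closing an
      # exon and e its first intron base: cannot confirm without exon lengths
      if (s$offset > 0L && e$offset == 0L) return(NA)
      if (s$offset == 0L && e$offset < 0L) return(NA)
      return(FALSE)
    }
    return(FALSE)
  }
  if (s$anchor == "cds_start" && e$anchor == "cds_end" && e$base == 1L && e$offset == 0L) {
    return(NA) # c.N_*1: adjacency depends on where the CDS ends
  }
  FALSE
}
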