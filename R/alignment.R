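# Per-exon alignment column machinery.
#
# An exon's alignment is a run-length list of segment ops: M (match), X
# (mismatch), TI (transcript base absent from the genome), GI (genome base
# absent from the transcript). Expanding runs to per-base "columns" makes
# projection arithmetic direct: each column carries the interbase index of
# its transcript base (NA for GI) and of its genomic base (NA for TI). For a
# minus-strand transcript, columns run in transcript order, so genomic
# indices decrease along the column vector. Introns are not columns; intronic
# positions are computed from exon genomic edges.

exon_columns <- function(rec, i) {
  sg <- rec$segments[[i]]
  op <- rep(sg$op, sg$len)
  K <- length(op)
  txpos <- rep(NA_integer_, K)
  gpos <- rep(NA_integer_, K)
  tx_consuming <- op %in% c("M", "X", "TI")
  g_consuming <- op %in% c("M", "X", "GI")
  txpos[tx_consuming] <- rec$exons$tx_start[i] + seq_len(sum(tx_consuming)) - 1L
  if (rec$strand > 0L) {
    gpos[g_consuming] <- rec$exons$g_start[i] + seq_len(sum(g_consuming)) - 1L
  } else {
    gpos[g_consuming] <- rec$exons$g_end[i] - seq_len(sum(g_consuming))
  }
  # boundary coordinates: txb[k+1]/gb[k+1] are the transcript / genomic
  # interbase points at boundary k (between column k and k+1), k = 0..K
  txb <- rec$exons$tx_start[i] + c(0L, cumsum(tx_consuming))
  gb <- if (rec$strand > 0L) {
    rec$exons$g_start[i] + c(0L, cumsum(g_consuming))
  } else {
    rec$exons$g_end[i] - c(0L, cumsum(g_consuming))
  }
  list(op = op, txpos = txpos, gpos = gpos, txb = txb, gb = gb, K = K)
}

# A boundary k (0..K) is "solid" when the columns on both sides (where they
# exist) are aligned (M or X): an interval cut there interacts with no gap.
solid_boundary <- function(cols, k) {
  (k == 0L || cols$op[k] %in% c("M", "X")) &&
    (k == cols$K || cols$op[k + 1L] %in% c("M", "X"))
}

# exon index containing the transcript interbase interval [ts, te); NA if it
# straddles a junction (caller falls back to endpoint-wise mapping)
exon_containing_tx <- function(rec, ts, te) {
  hit <- which(rec$exons$tx_start <= ts & te <= rec$exons$tx_end)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# exon index whose (primary) genomic span contains base index g0
exon_containing_g <- function(rec, g0, placement = "primary") {
  ex <- placement_exons(rec, placement)
  hit <- which(ex$g_start <= g0 & g0 < ex$g_end)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

placement_exons <- function(rec, placement) {
  if (placement == "alt") {
    if (is.null(rec$alt)) stop_data(sprintf("%s has no alternate genomic placement", rec$tx_ac))
    data.frame(tx_start = rec$exons$tx_start, tx_end = rec$exons$tx_end,
               g_start = rec$alt$exons$g_start, g_end = rec$alt$exons$g_end)
  } else {
    rec$exons
  }
}

placement_g_ac <- function(rec, placement) {
  if (placement == "alt") rec$alt$g_ac else rec$g_ac
}

# columns for a given placement: same ops, genomic coordinates re-anchored
exon_columns_pl <- function(rec, i, placement) {
  if (placement == "primary") return(exon_columns(rec, i))
  rec2 <- rec
  rec2$exons <- placement_exons(rec, placement)
  exon_columns(rec2, i)
}


# Decide whether an interval interacts with an alignment gap and pick its
# boundary columns. Endpoints merely adjacent to a gap run take the "tight"
# candidate (the one excluding the run), so adjacency alone never widens:
# the variant's alleles do not touch gap content. A gap interaction exists
# when gap columns fall strictly inside the tight interval, or when an
# insertion point sits at or inside a gap run (ambiguous placement); the
# interval is then widened to the nearest solid boundaries and the caller
# recomputes the allele over the widened region.
gap_and_bounds <- function(cols, empty, ks_cand, ke_cand) {
  if (empty) {
    k <- ks_cand[1L]
    gap <- length(ks_cand) > 1L || !solid_boundary(cols, k)
    if (!gap) return(list(gap = FALSE, ks = k, ke = k))
    ks <- min(ks_cand)
    while (!solid_boundary(cols, ks)) ks <- ks - 1L
    ke <- max(ke_cand)
    while (!solid_boundary(cols, ke)) ke <- ke + 1L
    return(list(gap = TRUE, ks = ks, ke = ke))
  }
  ks <- max(ks_cand)
  ke <- min(ke_cand)
  gap <- ke > ks && any(!cols$op[(ks + 1L):ke] %in% c("M", "X"))
  if (!gap) return(list(gap = FALSE, ks = ks, ke = ke))
  ks <- min(ks_cand)
  while (!solid_boundary(cols, ks)) ks <- ks - 1L
  ke <- max(ke_cand)
  while (!solid_boundary(cols, ke)) ke <- ke + 1L
  list(gap = TRUE, ks = ks, ke = ke)
}

# Project a transcript interbase interval [ts, te) (single exon) to the
# genome. Returns gs/ge (interbase, gs <= ge in genome orientation), whether
# the interval interacted with an alignment gap, and the (possibly widened)
# transcript interval actually projected.
project_tx_interval <- function(rec, ts, te, placement = "primary") {
  i <- exon_containing_tx(rec, ts, te)
  if (is.na(i)) return(NULL)
  cols <- exon_columns_pl(rec, i, placement)
  ks_cand <- which(cols$txb == ts) - 1L
  ke_cand <- which(cols$txb == te) - 1L
  gk <- gap_and_bounds(cols, ts == te, ks_cand, ke_cand)
  gap <- gk$gap
  ks <- gk$ks
  ke <- gk$ke
  g1 <- cols$gb[ks + 1L]
  g2 <- cols$gb[ke + 1L]
  list(gs = min(g1, g2), ge = max(g1, g2), gap = gap,
       ts = cols$txb[ks + 1L], te = cols$txb[ke + 1L], exon = i,
       ks = ks, ke = ke)
}

# Project a genomic interbase interval [gs, ge) (within one exon's genomic
# span) to the transcript; mirror of project_tx_interval.
project_g_interval <- function(rec, gs, ge, placement = "primary") {
  ex <- placement_exons(rec, placement)
  i <- which(ex$g_start <= gs & ge <= ex$g_end)
  if (length(i) == 0L) return(NULL)
  i <- i[1L]
  cols <- exon_columns_pl(rec, i, placement)
  b1 <- if (rec$strand > 0L) gs else ge
  b2 <- if (rec$strand > 0L) ge else gs
  ks_cand <- which(cols$gb == b1) - 1L
  ke_cand <- which(cols$gb == b2) - 1L
  gk <- gap_and_bounds(cols, b1 == b2, ks_cand, ke_cand)
  gap <- gk$gap
  ks <- gk$ks
  ke <- gk$ke
  list(ts = cols$txb[ks + 1L], te = cols$txb[ke + 1L], gap = gap,
       gs = min(cols$gb[ks + 1L], cols$gb[ke + 1L]),
       ge = max(cols$gb[ks + 1L], cols$gb[ke + 1L]), exon = i,
       ks = ks, ke = ke)
}

# genomic base index (interbase) of transcript base index t0 (interbase);
# requires the base to sit in an aligned (M/X) column
g_index_of_tx_base <- function(rec, t0, placement = "primary") {
  i <- exon_containing_tx(rec, t0, t0 + 1L)
  if (is.na(i)) return(NA_integer_)
  cols <- exon_columns_pl(rec, i, placement)
  k <- which(!is.na(cols$txpos) & cols$txpos == t0)
  if (length(k) != 1L || is.na(cols$gpos[k])) return(NA_integer_)
  cols$gpos[k]
}

# total intron span (genomic bases) between exon i and i+1 in transcript order
intron_g_range <- function(rec, i, placement = "primary") {
  ex <- placement_exons(rec, placement)
  if (rec$strand > 0L) c(ex$g_end[i], ex$g_start[i + 1L])
  else c(ex$g_end[i + 1L], ex$g_start[i])
}
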