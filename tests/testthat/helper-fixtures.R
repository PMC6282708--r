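# Shared fixtures and oracles. Everything is built in code; nothing is read
# from disk except what a test itself writes to a tempdir.

BASES <- c("A", "C", "G", "T")

toy_provider <- function() {
  fixture_bundle(sequences = c(T1 = "GCTTTA", T2 = "GCTA"))
}

# A small hand-built two-exon plus-strand coding transcript with no
# alignment discrepancies. Genome layout:
#   intergenic(10) exon1(30) intron(20) exon2(30) tail(10)
# CDS occupies tx [10, 46) (12 codons).
hand_tx_plus <- function() {
  exon1 <- "ATTTGCCGGTATGGCATCAATCGGAGCTGA"  # 30
  intron <- "GTAAGTCCCCCCCCCCCCAG"            # 20
  exon2 <- "CCTGGTCAGCTTGAAGGGCATTTTTTTTTA"  # 30
  genome <- paste0("GGGGGGGGGG", exon1, intron, exon2, "CCCCCCCCCC")
  tx <- paste0(exon1, exon2)
  rec <- list(
    tx_ac = "NM_000001.1", gene = "TST1", strand = 1L, g_ac = "NC_000900.1",
    exons = data.frame(tx_start = c(0L, 30L), tx_end = c(30L, 60L),
                       g_start = c(10L, 60L), g_end = c(40L, 90L)),
    segments = list(data.frame(op = "M", len = 30L), data.frame(op = "M", len = 30L)),
    cds_start = 10L, cds_end = 46L, alt = NULL
  )
  prot <- sub("\\*$", "", translate_aa(substr(tx, 11, 46)))
  fixture_bundle(
    sequences = c(NM_000001.1 = tx, NC_000900.1 = genome, NP_000001.1 = prot),
    transcripts = list(NM_000001.1 = rec),
    associations = data.frame(tx_ac = "NM_000001.1", pro_ac = "NP_000001.1",
                              g_ac = "NC_000900.1")
  )
}

# 1-letter translation for helper use (independent of package internals)
translate_aa <- function(x) {
  n <- nchar(x) %/% 3
  paste(vapply(seq_len(n), function(i) {
    cd <- substr(x, 3 * i - 2, 3 * i)
    aa <- Biostrings::GENETIC_CODE[[cd]]
    if (is.null(aa)) "X" else aa
  }, ""), collapse = "")
}

# Transcript reproducing a 3-nt genome insertion (GI gap) between two
# adjacent transcript bases, with the gap placed so that transcript base
# `tx_before_gap` maps to genomic base `g_before_gap` (1-based), echoing the
# published NM_033089-style indel-aware projection case. Synthetic.
gap_gi_provider <- function(tx_before_gap = 484L, g_before_gap = 278687L,
                            cds_start = 24L) {
  set.seed(4242)
  txlen <- tx_before_gap + 60L
  tx <- paste0(sample(BASES, txlen, replace = TRUE), collapse = "")
  # the bases flanking the gap are C on the transcript (as in the published
  # indel-aware projection example, where both flanking variants are C>N)
  substr(tx, tx_before_gap, tx_before_gap + 1L) <- "CC"
  # single exon: g run = tx length + 3 (the three genome-only bases)
  g_start <- (g_before_gap - 1L) - (tx_before_gap - 1L) # interbase
  g_len <- txlen + 3L
  exon_g <- paste0(
    substr(tx, 1L, tx_before_gap), "TAC",
    substr(tx, tx_before_gap + 1L, txlen)
  )
  genome <- paste0(strrep("N", g_start), exon_g, strrep("N", 25L))
  rec <- list(
    tx_ac = "NM_933089.1", gene = "GAPG", strand = 1L, g_ac = "NC_900020.1",
    exons = data.frame(tx_start = 0L, tx_end = txlen,
                       g_start = g_start, g_end = g_start + g_len),
    segments = list(data.frame(op = c("M", "GI", "M"),
                               len = c(tx_before_gap, 3L, txlen - tx_before_gap))),
    cds_start = cds_start, cds_end = cds_start + 3L * ((txlen - cds_start - 10L) %/% 3L),
    alt = NULL
  )
  fixture_bundle(sequences = c(NM_933089.1 = tx, NC_900020.1 = genome),
                 transcripts = list(NM_933089.1 = rec),
                 associations = data.frame(tx_ac = "NM_933089.1",
                                           pro_ac = NA_character_,
                                           g_ac = "NC_900020.1"))
}

# ---- independent splice-and-compare oracle ---------------------------------
# Given a genomic variant on a transcript's genome, rebuild the transcript
# implied by the edited genome. The variant consumes the alignment columns it
# covers; an endpoint merely adjacent to a gap run takes the tight boundary
# (the run survives on its side), while gap columns strictly inside the
# interval -- or an insertion point at/inside a gap run -- widen the region
# to solid (match/mismatch) anchors. The consumed region contributes the
# oriented edited genomic content verbatim; all other columns splice
# normally (M from the genome, X/TI from the transcript, GI skipped).
# Implemented from the raw segment runs, independently of the package's
# projection code.
oracle_resplice <- function(rec, p, gvar) {
  G <- get_seq(p, rec$g_ac)
  txseq <- get_seq(p, rec$tx_ac)
  iv <- gvar$posedit$interval
  e <- gvar$posedit$edit
  if (e$kind == "ins") {
    a <- iv$start$base
    b <- a
  } else {
    a <- iv$start$base - 1L
    b <- iv$end$base
  }
  al <- oracle_alleles(G, a, b, e)
  out <- character()
  for (i in seq_len(nrow(rec$exons))) {
    sg <- rec$segments[[i]]
    op <- rep(sg$op, sg$len)
    K <- length(op)
    txc <- op %in% c("M", "X", "TI")
    gc <- op %in% c("M", "X", "GI")
    txpos <- rep(NA_integer_, K)
    gpos <- rep(NA_integer_, K)
    txpos[txc] <- rec$exons$tx_start[i] + seq_len(sum(txc)) - 1L
    if (rec$strand > 0) gpos[gc] <- rec$exons$g_start[i] + seq_len(sum(gc)) - 1L
    else gpos[gc] <- rec$exons$g_end[i] - seq_len(sum(gc))
    gb <- if (rec$strand > 0) rec$exons$g_start[i] + c(0L, cumsum(gc))
          else rec$exons$g_end[i] - c(0L, cumsum(gc))
    emit_col <- function(k) {
      if (op[k] == "GI") return("")
      if (op[k] %in% c("X", "TI")) return(substr(txseq, txpos[k] + 1, txpos[k] + 1))
      bb <- substr(G, gpos[k] + 1, gpos[k] + 1)
      if (rec$strand < 0) chartr("ACGTN", "TGCAN", bb) else bb
    }
    b1 <- if (rec$strand > 0) a else b
    b2 <- if (rec$strand > 0) b else a
    ks_cand <- which(gb == b1) - 1L
    ke_cand <- which(gb == b2) - 1L
    if (length(ks_cand) == 0L || length(ke_cand) == 0L) { # unaffected exon
      out <- c(out, paste(vapply(seq_len(K), emit_col, ""), collapse = ""))
      next
    }
    solid <- function(k) (k == 0 || op[k] %in% c("M", "X")) &&
      (k == K || op[k + 1] %in% c("M", "X"))
    if (a == b) {
      ks <- ke <- ks_cand[1L]
      if (length(ks_cand) > 1L || !solid(ks)) {
        ks <- min(ks_cand); while (!solid(ks)) ks <- ks - 1L
        ke <- max(ke_cand); while (!solid(ke)) ke <- ke + 1L
      }
    } else {
      ks <- max(ks_cand)
      ke <- min(ke_cand)
      if (ke > ks && any(!op[(ks + 1):ke] %in% c("M", "X"))) {
        ks <- min(ks_cand); while (!solid(ks)) ks <- ks - 1L
        ke <- max(ke_cand); while (!solid(ke)) ke <- ke + 1L
      }
    }
    A <- min(gb[ks + 1L], gb[ke + 1L])
    B <- max(gb[ks + 1L], gb[ke + 1L])
    content <- paste0(substring(G, A + 1, a), al$alt, substring(G, b + 1, B))
    mid <- if (rec$strand < 0) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(content)))
    } else content
    pre <- if (ks >= 1L) paste(vapply(seq_len(ks), emit_col, ""), collapse = "") else ""
    post <- if (ke < K) paste(vapply((ke + 1L):K, emit_col, ""), collapse = "") else ""
    out <- c(out, paste0(pre, mid, post))
  }
  paste0(out, collapse = "")
}

oracle_alleles <- function(seq, a, b, e) {
  ref <- substring(seq, a + 1, b)
  alt <- switch(e$kind,
    sub = e$alt,
    del = "",
    delins = e$alt,
    ins = e$alt,
    dup = paste0(ref, ref),
    inv = as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref))),
    identity = ref
  )
  list(ref = ref, alt = alt)
}

# apply a variant object to its own sequence (1-based positions)
apply_variant_seq <- function(v, seq) {
  iv <- v$posedit$interval
  apply_edit(seq, c(iv$start$base, iv$end$base), v$posedit$edit)
}

# ---- random generators -----------------------------------------------------

random_nt <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

# random well-formed variant object for the parse/format round-trip property
random_variant_obj <- function() {
  type <- sample(c("g", "m", "n", "c", "p"), 1, prob = c(.25, .05, .2, .3, .2))
  ac <- switch(type,
    g = sprintf("NC_%06d.%d", sample(1e5, 1), sample(9, 1)),
    m = "NC_012920.1",
    n = sprintf("NR_%06d.%d", sample(1e5, 1), sample(9, 1)),
    c = sprintf("NM_%06d.%d", sample(1e5, 1), sample(9, 1)),
    p = sprintf("NP_%06d.%d", sample(1e5, 1), sample(9, 1))
  )
  if (type == "p") {
    pos <- sample(2000, 1)
    aa <- sample(setdiff(names(Biostrings::AMINO_ACID_CODE), c("U", "O", "B", "J", "Z", "X")), 2)
    kind <- sample(c("sub", "identity", "del", "dup", "ins", "delins", "fs", "ext"), 1)
    p1 <- hgvsr:::p_pos(aa[1], pos)
    ivp <- if (kind %in% c("ins", "delins", "del", "dup") && runif(1) < .6) {
      hgvsr:::p_interval(p1, hgvsr:::p_pos(aa[2], pos + sample(5, 1)))
    } else hgvsr:::p_interval(p1)
    alt_aa <- paste0(sample(setdiff(names(Biostrings::AMINO_ACID_CODE),
                                    c("U", "O", "B", "J", "Z", "X")), sample(3, 1)), collapse = "")
    e <- switch(kind,
      sub = hgvsr:::p_edit("sub", alt = substr(alt_aa, 1, 1)),
      identity = hgvsr:::p_edit("identity"),
      del = hgvsr:::p_edit("del"),
      dup = hgvsr:::p_edit("dup"),
      ins = hgvsr:::p_edit("ins", alt = alt_aa),
      delins = hgvsr:::p_edit("delins", alt = alt_aa),
      fs = hgvsr:::p_edit("fs", alt = substr(alt_aa, 1, 1),
                          ter = if (runif(1) < .7) sample(50, 1) else NA),
      ext = hgvsr:::p_edit("ext", alt = substr(alt_aa, 1, 1), ter = sample(50, 1))
    )
    return(variant(ac, "p", posedit(ivp, e, uncertain = runif(1) < .3)))
  }
  mkpos <- function(base) {
    if (type == "c") {
      r <- runif(1)
      if (r < .15) return(bo_pos(-sample(200, 1)))
      if (r < .3) return(bo_pos(sample(200, 1), anchor = "cds_end"))
      if (r < .55) return(bo_pos(base, sample(c(-50:-1, 1:50), 1)))
      return(bo_pos(base))
    }
    if (type == "n" && runif(1) < .3) return(bo_pos(base, sample(c(-30:-1, 1:30), 1)))
    bo_pos(base)
  }
  b <- sample(5000, 1)
  kind <- sample(c("sub", "del", "delins", "ins", "dup", "inv", "identity", "repeat", "con"), 1,
                 prob = c(.3, .15, .1, .15, .1, .05, .05, .05, .05))
  p1 <- mkpos(b)
  if (kind == "ins") {
    # flanks must be adjacent for a syntactically honest insertion
    p1 <- bo_pos(b)
    iv <- bo_interval(p1, bo_pos(b + 1L))
  } else if (kind == "sub") {
    iv <- bo_interval(p1, p1)
  } else {
    span <- sample(0:8, 1)
    p2 <- if (span == 0) p1 else tryCatch(bo_pos(p1$base + span, p1$offset, p1$anchor),
                                          error = function(e) p1)
    iv <- tryCatch(bo_interval(p1, p2), error = function(e) bo_interval(p1, p1))
  }
  span <- tryCatch(hgvsr:::interval_span(iv), error = function(e) NA)
  e <- switch(kind,
    sub = hgvs_edit("sub", ref = sample(BASES, 1), alt = sample(BASES, 1)),
    del = if (runif(1) < .3 && !is.na(span)) hgvs_edit("del", ref_len = span)
          else if (runif(1) < .5 && !is.na(span)) hgvs_edit("del", ref = random_nt(span))
          else hgvs_edit("del"),
    delins = hgvs_edit("delins", alt = random_nt(sample(6, 1))),
    ins = hgvs_edit("ins", alt = random_nt(sample(6, 1))),
    dup = if (runif(1) < .4 && !is.na(span)) hgvs_edit("dup", ref = random_nt(span))
          else hgvs_edit("dup"),
    inv = hgvs_edit("inv"),
    identity = hgvs_edit("identity"),
    "repeat" = {
      n1 <- sample(20, 1)
      if (runif(1) < .5) hgvs_edit("repeat", unit = random_nt(sample(4, 1)), rep_min = n1, rep_max = n1)
      else hgvs_edit("repeat", unit = random_nt(sample(4, 1)), rep_min = n1, rep_max = n1 + sample(8, 1))
    },
    con = hgvs_edit("con", source = sprintf("%d_%d", b + 100, b + 100 + sample(20, 1)))
  )
  variant(ac, type, posedit(iv, e))
}

# random exonic transcript variant on a generated fixture; optionally keeps a
# margin away from exon junctions, alignment features and transcript ends
random_tx_variant <- function(p, truth, tx_ac, margin = 0L, kinds = c("sub", "del", "ins", "dup", "delins")) {
  rec <- get_transcript(p, tx_ac)
  txseq <- get_seq(p, tx_ac)
  n <- nchar(txseq)
  feats <- c(0L, n, rec$exons$tx_start, rec$exons$tx_end)
  tr <- truth[truth$tx_ac == tx_ac, ]
  if (nrow(tr)) feats <- c(feats, tr$tx_start, tr$tx_end)
  for (i in 1:50) {
    b <- sample(seq_len(n - 1L), 1)
    span <- sample(0:3, 1)
    if (margin > 0L && any(abs(c(b, b + span) - rep(feats, each = 2)) <= margin)) next
    kind <- sample(kinds, 1)
    e <- switch(kind,
      sub = {
        r <- substr(txseq, b, b)
        hgvs_edit("sub", ref = r, alt = sample(setdiff(BASES, r), 1))
      },
      del = hgvs_edit("del"),
      ins = hgvs_edit("ins", alt = random_nt(sample(3, 1))),
      dup = hgvs_edit("dup"),
      delins = hgvs_edit("delins", alt = random_nt(sample(4, 1)))
    )
    iv <- if (kind == "ins") bo_interval(bo_pos(b), bo_pos(b + 1L))
          else if (kind == "sub") bo_interval(bo_pos(b))
          else bo_interval(bo_pos(b), bo_pos(min(b + span, n)))
    v <- variant(tx_ac, "n", posedit(iv, e))
    ib <- c(if (kind == "ins") b else b - 1L, if (kind == "ins") b else min(b + span, n))
    if (is.na(hgvsr:::exon_containing_tx(rec, ib[1], ib[2]))) next
    return(v)
  }
  NULL
}
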