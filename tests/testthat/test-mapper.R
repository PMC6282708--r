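test_that("c./n. renumbering round-trips and respects the CDS anchors", {
  p <- hand_tx_plus()
  rec <- get_transcript(p, "NM_000001.1")
  # CDS starts at interbase 10: n.11 == c.1, n.10 == c.-1, n.47 == c.*1
  vc <- parse_hgvs("NM_000001.1:c.1del")
  expect_identical(c_to_n(vc, rec)$posedit$interval$start$base, 11L)
  vn <- parse_hgvs("NM_000001.1:n.10del")
  expect_identical(n_to_c(vn, rec)$posedit$interval$start$base, -1L)
  vs <- parse_hgvs("NM_000001.1:n.47del")
  cc <- n_to_c(vs, rec)
  expect_identical(cc$posedit$interval$start$anchor, "cds_end")
  expect_identical(cc$posedit$interval$start$base, 1L)
  # exhaustive inverse over the whole transcript
  for (b in seq_len(tx_length(rec))) {
    v <- variant("NM_000001.1", "n",
                 posedit(bo_interval(bo_pos(b)), hgvs_edit("del")))
    back <- c_to_n(n_to_c(v, rec), rec)
    expect_identical(back$posedit$interval$start$base, b)
  }
  # no transcript position maps to c.0
  cs <- vapply(seq_len(tx_length(rec)), function(b) {
    v <- variant("NM_000001.1", "n",
                 posedit(bo_interval(bo_pos(b)), hgvs_edit("del")))
    n_to_c(v, rec)$posedit$interval$start$base
  }, integer(1))
  expect_false(any(cs == 0L))
  # non-coding transcripts have no c. numbering
  fx <- generate_fixture(seed = 51)
  nr <- get_transcript(fx$provider, "NR_900201.1")
  vnr <- variant("NR_900201.1", "n", posedit(bo_interval(bo_pos(5)), hgvs_edit("del")))
  expect_error(n_to_c(vnr, nr), class = "hgvs_coord_error")
})

test_that("gap-free exonic positions project affinely on both strands", {
  p <- hand_tx_plus()
  rec <- get_transcript(p, "NM_000001.1")
  # exon 1 starts at genomic interbase 10: n.1 -> g.11
  v <- variant("NM_000001.1", "n", posedit(bo_interval(bo_pos(1)), hgvs_edit("del")))
  vg <- n_to_g(v, rec, p)
  expect_identical(vg$posedit$interval$start$base, 11L)
  # exon 2 starts at genomic interbase 60: n.31 -> g.61
  v2 <- variant("NM_000001.1", "n", posedit(bo_interval(bo_pos(31)), hgvs_edit("del")))
  expect_identical(n_to_g(v2, rec, p)$posedit$interval$start$base, 61L)
  # minus strand: first transcript base sits at the exon's genomic end
  fx <- generate_fixture(seed = 52)
  pm <- fx$provider
  minus <- Filter(function(r) r$strand < 0L, pm$transcripts)
  rec2 <- minus[[1]]
  v3 <- variant(rec2$tx_ac, "n", posedit(bo_interval(bo_pos(1)), hgvs_edit("del")))
  vg3 <- n_to_g(v3, rec2, pm)
  expect_identical(vg3$posedit$interval$start$base, rec2$exons$g_end[1])
  # minus-strand alleles are reverse-complemented
  txseq <- get_seq(pm, rec2$tx_ac)
  r1 <- substr(txseq, 1, 1)
  v4 <- variant(rec2$tx_ac, "n",
                posedit(bo_interval(bo_pos(1)),
                        hgvs_edit("sub", ref = r1, alt = setdiff(BASES, r1)[1])))
  vg4 <- n_to_g(v4, rec2, pm)
  expect_identical(vg4$posedit$edit$ref, hgvsr:::revcomp(r1))
})

test_that("a genome insertion gap separates adjacent transcript positions", {
  p <- gap_gi_provider() # 3-nt genomic insertion between tx base 484 and 485
  rec <- get_transcript(p, "NM_933089.1")
  proj_start <- function(cpos) {
    v <- variant("NM_933089.1", "c",
                 posedit(bo_interval(bo_pos(cpos)), hgvs_edit("del")))
    vg <- n_to_g(c_to_n(v, rec), rec, p)
    vg$posedit$interval$start$base
  }
  g460 <- proj_start(460L) # tx base 484
  g461 <- proj_start(461L) # tx base 485, beyond the 3-nt gap
  expect_identical(g460, 278687L)
  expect_identical(g461, 278691L)
  expect_identical(g461 - g460, 4L) # adjacent on the transcript, 4 apart on the genome
})

test_that("intronic positions take the closest exon edge, ties going upstream", {
  p <- hand_tx_plus()
  rec <- get_transcript(p, "NM_000001.1")
  # intron spans genomic interbase [40, 60), 20 bases; exon1 ends at n.30
  near_up <- variant("NC_000900.1", "g",
                     posedit(bo_interval(bo_pos(43)), hgvs_edit("del")))
  vn <- g_to_n(near_up, rec, p)
  expect_identical(vn$posedit$interval$start$base, 30L)
  expect_identical(vn$posedit$interval$start$offset, 3L)
  near_dn <- variant("NC_000900.1", "g",
                     posedit(bo_interval(bo_pos(58)), hgvs_edit("del")))
  vn2 <- g_to_n(near_dn, rec, p)
  expect_identical(vn2$posedit$interval$start$base, 31L)
  expect_identical(vn2$posedit$interval$start$offset, -3L)
  # exact middle (g.50: 10 from either edge): tie resolved as +10
  mid <- variant("NC_000900.1", "g",
                 posedit(bo_interval(bo_pos(50)), hgvs_edit("del")))
  vn3 <- g_to_n(mid, rec, p)
  expect_identical(vn3$posedit$interval$start$base, 30L)
  expect_identical(vn3$posedit$interval$start$offset, 10L)
})

test_that("projection refuses positions beyond the transcript bounds", {
  p <- hand_tx_plus()
  expect_error(project_tx_to_genome(parse_hgvs("NM_000001.1:c.500000G>T"), p),
               class = "hgvs_bounds_error")
  rec <- get_transcript(p, "NM_000001.1")
  v <- variant("NM_000001.1", "n", posedit(bo_interval(bo_pos(99)), hgvs_edit("del")))
  expect_error(n_to_g(v, rec, p), class = "hgvs_bounds_error")
  # genomic variant outside the transcript span
  far <- variant("NC_000900.1", "g", posedit(bo_interval(bo_pos(5)), hgvs_edit("del")))
  expect_error(g_to_n(far, rec, p), class = "hgvs_bounds_error")
})

test_that("the reference allele is replaced after projection at discrepant sites", {
  # fixture with an X (substitution discrepancy) column
  fx <- generate_fixture(seed = 53, gap_spec = list(n_tx_ins = 0L, n_genome_ins = 0L, len_range = c(1L, 1L)),
                         snp_spec = list(n = 3L))
  p <- fx$provider
  tr <- fx$truth[fx$truth$kind == "mismatch", ][1, ]
  rec <- get_transcript(p, tr$tx_ac)
  txseq <- get_seq(p, tr$tx_ac)
  tx_base <- substring(txseq, tr$tx_start + 1, tr$tx_end) # transcript side of the SNP
  g_base <- get_seq(p, rec$g_ac, tr$g_start, tr$g_end)    # genome side (plus strand)
  or_tx_base <- if (rec$strand < 0) hgvsr:::revcomp(tx_base) else tx_base
  expect_false(or_tx_base == g_base)
  alt <- setdiff(BASES, c(tx_base, if (rec$strand > 0) g_base else hgvsr:::revcomp(g_base)))[1]
  v <- variant(tr$tx_ac, "n",
               posedit(bo_interval(bo_pos(tr$tx_start + 1L)),
                       hgvs_edit("sub", ref = tx_base, alt = alt)))
  vg <- project_tx_to_genome(v, p)
  # stated genomic reference is the genome's own base, not the transcript's
  expect_identical(vg$posedit$edit$ref, g_base)
  expect_identical(vg$posedit$edit$alt, if (rec$strand < 0) hgvsr:::revcomp(alt) else alt)
  # and back-projection restores the transcript's reference
  vt <- project_genome_to_tx(vg, tr$tx_ac, p)
  vt_n <- if (vt$type == "c") c_to_n(vt, rec) else vt
  expect_identical(vt_n$posedit$edit$ref, tx_base)
})

test_that("a genomic variant matching the reference collapses to identity", {
  p <- hand_tx_plus()
  G <- get_seq(p, "NC_000900.1")
  seg <- substr(G, 61, 65)
  v <- variant("NC_000900.1", "g",
               posedit(bo_interval(bo_pos(61), bo_pos(65)),
                       hgvs_edit("delins", alt = seg)))
  out <- project_genome_to_tx(v, "NM_000001.1", p)
  expect_identical(out$posedit$edit$kind, "identity")
})

test_that("relevant_transcripts finds spanning transcripts in sorted order", {
  fx <- generate_fixture(seed = 54)
  p <- fx$provider
  # NR isoform shares gene 1's locus: a variant there sees both transcripts
  rec1 <- get_transcript(p, "NM_900101.1")
  mid <- rec1$exons$g_start[1] + 5L
  v <- variant(rec1$g_ac, "g", posedit(bo_interval(bo_pos(mid + 1L)), hgvs_edit("del")))
  hits <- relevant_transcripts(v, p)
  expect_true(all(c("NM_900101.1", "NR_900201.1") %in% hits))
  expect_identical(hits, sort(hits))
  # intergenic position: no transcripts
  v2 <- variant(rec1$g_ac, "g", posedit(bo_interval(bo_pos(5)), hgvs_edit("del")))
  expect_identical(relevant_transcripts(v2, p), character(0))
  # single-gene position
  rec3 <- get_transcript(p, "NM_900103.1")
  v3 <- variant(rec3$g_ac, "g",
                posedit(bo_interval(bo_pos(rec3$exons$g_start[1] + 6L)), hgvs_edit("del")))
  expect_identical(relevant_transcripts(v3, p), "NM_900103.1")
})

test_that("pseudoautosomal transcripts project to the chosen placement", {
  fx <- generate_fixture(seed = 55)
  p <- fx$provider
  par_tx <- Filter(function(r) !is.null(r$alt), p$transcripts)[[1]]
  txseq <- get_seq(p, par_tx$tx_ac)
  b <- par_tx$exons$tx_start[1] + 10L
  r <- substr(txseq, b, b)
  v <- variant(par_tx$tx_ac, "n",
               posedit(bo_interval(bo_pos(b)),
                       hgvs_edit("sub", ref = r, alt = setdiff(BASES, r)[1])))
  vx <- project_tx_to_genome(v, p, par = "X")
  vy <- project_tx_to_genome(v, p, par = "Y")
  expect_identical(vx$ac, par_tx$g_ac)
  expect_identical(vy$ac, par_tx$alt$g_ac)
  # both placements carry the same sequence, so the alleles agree
  expect_identical(vx$posedit$edit$ref, vy$posedit$edit$ref)
  expect_identical(vx$posedit$edit$alt, vy$posedit$edit$alt)
  # dual placement is visible to transcript discovery on the Y-like accession
  hits <- relevant_transcripts(vy, p)
  expect_true(par_tx$tx_ac %in% hits)
})

test_that("projection round trips restore the normalized transcript variant", {
  fx <- generate_fixture(seed = 56)
  p <- fx$provider
  set.seed(57)
  n_done <- 0
  while (n_done < 150) {
    tx_ac <- sample(names(p$transcripts), 1)
    rec <- get_transcript(p, tx_ac)
    v <- random_tx_variant(p, fx$truth, tx_ac, margin = 20L)
    if (is.null(v)) next
    vt <- if (!is.na(rec$cds_start)) n_to_c(v, rec) else v
    vg <- project_tx_to_genome(vt, p)
    vt2 <- project_genome_to_tx(vg, tx_ac, p)
    expect_identical(format_hgvs(vt2), format_hgvs(normalize_variant(vt, p)))
    n_done <- n_done + 1
  }
})

test_that("minus-strand duplications are re-normalized on the plus strand", {
  # transcript-3'-correct dup on a minus-strand gene must re-shift 3' on the
  # genome after projection
  fx <- generate_fixture(seed = 58)
  p <- fx$provider
  minus <- Filter(function(r) r$strand < 0L, p$transcripts)
  rec <- minus[[1]]
  txseq <- get_seq(p, rec$tx_ac)
  set.seed(59)
  found <- FALSE
  for (i in 1:400) {
    b <- sample(30:(nchar(txseq) - 30), 1)
    v <- variant(rec$tx_ac, "n",
                 posedit(bo_interval(bo_pos(b), bo_pos(b + 1L)), hgvs_edit("dup")))
    vn <- tryCatch(normalize_variant(v, p), error = function(e) NULL)
    if (is.null(vn) || vn$posedit$edit$kind != "dup") next
    vg <- tryCatch(project_tx_to_genome(vn, p), error = function(e) NULL)
    if (is.null(vg) || vg$posedit$edit$kind != "dup") next
    found <- TRUE
    # the genomic dup must itself be 3'-most on the plus strand
    vg2 <- normalize_variant(vg, p)
    expect_identical(format_hgvs(vg2), format_hgvs(vg))
  }
  expect_true(found)
})

test_that("protein consequences are predicted from the edited CDS", {
  # CDS: ATG GGC CGC AAA TTG TAA; 3' UTR supplies downstream frames
  tx <- paste0("GGGGG", "ATGGGCCGCAAATTGTAA", "CCCCTAACCGGTTAACCGGTT")
  rec <- list(
    tx_ac = "NM_000002.1", gene = "TST2", strand = 1L, g_ac = "NC_000901.1",
    exons = data.frame(tx_start = 0L, tx_end = nchar(tx), g_start = 0L, g_end = nchar(tx)),
    segments = list(data.frame(op = "M", len = nchar(tx))),
    cds_start = 5L, cds_end = 23L, alt = NULL
  )
  p <- fixture_bundle(
    sequences = c(NM_000002.1 = tx, NC_000901.1 = tx, NP_000002.1 = "MGRKL"),
    transcripts = list(NM_000002.1 = rec),
    associations = data.frame(tx_ac = "NM_000002.1", pro_ac = "NP_000002.1",
                              g_ac = "NC_000901.1")
  )
  fmt <- function(v) format_hgvs(v)

  # missense: c.4G>C turns GGC (Gly2) into CGC (Arg)
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.4G>C"), p)),
                   "NP_000002.1:p.(Gly2Arg)")
  # synonymous: c.6C>T keeps Gly2 (GGC -> GGT)
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.6C>T"), p)),
                   "NP_000002.1:p.(Gly2=)")
  # nonsense: c.10A>T makes AAA (Lys4) TAA
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.10A>T"), p)),
                   "NP_000002.1:p.(Lys4Ter)")
  # frameshift: one-base deletion in codon 2; new frame reads GCC GCA AAT
  # TGT AAC CCC TAA -> stop is the 7th residue from the changed one
  vfs <- c_to_p(parse_hgvs("NM_000002.1:c.4del"), p)
  expect_identical(vfs$posedit$edit$kind, "fs")
  expect_identical(vfs$posedit$interval$start$pos, 2L)
  expect_identical(fmt(vfs), "NP_000002.1:p.(Gly2AlafsTer7)")
  # in-frame deletion of codon 4 (AAA): Lys4del
  vdel <- c_to_p(parse_hgvs("NM_000002.1:c.10_12del"), p)
  expect_identical(fmt(vdel), "NP_000002.1:p.(Lys4del)")
  # in-frame duplication of codon 2
  vdup <- c_to_p(parse_hgvs("NM_000002.1:c.4_6dup"), p)
  expect_identical(fmt(vdup), "NP_000002.1:p.(Gly2dup)")
  # in-frame insertion of a codon between 2 and 3
  vins <- c_to_p(parse_hgvs("NM_000002.1:c.6_7insGAT"), p)
  expect_identical(vins$posedit$edit$kind, "ins")
  expect_identical(fmt(vins), "NP_000002.1:p.(Gly2_Arg3insAsp)")
  # stop-loss: c.16_18 TAA... c.16T>C turns TAA into CAA -> extension
  vext <- c_to_p(parse_hgvs("NM_000002.1:c.16T>C"), p)
  expect_identical(vext$posedit$edit$kind, "ext")
  # intronic and UTR-only variants are p.?, not exceptions
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.2-1del"), p)),
                   "NP_000002.1:p.?")
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.-2del"), p)),
                   "NP_000002.1:p.?")
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.*3del"), p)),
                   "NP_000002.1:p.?")
  # initiator-codon change is unknowable
  expect_identical(fmt(c_to_p(parse_hgvs("NM_000002.1:c.2T>C"), p)),
                   "NP_000002.1:p.?")
  # non-coding transcripts have no protein consequence
  fx <- generate_fixture(seed = 60)
  vnr <- variant("NR_900201.1", "c", posedit(bo_interval(bo_pos(5)), hgvs_edit("del")))
  expect_error(c_to_p(vnr, fx$provider), class = "hgvs_coord_error")
})

test_that("frameshift stop scanning matches brute-force translation", {
  fx <- generate_fixture(seed = 61)
  p <- fx$provider
  set.seed(62)
  n_done <- 0
  while (n_done < 60) {
    tx_ac <- sample(grep("^NM_", names(p$transcripts), value = TRUE), 1)
    rec <- get_transcript(p, tx_ac)
    txseq <- get_seq(p, tx_ac)
    b <- sample((rec$cds_start + 4L):(rec$cds_end - 6L), 1) # inside CDS, past codon 1
    v <- variant(tx_ac, "n", posedit(bo_interval(bo_pos(b)), hgvs_edit("del")))
    vp <- c_to_p(n_to_c(v, rec), p)
    if (vp$posedit$edit$kind != "fs") { n_done <- n_done + 1; next }
    # brute force: translate the shifted suffix and find the stop
    alt_cds_on <- paste0(substring(txseq, rec$cds_start + 1, b - 1),
                         substring(txseq, b + 1, nchar(txseq)))
    aa_alt <- translate_aa(substr(alt_cds_on, 1, 3 * (nchar(alt_cds_on) %/% 3)))
    aa_ref <- translate_aa(substring(txseq, rec$cds_start + 1, rec$cds_end))
    i <- vp$posedit$interval$start$pos
    expect_identical(substr(aa_ref, i, i), vp$posedit$interval$start$aa)
    if (!is.na(vp$posedit$edit$ter)) {
      stop_rel <- regexpr("*", substring(aa_alt, i), fixed = TRUE)[1]
      expect_identical(vp$posedit$edit$ter, as.integer(stop_rel))
    }
    n_done <- n_done + 1
  }
})
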