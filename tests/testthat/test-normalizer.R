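test_that("allele trimming removes shared bases and adjusts the interval", {
  expect_identical(trim_alleles("TTT", "TT", c(3, 5)),
                   list(ref = "T", alt = "", interval = c(5L, 5L)))
  expect_identical(trim_alleles("TT", "T", c(3, 4)),
                   list(ref = "T", alt = "", interval = c(4L, 4L)))
  tr <- trim_alleles("A", "A", c(2, 2))
  expect_identical(tr$ref, "")
  expect_identical(tr$alt, "")
  expect_identical(tr$interval, c(2L, 2L)) # identity keeps its interval
  # trimmed alleles never share a prefix or suffix
  set.seed(21)
  for (i in 1:200) {
    ref <- random_nt(sample(0:6, 1))
    alt <- random_nt(sample(0:6, 1))
    if (!nzchar(ref) && !nzchar(alt)) next
    s <- sample(50, 1)
    tr <- trim_alleles(ref, alt, c(s, s + max(nchar(ref) - 1, 1)))
    if (nzchar(tr$ref) && nzchar(tr$alt)) {
      expect_false(substr(tr$ref, 1, 1) == substr(tr$alt, 1, 1))
      expect_false(substr(tr$ref, nchar(tr$ref), nchar(tr$ref)) ==
                     substr(tr$alt, nchar(tr$alt), nchar(tr$alt)))
    }
  }
})

test_that("3' shifting finds the rightmost equivalent placement", {
  expect_identical(shift_3prime("T", "", c(3, 3), "GCTTTA")$interval, c(5L, 5L))
  # insertion already 3'-most stays put (rewriting handles the dup form)
  sh <- shift_3prime("", "A", c(4, 5), "GCTA")
  expect_identical(sh$interval, c(4L, 5L))
  # homopolymer shifting stops at the window edge
  sh <- shift_3prime("A", "", c(2, 2), "CAAAAAAC", whi = 5L)
  expect_identical(sh$interval, c(5L, 5L))
  # shifted placement denotes the same altered sequence
  set.seed(22)
  for (i in 1:200) {
    seq <- random_nt(40)
    s <- sample(30, 1)
    w <- sample(1:3, 1)
    del0 <- apply_edit(seq, c(s, s + w - 1), hgvs_edit("del"))
    sh <- shift_3prime(substr(seq, s, s + w - 1), "", c(s, s + w - 1), seq)
    del1 <- apply_edit(seq, sh$interval, hgvs_edit("del"))
    expect_identical(del0, del1)
  }
})

test_that("rewriting emits the highest-priority edit type", {
  rw <- rewrite_edit("", "A", c(4, 5), "GCTA")
  expect_identical(rw$edit$kind, "dup")
  expect_equal(rw$interval, c(4, 4))
  expect_identical(rewrite_edit("CA", "TG", c(2, 3), "GCAT")$edit$kind, "inv")
  expect_identical(rewrite_edit("A", "G", c(2, 2), "GACT")$edit$kind, "sub")
  expect_identical(rewrite_edit("AC", "", c(2, 3), "GACT")$edit$kind, "del")
  expect_identical(rewrite_edit("", "TT", c(2, 3), "GACT")$edit$kind, "ins")
  expect_identical(rewrite_edit("AC", "GTT", c(2, 3), "GACT")$edit$kind, "delins")
  expect_identical(rewrite_edit("", "", c(2, 2), "GACT")$edit$kind, "identity")
})

test_that("the single-T deletion equivalence class converges to one form", {
  p <- toy_provider()
  forms <- c("T1:g.3delT", "T1:g.4delT", "T1:g.5delT",
             "T1:g.3_5delTTTinsTT", "T1:g.3_4delTTinsT")
  out <- vapply(forms, function(s) format_hgvs(normalize_variant(parse_hgvs(s), p)), "")
  expect_true(all(out == "T1:g.5del"))
})

test_that("an insertion equal to the preceding base becomes a duplication", {
  p <- toy_provider()
  expect_identical(format_hgvs(normalize_variant(parse_hgvs("T2:g.4_5insA"), p)),
                   "T2:g.4dup")
})

test_that("a duplication right-shifts by the shared prefix of its trailing sequence", {
  gs <- paste0(strrep("N", 32417910), "ACCGTACAAG", strrep("N", 40))
  p <- fixture_bundle(sequences = c(NC_900011.1 = gs))
  v <- normalize_variant(parse_hgvs("NC_900011.1:g.32417911_32417915dup"), p)
  expect_identical(v$posedit$interval$start$base, 32417913L)
  expect_identical(v$posedit$interval$end$base, 32417917L)
  expect_identical(v$posedit$edit$kind, "dup")
})

test_that("trimming to nothing yields an identity variant over the original interval", {
  p <- toy_provider()
  v <- normalize_variant(parse_hgvs("T1:g.2_3delCTinsCT"), p)
  expect_identical(format_hgvs(v), "T1:g.2_3=")
  # a substitution whose alt equals the reference also collapses
  v2 <- normalize_variant(parse_hgvs("T1:g.2C>C"), p)
  expect_identical(v2$posedit$edit$kind, "identity")
})

test_that("normalization is boundary-aware for transcript variants", {
  p <- hand_tx_plus()
  rec <- get_transcript(p, "NM_000001.1")
  txseq <- get_seq(p, "NM_000001.1")
  # deletion of the last exon-1 base whose genomic 3' neighbour (the intron
  # start) matches: on the transcript the window stops at the junction
  b <- 30L # last base of exon 1 (n.30 == c.20)
  vn <- variant("NM_000001.1", "n",
                posedit(bo_interval(bo_pos(b)), hgvs_edit("del")))
  out <- normalize_variant(vn, p)
  ib <- c(out$posedit$interval$start$base, out$posedit$interval$end$base)
  expect_lte(ib[2], 30L) # never shifted into exon 2's transcript bases
  # with cross_boundaries the same variant may travel further
  out2 <- normalize_variant(vn, p, normalizer_config(cross_boundaries = TRUE))
  expect_s3_class(out2, "hgvs_variant")
  # boundary-adjacent seeding never yields a junction-straddling interval
  set.seed(23)
  for (i in 1:200) {
    off <- sample(-2:0, 1)
    b <- 30L + off
    kind <- sample(c("del", "dup"), 1)
    vv <- variant("NM_000001.1", "n",
                  posedit(bo_interval(bo_pos(b)), hgvs_edit(kind)))
    ov <- normalize_variant(vv, p)
    s <- ov$posedit$interval$start$base
    e <- ov$posedit$interval$end$base
    expect_true((s <= 30 && e <= 30) || (s >= 31 && e >= 31))
  }
})

test_that("intronic variants are normalized in genomic context when available", {
  p <- hand_tx_plus()
  # intron starts GTAAGT...: deleting the first A (c.20+3) can shift 3' to c.20+4
  v <- parse_hgvs("NM_000001.1:c.20+3del")
  out <- normalize_variant(v, p)
  expect_identical(out$posedit$interval$start$offset, 4L)
  # without genomic context the variant is returned unchanged with a notice
  p2 <- p
  p2$sequences <- p2$sequences[names(p2$sequences) != "NC_000900.1"]
  out2 <- normalize_variant(v, p2)
  expect_identical(format_hgvs(out2), format_hgvs(v))
  expect_false(is.null(attr(out2, "notice")))
})

test_that("conversion and repeat edits pass through with a notice", {
  p <- toy_provider()
  for (s in c("T1:g.1_2conT1:g.4_5", "T1:g.3TA[4]")) {
    v <- parse_hgvs(s)
    out <- normalize_variant(v, p)
    expect_identical(format_hgvs(out), s)
    expect_false(is.null(attr(out, "notice")))
  }
})

test_that("5' mode shifts toward the sequence start", {
  p <- toy_provider()
  out <- normalize_variant(parse_hgvs("T1:g.5delT"), p,
                           normalizer_config(shift_direction = "5p"))
  expect_identical(out$posedit$interval$start$base, 3L)
})

test_that("normalization refuses intrinsically invalid input and bad references", {
  p <- toy_provider()
  expect_error(normalize_variant(parse_hgvs("T1:g.5_3del"), p),
               class = "hgvs_validation_error")
  expect_error(normalize_variant(parse_hgvs("T1:g.3delA"), p),
               class = "hgvs_ref_mismatch_error")
})

test_that("normalization is idempotent and allele-preserving on random variants", {
  fx <- generate_fixture(seed = 41)
  p <- fx$provider
  set.seed(42)
  n_done <- 0
  while (n_done < 300) {
    if (runif(1) < 0.4) { # genomic variants
      G <- get_seq(p, "NC_900001.9")
      b <- sample(nchar(G) - 10, 1)
      kind <- sample(c("sub", "del", "ins", "dup", "delins"), 1)
      e <- switch(kind,
        sub = {
          r <- substr(G, b, b)
          hgvs_edit("sub", ref = r, alt = sample(setdiff(BASES, r), 1))
        },
        del = hgvs_edit("del"), dup = hgvs_edit("dup"),
        ins = hgvs_edit("ins", alt = random_nt(2)),
        delins = hgvs_edit("delins", alt = random_nt(3)))
      iv <- if (kind == "ins") bo_interval(bo_pos(b), bo_pos(b + 1))
            else if (kind == "sub") bo_interval(bo_pos(b))
            else bo_interval(bo_pos(b), bo_pos(b + sample(0:3, 1)))
      v <- variant("NC_900001.9", "g", posedit(iv, e))
      seq <- G
    } else {
      tx_ac <- sample(names(p$transcripts), 1)
      v <- random_tx_variant(p, fx$truth, tx_ac)
      if (is.null(v)) next
      seq <- get_seq(p, tx_ac)
    }
    v1 <- tryCatch(normalize_variant(v, p), error = function(e) e)
    if (inherits(v1, "error")) next # e.g. random interval ran out of bounds
    v2 <- normalize_variant(v1, p)
    expect_identical(format_hgvs(v1), format_hgvs(v2))
    expect_identical(apply_variant_seq(v, seq), apply_variant_seq(v1, seq))
    n_done <- n_done + 1
  }
})
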