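#' Generate a synthetic fixture bundle
#'
#' Builds a deterministic (seeded) random genome carrying multi-exon genes on
#' both strands, with optional transcript-genome alignment discrepancies:
#' `TI` gaps (transcript bases absent from the genome), `GI` gaps (genome
#' bases absent from the transcript) and `X` substitution discrepancies, the
#' three kinds of gapped-alignment features observed between curated
#' transcripts and assemblies. Coding transcripts get a clean ORF (ATG start,
#' terminal stop, no internal stop) so protein consequence prediction behaves
#' as on real transcripts. One gene receives a second, sequence-identical
#' genomic placement on a separate accession, emulating a pseudoautosomal
#' (PAR) dual placement; when at least one gene has three or more exons, an
#' additional non-coding isoform sharing a subset of its exons is emitted so
#' that overlapping-transcript queries have a target.
#'
#' Every injected feature is reported in the returned truth table so tests
#' can aim variants at (or away from) gap neighborhoods.
#'
#' @param seed integer; the same seed reproduces a bit-identical bundle.
#' @param n_genes number of genes.
#' @param exon_count_range,exon_len_range,intron_len_range integer ranges
#'   (length-2) for exons per gene, exon genomic length, intron length.
#' @param gap_spec list with `n_tx_ins`, `n_genome_ins`, `len_range`: how
#'   many alignment indel gaps of each kind to inject, and their lengths.
#' @param snp_spec list with `n`: how many single-base substitution
#'   discrepancies to inject.
#' @param include_par place the last gene on a second genomic accession as
#'   well (dual placement).
#' @return list with `provider` (an [fixture_bundle()]) and `truth`
#'   (data.frame: `tx_ac`, `kind` in `tx_ins`/`genome_ins`/`mismatch`,
#'   `exon`, interbase `tx_start`/`tx_end`/`g_start`/`g_end`, `len`,
#'   `content`).
#' @examples
#' fx <- generate_fixture(seed = 1, n_genes = 2)
#' names(fx$provider$transcripts)
#' @export
generate_fixture <- function(seed,
                             n_genes = 4L,
                             exon_count_range = c(2L, 5L),
                             exon_len_range = c(90L, 240L),
                             intron_len_range = c(60L, 200L),
                             gap_spec = list(n_tx_ins = 2L, n_genome_ins = 2L, len_range = c(1L, 4L)),
                             snp_spec = list(n = 3L),
                             include_par = TRUE) {
  if (exon_len_range[1L] < 30L) stop_data("exon_len_range too small for gap injection margins")
  if (intron_len_range[1L] < 10L) stop_data("intron_len_range must allow introns of at least 10 bases")
  set.seed(as.integer(seed))
  g_ac <- "NC_900001.9"
  y_ac <- "NC_900024.1"

  rint <- function(rng) if (rng[1L] >= rng[2L]) rng[1L] else sample(rng[1L]:rng[2L], 1L)

  genes <- list()
  cursor <- rint(c(200L, 400L))
  for (gi in seq_len(n_genes)) {
    n_ex <- rint(exon_count_range)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(exon_len_range), 0L)
    in_len <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L), function(i) rint(intron_len_range), 0L) else integer()
    g_start <- integer(n_ex)
    p <- cursor
    for (i in seq_len(n_ex)) {
      g_start[i] <- p
      p <- p + ex_len[i] + if (i < n_ex) in_len[i] else 0L
    }
    cursor <- p + rint(c(250L, 500L))
    strand <- sample(c(1L, -1L), 1L)
    # exon column-op vectors, transcript order; start as all-match
    ord <- if (strand > 0L) seq_len(n_ex) else rev(seq_len(n_ex))
    ops <- lapply(ord, function(i) rep("M", ex_len[i]))
    genes[[gi]] <- list(
      idx = gi, strand = strand, n_ex = n_ex,
      g_start = g_start[ord], g_end = (g_start + ex_len)[ord],
      ops = ops
    )
  }
  genome_len <- cursor + rint(c(300L, 600L))

  # inject alignment features into random coding genes, away from exon edges
  truth_plan <- list()
  inject <- function(kind, len) {
    for (attempt in 1:200) {
      gi <- rint(c(1L, n_genes))
      ei <- rint(c(1L, genes[[gi]]$n_ex))
      op <- genes[[gi]]$ops[[ei]]
      lo <- 8L
      hi <- length(op) - 8L - (if (kind == "genome_ins") len else 0L)
      if (hi <= lo) next
      k <- rint(c(lo, hi))
      span <- if (kind == "tx_ins") k else k:(k + len - 1L)
      # keep features isolated: require an all-M margin around the site
      ctx <- max(1L, min(span) - 3L):min(length(op), max(span) + 3L)
      if (!all(op[ctx] == "M")) next
      if (kind == "tx_ins") {
        op <- append(op, rep("TI", len), after = k)
      } else if (kind == "genome_ins") {
        op[span] <- "GI"
      } else {
        op[k] <- "X"
      }
      genes[[gi]]$ops[[ei]] <<- op
      truth_plan[[length(truth_plan) + 1L]] <<- list(gene = gi, exon = ei, kind = kind, len = len)
      return(invisible(NULL))
    }
    stop_data("could not place an alignment feature; enlarge exons or reduce gap_spec")
  }
  for (j in seq_len(gap_spec$n_tx_ins %||% 0L)) inject("tx_ins", rint(gap_spec$len_range))
  for (j in seq_len(gap_spec$n_genome_ins %||% 0L)) inject("genome_ins", rint(gap_spec$len_range))
  for (j in seq_len(snp_spec$n %||% 0L)) inject("mismatch", 1L)

  genome <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  orient <- function(strand, b) if (strand > 0L) b else chartr("ACGT", "TGCA", b)

  # assemble records + transcript sequences
  transcripts <- list()
  sequences <- character()
  assoc <- data.frame(tx_ac = character(), pro_ac = character(), g_ac = character())
  overrides_all <- list()

  make_record <- function(tx_ac, gene, keep = NULL) {
    gn <- genes[[gene]]
    keep <- keep %||% seq_len(gn$n_ex)
    segs <- lapply(gn$ops[keep], function(op) {
      r <- rle(op)
      data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
    })
    tx_lens <- vapply(gn$ops[keep], function(op) sum(op %in% c("M", "X", "TI")), 0L)
    tx_end <- cumsum(tx_lens)
    list(
      tx_ac = tx_ac, gene = paste0("GENE", gene), strand = gn$strand, g_ac = g_ac,
      exons = data.frame(tx_start = c(0L, tx_end[-length(tx_end)]), tx_end = tx_end,
                         g_start = gn$g_start[keep], g_end = gn$g_end[keep]),
      segments = segs, cds_start = NA_integer_, cds_end = NA_integer_, alt = NULL
    )
  }

  build_seq <- function(rec, ovr) {
    out <- character(nrow(rec$exons))
    for (i in seq_len(nrow(rec$exons))) {
      cols <- exon_columns(rec, i)
      b <- character(cols$K)
      gidx <- !is.na(cols$gpos) & cols$op %in% c("M")
      b[gidx] <- orient(rec$strand, genome[cols$gpos[gidx] + 1L])
      oi <- ovr[[i]]
      if (length(oi)) b[as.integer(names(oi))] <- oi
      out[i] <- paste0(b[cols$op %in% c("M", "X", "TI")], collapse = "")
    }
    paste0(out, collapse = "")
  }

  # set transcript base t0 (interbase) to `base`, editing genome (M), the
  # override table (X/TI); X columns keep the discrepancy by nudging the
  # genome base away when it would coincide
  set_tx_base <- function(rec, ovr, t0, base) {
    i <- exon_containing_tx(rec, t0, t0 + 1L)
    cols <- exon_columns(rec, i)
    k <- which(!is.na(cols$txpos) & cols$txpos == t0)
    op <- cols$op[k]
    if (op == "M") {
      genome[cols$gpos[k] + 1L] <<- orient(rec$strand, base)
    } else {
      ovr[[i]][as.character(k)] <- base
      if (op == "X" && orient(rec$strand, genome[cols$gpos[k] + 1L]) == base) {
        genome[cols$gpos[k] + 1L] <<- orient(rec$strand, setdiff(c("A", "C", "G", "T"), base)[1L])
      }
    }
    ovr
  }

  for (gi in seq_len(n_genes)) {
    tx_ac <- sprintf("NM_9001%02d.1", gi)
    rec <- make_record(tx_ac, gi)
    # seed overrides for X and TI columns
    ovr <- vector("list", nrow(rec$exons))
    for (i in seq_len(nrow(rec$exons))) {
      cols <- exon_columns(rec, i)
      o <- character()
      for (k in which(cols$op == "X")) {
        gbase <- orient(rec$strand, genome[cols$gpos[k] + 1L])
        o[as.character(k)] <- sample(setdiff(c("A", "C", "G", "T"), gbase), 1L)
      }
      for (k in which(cols$op == "TI")) {
        o[as.character(k)] <- sample(c("A", "C", "G", "T"), 1L)
      }
      ovr[[i]] <- o
    }
    # choose CDS and enforce a clean ORF
    txlen <- tx_length(rec)
    utr5 <- rint(c(15L, 40L))
    utr3 <- rint(c(15L, 40L))
    cds_len <- 3L * ((txlen - utr5 - utr3) %/% 3L)
    if (cds_len < 30L) stop_data("transcript too short for a CDS; enlarge exon lengths")
    rec$cds_start <- utr5
    rec$cds_end <- utr5 + cds_len
    for (iter in 1:12) {
      s <- build_seq(rec, ovr)
      cds <- substr_ib(s, rec$cds_start, rec$cds_end)
      fixes <- list()
      if (substr(cds, 1L, 3L) != "ATG") fixes <- c(fixes, list(c(0L, NA)))
      aa <- translate_nt(cds)
      stops <- which(strsplit(aa, "")[[1L]] == "*")
      n_codon <- nchar(aa)
      if (!n_codon %in% stops) fixes <- c(fixes, list(c(n_codon - 1L, NA)))
      for (sc in setdiff(stops, n_codon)) fixes <- c(fixes, list(c(sc - 1L, NA)))
      if (length(fixes) == 0L) break
      # first fix only per pass (fixes can interact through shared genome)
      codon0 <- fixes[[1L]][1L]
      target <- if (codon0 == 0L) "ATG" else if (codon0 == n_codon - 1L) "TAA" else {
        cd <- substr_ib(cds, codon0 * 3L, codon0 * 3L + 3L)
        substr(cd, 3L, 3L) <- "C" # recode third base: breaks TAA/TAG/TGA
        cd
      }
      for (j in 1:3) {
        ovr <- set_tx_base(rec, ovr, rec$cds_start + codon0 * 3L + j - 1L,
                           substr(target, j, j))
      }
    }
    s <- build_seq(rec, ovr)
    transcripts[[tx_ac]] <- rec
    sequences[[tx_ac]] <- s
    overrides_all[[tx_ac]] <- ovr
    pro_ac <- sprintf("NP_9001%02d.1", gi)
    prot <- translate_nt(substr_ib(s, rec$cds_start, rec$cds_end))
    prot <- sub("\\*$", "", prot)
    sequences[[pro_ac]] <- prot
    assoc <- rbind(assoc, data.frame(tx_ac = tx_ac, pro_ac = pro_ac, g_ac = g_ac))
  }

  # non-coding isoform of the first gene with >= 3 exons (middle exon dropped)
  iso_src <- which(vapply(genes, `[[`, 0L, "n_ex") >= 3L)
  if (length(iso_src)) {
    gi <- iso_src[1L]
    keep <- setdiff(seq_len(genes[[gi]]$n_ex), 2L)
    tx_ac <- "NR_900201.1"
    rec <- make_record(tx_ac, gi, keep = keep)
    src_ovr <- overrides_all[[sprintf("NM_9001%02d.1", gi)]][keep]
    sequences[[tx_ac]] <- build_seq(rec, src_ovr)
    transcripts[[tx_ac]] <- rec
    assoc <- rbind(assoc, data.frame(tx_ac = tx_ac, pro_ac = NA_character_, g_ac = g_ac))
  }

  genome_str <- paste0(genome, collapse = "")
  sequences[[g_ac]] <- genome_str

  # PAR-like dual placement: copy the last gene's locus onto a second
  # accession; the copied region is sequence-identical, so both placements
  # satisfy the alignment
  if (include_par) {
    gn <- genes[[n_genes]]
    lo <- min(gn$g_start) - 50L
    hi <- max(gn$g_end) + 50L
    y_off <- 150L
    y_len <- (hi - lo) + y_off + 250L
    y <- sample(c("A", "C", "G", "T"), y_len, replace = TRUE)
    y[(y_off + 1L):(y_off + hi - lo)] <- genome[(lo + 1L):hi]
    sequences[[y_ac]] <- paste0(y, collapse = "")
    tx_ac <- sprintf("NM_9001%02d.1", n_genes)
    shift <- y_off - lo
    transcripts[[tx_ac]]$alt <- list(
      g_ac = y_ac,
      exons = data.frame(g_start = transcripts[[tx_ac]]$exons$g_start + shift,
                         g_end = transcripts[[tx_ac]]$exons$g_end + shift)
    )
  }

  provider <- fixture_bundle(sequences = sequences, transcripts = transcripts,
                             associations = assoc)

  # derive the truth table from the final records
  truth <- list()
  for (tx_ac in names(transcripts)) {
    rec <- transcripts[[tx_ac]]
    for (i in seq_len(nrow(rec$exons))) {
      cols <- exon_columns(rec, i)
      r <- rle(cols$op)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values %in% c("X", "TI", "GI"))) {
        ks <- starts[j] - 1L # boundary before the run
        ke <- ends[j]
        kind <- c(X = "mismatch", TI = "tx_ins", GI = "genome_ins")[[r$values[j]]]
        content <- if (r$values[j] == "GI") {
          substr_ib(sequences[[rec$g_ac]], min(cols$gb[ks + 1L], cols$gb[ke + 1L]),
                    max(cols$gb[ks + 1L], cols$gb[ke + 1L]))
        } else {
          substr_ib(sequences[[tx_ac]], cols$txb[ks + 1L], cols$txb[ke + 1L])
        }
        truth[[length(truth) + 1L]] <- data.frame(
          tx_ac = tx_ac, kind = kind, exon = i,
          tx_start = cols$txb[ks + 1L], tx_end = cols$txb[ke + 1L],
          g_start = min(cols$gb[ks + 1L], cols$gb[ke + 1L]),
          g_end = max(cols$gb[ks + 1L], cols$gb[ke + 1L]),
          len = r$lengths[j], content = content, stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tx_ac = character(), kind = character(), exon = integer(),
               tx_start = integer(), tx_end = integer(), g_start = integer(),
               g_end = integer(), len = integer(), content = character())

  list(provider = provider, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
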