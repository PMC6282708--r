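#' Predict the protein consequence of a coding variant
#'
#' Applies the edit to the CDS, translates the original and altered reading
#' frames (reading on into the 3' UTR for frameshifts until a stop is met)
#' and emits the protein-level description: synonymous (`p.(Xaa#=)`),
#' substitution, in-frame deletion/insertion/duplication/delins, frameshift
#' (`p.(Xaa#YaafsTer#)`, the stop counted with the first changed residue as
#' 1), stop-gain, or stop-loss extension (`ext`, an experimental notation
#' here). The result is a prediction and is therefore marked uncertain
#' (printed in parentheses). Variants whose consequence cannot be computed
#' from the CDS -- intronic, UTR-only, or touching the initiator codon --
#' return `p.?` rather than raising.
#'
#' @param v an `hgvs_variant` of type `c` on a coding transcript.
#' @param provider data provider (transcript + protein sequences,
#'   associations).
#' @return an `hgvs_variant` of type `p` on the associated protein
#'   accession.
#' @export
c_to_p <- function(v, provider) {
  stopifnot(v$type == "c")
  rec <- get_transcript(provider, v$ac)
  if (is.na(rec$cds_start)) {
    stop_coord(sprintf("%s has no CDS; protein consequences are undefined", rec$tx_ac))
  }
  pro_ac <- protein_ac_for(provider, v$ac)
  iv <- v$posedit$interval
  unknown <- function() variant(pro_ac, "p", posedit(NULL, p_edit("unknown")))
  if (iv$start$offset != 0L || iv$end$offset != 0L) return(unknown())

  vn <- c_to_n(v, rec)
  ib <- nt_interval_ib(vn)
  cs <- rec$cds_start
  ce <- rec$cds_end
  if (ib[2L] <= cs || ib[1L] >= ce) return(unknown()) # UTR-only
  if (ib[1L] < cs) return(unknown())                  # touches the initiator region

  txseq <- get_seq(provider, rec$tx_ac)
  al <- materialize_alleles(txseq, ib[1L], ib[2L], vn$posedit$edit)
  ref_tail <- substr_ib(txseq, cs, nchar(txseq))
  alt_tail <- paste0(substr_ib(txseq, cs, ib[1L]), al$alt, substr_ib(txseq, ib[2L], nchar(txseq)))
  r <- cut_at_stop(translate_nt(ref_tail))
  a <- cut_at_stop(translate_nt(alt_tail))

  if (identical(r, a)) { # synonymous
    c0 <- (ib[1L] - cs) %/% 3L + 1L
    aa <- substr(r, c0, c0)
    pp <- p_pos(aa, c0)
    return(variant(pro_ac, "p",
                   posedit(p_interval(pp), p_edit("identity"), uncertain = TRUE)))
  }
  i <- first_diff(r, a)
  if (i == 1L) return(unknown()) # initiator residue affected
  frameshift <- (nchar(al$alt) - (ib[2L] - ib[1L])) %% 3L != 0L
  if (frameshift) {
    R <- substr(r, i, i)
    A <- substr(a, i, i)
    if (!nzchar(R)) R <- "*" # ran off the reference protein end
    if (A == "*") { # frameshift lands straight on a stop: a nonsense change
      return(variant(pro_ac, "p",
                     posedit(p_interval(p_pos(R, i)), p_edit("sub", alt = "*"), uncertain = TRUE)))
    }
    stop_at <- regexpr("*", substr(a, i, nchar(a)), fixed = TRUE)[1L]
    ter <- if (stop_at > 0L) as.integer(stop_at) else NA_integer_
    return(variant(pro_ac, "p",
                   posedit(p_interval(p_pos(R, i)), p_edit("fs", alt = A, ter = ter),
                           uncertain = TRUE)))
  }
  # in-frame
  R <- substr(r, i, i)
  A <- substr(a, i, i)
  if (A == "*" && R != "*") { # stop gain truncates the protein
    return(variant(pro_ac, "p",
                   posedit(p_interval(p_pos(R, i)), p_edit("sub", alt = "*"), uncertain = TRUE)))
  }
  if (R == "*") { # stop-loss: extension into the 3' UTR frame
    stop_at <- regexpr("*", substr(a, i, nchar(a)), fixed = TRUE)[1L]
    ter <- if (stop_at > 0L) as.integer(stop_at) - 1L else NA_integer_
    return(variant(pro_ac, "p",
                   posedit(p_interval(p_pos("*", i)), p_edit("ext", alt = A, ter = ter),
                           uncertain = TRUE)))
  }
  if (nchar(r) == nchar(a)) {
    j <- last_diff(r, a)
    if (i == j) { # single-residue substitution (possibly to Ter)
      return(variant(pro_ac, "p",
                     posedit(p_interval(p_pos(R, i)), p_edit("sub", alt = A), uncertain = TRUE)))
    }
  }
  # in-frame indel: trim protein alleles and classify
  p <- common_prefix_len(r, a)
  s <- common_suffix_len(substr(r, p + 1L, nchar(r)), substr(a, p + 1L, nchar(a)))
  ref_core <- substr(r, p + 1L, nchar(r) - s)
  alt_core <- substr(a, p + 1L, nchar(a) - s)
  if (!nzchar(alt_core)) {
    ivp <- p_interval(p_pos(substr(r, p + 1L, p + 1L), p + 1L),
                      p_pos(substr(r, nchar(r) - s, nchar(r) - s), nchar(r) - s))
    return(variant(pro_ac, "p", posedit(ivp, p_edit("del"), uncertain = TRUE)))
  }
  if (!nzchar(ref_core)) {
    la <- nchar(alt_core)
    if (p - la >= 0L && substr(r, p - la + 1L, p) == alt_core) {
      ivp <- p_interval(p_pos(substr(r, p - la + 1L, p - la + 1L), p - la + 1L),
                        p_pos(substr(r, p, p), p))
      if (la == 1L) ivp <- p_interval(ivp$start)
      return(variant(pro_ac, "p", posedit(ivp, p_edit("dup"), uncertain = TRUE)))
    }
    ivp <- p_interval(p_pos(substr(r, p, p), p), p_pos(substr(r, p + 1L, p + 1L), p + 1L))
    return(variant(pro_ac, "p", posedit(ivp, p_edit("ins", alt = alt_core), uncertain = TRUE)))
  }
  ivp <- if (nchar(ref_core) == 1L) {
    p_interval(p_pos(ref_core, p + 1L))
  } else {
    p_interval(p_pos(substr(ref_core, 1L, 1L), p + 1L),
               p_pos(substr(ref_core, nchar(ref_core), nchar(ref_core)), nchar(r) - s))
  }
  variant(pro_ac, "p", posedit(ivp, p_edit("delins", alt = alt_core), uncertain = TRUE))
}

protein_ac_for <- function(provider, tx_ac) {
  a <- provider$associations
  hit <- a$pro_ac[a$tx_ac == tx_ac]
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1L] else paste0(tx_ac, ":protein")
}

cut_at_stop <- function(aa) {
  k <- regexpr("*", aa, fixed = TRUE)[1L]
  if (k > 0L) substr(aa, 1L, k) else aa
}

first_diff <- function(a, b) {
  p <- common_prefix_len(a, b)
  p + 1L
}

last_diff <- function(a, b) {
  s <- common_suffix_len(a, b)
  max(nchar(a), nchar(b)) - s
}
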