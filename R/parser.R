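#' Parse an HGVS variant description
#'
#' Converts a single-variant HGVS string (`"<accession>:<type>.<posedit>"`)
#' into a structured [variant()]. The grammar covers substitution, deletion,
#' insertion, deletion-insertion, duplication, inversion, conversion, identity
#' and repeated-sequence edits on `g.`/`m.`/`n.`/`c.` references, and
#' substitution, synonymous, deletion, insertion, duplication,
#' deletion-insertion, frameshift and extension edits on `p.` references.
#' Alternatives are tried longest-match-first so `delins` is never split into
#' `del` + `ins`.
#'
#' Malformed strings raise an `hgvs_syntax_error` carrying the failing
#' character position. Descriptions that the nomenclature permits but this
#' package does not model -- uncertain positions (`(?_17019)`, `c.-227-?`),
#' compound/mosaic/chimeric alleles -- raise the distinct
#' `hgvs_unsupported_error`.
#'
#' @param s an HGVS string, e.g. `"NM_000059.3:c.201_202dupGA"`.
#' @return an `hgvs_variant`.
#' @examples
#' parse_hgvs("NM_000016.5:c.387+32C>G")
#' parse_hgvs("NC_000008.11:g.89955482_89955483invCA")
#' @export
parse_hgvs <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop_syntax("input must be a single character string", 1L)
  }
  if (grepl("[[:space:]]", s)) {
    stop_syntax("whitespace is not permitted in a variant description",
                regexpr("[[:space:]]", s)[1L])
  }
  colon <- regexpr(":", s, fixed = TRUE)[1L]
  if (colon < 0L) stop_syntax("missing ':' between accession and position", nchar(s))
  ac <- substr(s, 1L, colon - 1L)
  if (!grepl("^[A-Za-z][A-Za-z0-9_.-]*$", ac)) {
    stop_syntax(sprintf("malformed accession '%s'", ac), 1L)
  }
  rest <- substr(s, colon + 1L, nchar(s))
  m <- regexec("^([gmncp])\\.(.*)$", rest)[[1L]]
  if (m[1L] < 0L) stop_syntax("expected coordinate type prefix 'g.', 'm.', 'n.', 'c.' or 'p.'", colon + 1L)
  type <- regmatches(rest, list(m))[[1L]][2L]
  pe_str <- regmatches(rest, list(m))[[1L]][3L]
  pe_at <- colon + 3L # 1-based index of the first posedit character
  if (!nzchar(pe_str)) stop_syntax("empty position/edit", pe_at)

  check_unsupported(pe_str, type)

  pe <- if (type == "p") parse_p_posedit(pe_str, pe_at) else parse_nt_posedit(pe_str, type, pe_at)
  variant(ac, type, pe)
}

# descriptions recognized as valid nomenclature we deliberately do not model
check_unsupported <- function(pe_str, type) {
  if (grepl(";", pe_str, fixed = TRUE) || startsWith(pe_str, "[")) {
    stop_unsupported("compound/multi-variant alleles are not supported")
  }
  if (grepl("/", pe_str, fixed = TRUE)) {
    stop_unsupported("mosaic/chimeric descriptions are not supported")
  }
  if (type != "p") {
    if (grepl("?", pe_str, fixed = TRUE)) {
      stop_unsupported("uncertain positions are not supported")
    }
    if (grepl("^\\(|_\\(", pe_str)) {
      stop_unsupported("uncertain (parenthesized) positions are not supported")
    }
  }
}

NT <- "[ACGTURYSWKMBDHVNacgturyswkmbdhvn]"

# ---- nucleotide posedits ---------------------------------------------------

parse_nt_posedit <- function(str, type, at) {
  p1 <- parse_nt_pos(str, type, at)
  used <- p1$used
  rest <- substr(str, used + 1L, nchar(str))
  if (startsWith(rest, "_")) {
    p2 <- parse_nt_pos(substr(rest, 2L, nchar(rest)), type, at + used + 1L)
    used <- used + 1L + p2$used
    rest <- substr(str, used + 1L, nchar(str))
    iv <- bo_interval_unchecked(p1$pos, p2$pos)
  } else {
    iv <- bo_interval_unchecked(p1$pos, p1$pos)
  }
  e <- parse_nt_edit(rest, at + used)
  posedit(iv, e)
}

parse_nt_pos <- function(str, type, at) {
  pat <- switch(type,
    c = "^(\\*)?(-?[0-9]+)([+-][0-9]+)?",
    n = "^()([0-9]+)([+-][0-9]+)?",
    g = ,
    m = "^()([0-9]+)()"
  )
  m <- regexec(pat, str)[[1L]]
  if (m[1L] < 0L || attr(m, "match.length")[3L] == 0L) {
    stop_syntax("expected a position", at)
  }
  g <- regmatches(str, list(m))[[1L]]
  anchor <- if (identical(g[2L], "*")) "cds_end" else "cds_start"
  base <- suppressWarnings(as.integer(g[3L]))
  offset <- if (nzchar(g[4L])) as.integer(g[4L]) else 0L
  if (is.na(base) || base == 0L) stop_syntax("position base 0 does not exist", at)
  if (anchor == "cds_end" && base < 0L) stop_syntax("'*' positions cannot be negative", at)
  list(pos = bo_pos(base, offset, anchor), used = attr(m, "match.length")[1L])
}

parse_nt_edit <- function(str, at) {
  if (!nzchar(str)) stop_syntax("missing edit after position", at)
  if (str == "=") return(edit("identity"))

  # delins (before del so "del...ins..." is never split)
  m <- regexec(sprintf("^del((?:%s)+|[0-9]+)?ins(.*)$", NT), str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    alt <- g[3L]
    if (!grepl(sprintf("^(?:%s)+$", NT), alt)) {
      stop_syntax("deletion-insertion requires an explicit inserted sequence", at + 3L)
    }
    ref <- NA_character_
    ref_len <- NA_integer_
    if (nzchar(g[2L])) {
      if (grepl("^[0-9]+$", g[2L])) ref_len <- as.integer(g[2L]) else ref <- toupper(g[2L])
    }
    return(edit("delins", ref = ref, alt = toupper(alt), ref_len = ref_len))
  }

  for (kw in c("del", "dup", "inv")) {
    m <- regexec(sprintf("^%s((?:%s)+|[0-9]+)?$", kw, NT), str)[[1L]]
    if (m[1L] >= 0L) {
      g <- regmatches(str, list(m))[[1L]]
      ref <- NA_character_
      ref_len <- NA_integer_
      if (nzchar(g[2L])) {
        if (grepl("^[0-9]+$", g[2L])) ref_len <- as.integer(g[2L]) else ref <- toupper(g[2L])
      }
      return(edit(kw, ref = ref, ref_len = ref_len))
    }
  }

  if (startsWith(str, "ins")) {
    alt <- substr(str, 4L, nchar(str))
    if (grepl("^[0-9]+$", alt)) {
      stop_syntax("insertion requires an explicit sequence, not a length", at + 3L)
    }
    if (!grepl(sprintf("^(?:%s)+$", NT), alt)) {
      stop_syntax("malformed inserted sequence", at + 3L)
    }
    return(edit("ins", alt = toupper(alt)))
  }

  m <- regexec(sprintf("^(%s)>(%s)$", NT, NT), str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    return(edit("sub", ref = toupper(g[2L]), alt = toupper(g[3L])))
  }
  if (grepl(">", str, fixed = TRUE)) {
    stop_syntax("substitution requires exactly one base on each side of '>'", at)
  }

  if (startsWith(str, "con")) {
    src <- substr(str, 4L, nchar(str))
    if (!nzchar(src)) stop_syntax("conversion requires a source interval", at + 3L)
    return(edit("con", source = src))
  }

  # repeats: unit then an exact count "[n]" or a range "(min_max)"
  m <- regexec(sprintf("^((?:%s)+)\\[([0-9]+)\\]$", NT), str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    n <- as.integer(g[3L])
    return(edit("repeat", unit = toupper(g[2L]), rep_min = n, rep_max = n))
  }
  m <- regexec(sprintf("^((?:%s)+)\\(([0-9]+)_([0-9]+)\\)$", NT), str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    return(edit("repeat", unit = toupper(g[2L]),
                rep_min = as.integer(g[3L]), rep_max = as.integer(g[4L])))
  }

  stop_syntax(sprintf("unrecognized edit '%s'", str), at)
}

# ---- protein posedits ------------------------------------------------------

parse_p_posedit <- function(str, at) {
  uncertain <- FALSE
  if (startsWith(str, "(") && endsWith(str, ")")) {
    uncertain <- TRUE
    str <- substr(str, 2L, nchar(str) - 1L)
    at <- at + 1L
  }
  if (grepl("[()]", str)) stop_unsupported("nested/uncertain protein positions are not supported")
  if (str == "?") return(posedit(NULL, p_edit("unknown"), uncertain))
  if (str == "=") return(posedit(NULL, p_edit("identity"), uncertain))

  p1 <- parse_p_pos(str, at)
  used <- p1$used
  rest <- substr(str, used + 1L, nchar(str))
  iv <- p_interval(p1$pos)
  if (startsWith(rest, "_")) {
    p2 <- parse_p_pos(substr(rest, 2L, nchar(rest)), at + used + 1L)
    used <- used + 1L + p2$used
    rest <- substr(str, used + 1L, nchar(str))
    iv <- p_interval(p1$pos, p2$pos)
  }
  e <- parse_p_edit(rest, at + used)
  posedit(iv, e, uncertain)
}

# one residue + number, residue as 3-letter code, '*'/'Ter', or 1-letter
parse_p_pos <- function(str, at) {
  m <- regexec("^([A-Z][a-z]{2}|\\*|[A-Z])([0-9]+)", str)[[1L]]
  if (m[1L] < 0L) stop_syntax("expected an amino-acid position", at)
  g <- regmatches(str, list(m))[[1L]]
  aa <- p_token_to_1(g[2L], at)
  list(pos = p_pos(aa, as.integer(g[3L])), used = attr(m, "match.length")[1L])
}

p_token_to_1 <- function(tok, at) {
  if (tok == "*") return("*")
  if (nchar(tok) == 3L) {
    aa <- AA1[tok]
    if (is.na(aa)) stop_syntax(sprintf("unknown amino acid '%s'", tok), at)
    return(unname(aa))
  }
  if (!tok %in% c(names(AA3))) stop_syntax(sprintf("unknown amino acid '%s'", tok), at)
  tok
}

# a run of residues (all 3-letter or all 1-letter), to 1-letter string
parse_p_seq <- function(str, at) {
  if (grepl("^([A-Z][a-z]{2}|\\*)+$", str) && nchar(str) %% 3L == 0L || str == "*") {
    toks <- regmatches(str, gregexpr("[A-Z][a-z]{2}|\\*", str))[[1L]]
    if (sum(nchar(toks)) == nchar(str)) {
      return(paste0(vapply(toks, p_token_to_1, "", at = at), collapse = ""))
    }
  }
  if (grepl("^[A-Z*]+$", str)) {
    for (ch in strsplit(str, "")[[1L]]) p_token_to_1(ch, at)
    return(str)
  }
  stop_syntax(sprintf("malformed amino-acid sequence '%s'", str), at)
}

parse_p_edit <- function(str, at) {
  if (str == "=") return(p_edit("identity"))
  if (str == "del") return(p_edit("del"))
  if (str == "dup") return(p_edit("dup"))
  m <- regexec("^delins(.+)$", str)[[1L]]
  if (m[1L] >= 0L) {
    return(p_edit("delins", alt = parse_p_seq(regmatches(str, list(m))[[1L]][2L], at + 6L)))
  }
  m <- regexec("^ins(.+)$", str)[[1L]]
  if (m[1L] >= 0L) {
    return(p_edit("ins", alt = parse_p_seq(regmatches(str, list(m))[[1L]][2L], at + 3L)))
  }
  m <- regexec("^([A-Z][a-z]{2}|\\*|[A-Z])?fs(?:(?:Ter|\\*)([0-9]+|\\?))?$", str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    alt <- if (nzchar(g[2L])) p_token_to_1(g[2L], at) else NA_character_
    ter <- if (nzchar(g[3L]) && g[3L] != "?") as.integer(g[3L]) else NA_integer_
    return(p_edit("fs", alt = alt, ter = ter))
  }
  m <- regexec("^([A-Z][a-z]{2}|\\*|[A-Z])?ext(?:(?:Ter|\\*)([0-9]+|\\?))?$", str)[[1L]]
  if (m[1L] >= 0L) {
    g <- regmatches(str, list(m))[[1L]]
    alt <- if (nzchar(g[2L])) p_token_to_1(g[2L], at) else NA_character_
    ter <- if (nzchar(g[3L]) && g[3L] != "?") as.integer(g[3L]) else NA_integer_
    return(p_edit("ext", alt = alt, ter = ter))
  }
  m <- regexec("^([A-Z][a-z]{2}|\\*|[A-Z])$", str)[[1L]]
  if (m[1L] >= 0L) {
    return(p_edit("sub", alt = p_token_to_1(str, at)))
  }
  stop_syntax(sprintf("unrecognized protein edit '%s'", str), at)
}
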