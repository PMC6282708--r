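#' Formatter configuration
#'
#' Controls only how a variant prints, never what is stored.
#'
#' @param max_ref_length longest reference allele (deletions, duplications,
#'   inversions, and the deleted part of delins) that is still written out;
#'   `0` (the default) always suppresses it (`c.31_35del`), `Inf` always
#'   prints it. Declared-length refs (`del174`) follow the same rule.
#' @param p_3_letter print protein residues with 3-letter codes (default) or
#'   1-letter codes.
#' @param p_term_asterisk print the stop codon as `*` instead of `Ter` in
#'   3-letter mode (1-letter mode always uses `*`).
#' @return a `formatter_config` object.
#' @export
formatter_config <- function(max_ref_length = 0, p_3_letter = TRUE, p_term_asterisk = FALSE) {
  stopifnot(length(max_ref_length) == 1L, max_ref_length >= 0)
  structure(list(max_ref_length = max_ref_length,
                 p_3_letter = isTRUE(p_3_letter),
                 p_term_asterisk = isTRUE(p_term_asterisk)),
            class = "formatter_config")
}

#' Format a variant as an HGVS string
#'
#' Deterministic inverse of [parse_hgvs()] up to the configured display
#' settings; consults no external data.
#'
#' @param v an `hgvs_variant`.
#' @param config a [formatter_config()].
#' @return character scalar.
#' @examples
#' v <- parse_hgvs("NM_001166478.1:c.31_35delTTTTT")
#' format_hgvs(v)                                        # "NM_001166478.1:c.31_35del"
#' format_hgvs(v, formatter_config(max_ref_length = 10)) # ref printed again
#' @export
format_hgvs <- function(v, config = formatter_config()) {
  stopifnot(inherits(v, "hgvs_variant"))
  pe <- if (v$type == "p") fmt_p_posedit(v$posedit, config) else fmt_nt_posedit(v$posedit, v$type, config)
  paste0(v$ac, ":", v$type, ".", pe)
}

fmt_bo_pos <- function(p, type) {
  base <- if (type == "c" && p$anchor == "cds_end") paste0("*", p$base) else as.character(p$base)
  if (p$offset != 0L) paste0(base, sprintf("%+d", p$offset)) else base
}
format_bo_pos <- fmt_bo_pos # internal alias used in messages

fmt_nt_interval <- function(iv, type) {
  s <- fmt_bo_pos(iv$start, type)
  if (pos_eq(iv$start, iv$end)) s else paste0(s, "_", fmt_bo_pos(iv$end, type))
}

fmt_ref <- function(e, config) {
  if (!is.na(e$ref) && nzchar(e$ref) && nchar(e$ref) <= config$max_ref_length) return(e$ref)
  if (!is.na(e$ref_len) && e$ref_len <= config$max_ref_length) return(as.character(e$ref_len))
  ""
}

fmt_nt_posedit <- function(pe, type, config) {
  e <- pe$edit
  iv <- fmt_nt_interval(pe$interval, type)
  ed <- switch(e$kind,
    sub = paste0(e$ref, ">", e$alt),
    del = paste0("del", fmt_ref(e, config)),
    dup = paste0("dup", fmt_ref(e, config)),
    inv = paste0("inv", fmt_ref(e, config)),
    delins = paste0("del", fmt_ref(e, config), "ins", e$alt),
    ins = paste0("ins", e$alt),
    identity = "=",
    con = paste0("con", e$source),
    "repeat" = if (e$rep_min == e$rep_max) {
      paste0(e$unit, "[", e$rep_min, "]")
    } else {
      paste0(e$unit, "(", e$rep_min, "_", e$rep_max, ")")
    }
  )
  paste0(iv, ed)
}

# ---- protein ---------------------------------------------------------------

fmt_aa <- function(aa, config) {
  if (is.na(aa) || !nzchar(aa)) return("")
  if (!config$p_3_letter) return(aa)
  out <- vapply(strsplit(aa, "")[[1L]], function(ch) {
    if (ch == "*") {
      if (config$p_term_asterisk) "*" else "Ter"
    } else {
      unname(AA3[ch])
    }
  }, "")
  paste0(out, collapse = "")
}

fmt_p_pos <- function(p, config) paste0(fmt_aa(p$aa, config), p$pos)

fmt_p_posedit <- function(pe, config) {
  e <- pe$edit
  body <- if (is.null(pe$interval)) {
    switch(e$kind, unknown = "?", identity = "=",
           stop_coord("positionless protein edit must be '?' or '='"))
  } else {
    iv <- fmt_p_pos(pe$interval$start, config)
    if (!identical(pe$interval$start, pe$interval$end)) {
      iv <- paste0(iv, "_", fmt_p_pos(pe$interval$end, config))
    }
    term <- if (!config$p_3_letter || config$p_term_asterisk) "*" else "Ter"
    ed <- switch(e$kind,
      sub = fmt_aa(e$alt, config),
      identity = "=",
      del = "del",
      dup = "dup",
      ins = paste0("ins", fmt_aa(e$alt, config)),
      delins = paste0("delins", fmt_aa(e$alt, config)),
      fs = paste0(fmt_aa(e$alt, config), "fs",
                  if (!is.na(e$ter)) paste0(term, e$ter) else ""),
      ext = paste0(fmt_aa(e$alt, config), "ext",
                   if (!is.na(e$ter)) paste0(term, e$ter) else "")
    )
    paste0(iv, ed)
  }
  if (pe$uncertain) paste0("(", body, ")") else body
}
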