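#' Validation reports
#'
#' A validation run is an ordered series of criteria, each returning one of
#' three response levels: `VALID` (criterion satisfied), `ERROR` (criterion
#' violated) or `WARNING` (criterion cannot be evaluated -- e.g. an intronic
#' reference allele with no genomic context to check it against). The report
#' keeps every outcome with its message; `overall` is the maximum level.
#' This three-way scheme separates variants that are unambiguously valid,
#' plausibly valid, and unambiguously invalid.
#'
#' @param outcomes data.frame with columns `criterion`, `level`, `message`.
#' @return a `validation_report` with fields `outcomes` and `overall`.
#' @export
validation_report <- function(outcomes) {
  lv <- c(VALID = 0L, WARNING = 1L, ERROR = 2L)
  overall <- if (nrow(outcomes) == 0L) "VALID" else names(lv)[max(lv[outcomes$level]) + 1L]
  structure(list(outcomes = outcomes, overall = overall), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s>\n", x$overall))
  for (i in seq_len(nrow(x$outcomes))) {
    o <- x$outcomes[i, ]
    cat(sprintf("  [%s] %-3s %s\n", o$level, o$criterion, o$message))
  }
  invisible(x)
}

outcome <- function(criterion, level, message) {
  data.frame(criterion = criterion, level = level, message = message,
             stringsAsFactors = FALSE)
}

merge_reports <- function(...) {
  validation_report(do.call(rbind, lapply(list(...), function(r) {
    if (inherits(r, "validation_report")) r$outcomes else r
  })))
}

#' Report serialization for batch audits
#'
#' One JSON object per variant: `{"input": ..., "overall": ...,
#' "outcomes": [...]}`.
#' @param input the input string the report describes.
#' @param report a `validation_report`.
#' @return a JSON character scalar (one line).
#' @export
report_to_json <- function(input, report) {
  jsonlite::toJSON(list(input = input, overall = report$overall,
                        outcomes = report$outcomes),
                   auto_unbox = TRUE, na = "null")
}

# accession prefix families compatible with each coordinate type
AC_PREFIX_TYPES <- list(
  NC = c("g", "m"), NG = c("g", "m"), NT = c("g", "m"), NW = c("g", "m"),
  NM = c("n", "c"), NR = c("n"), NP = c("p")
)

#' Intrinsic validation
#'
#' Self-consistency checks requiring no external data, reported in order:
#' \describe{
#'   \item{i1}{interval start <= end under the position ordering;}
#'   \item{i2}{an insertion's interval spans exactly two adjacent positions
#'     (adjacency across an exon junction or the CDS/UTR seam cannot be
#'     decided intrinsically and yields WARNING);}
#'   \item{i3}{the accession prefix is appropriate for the coordinate type
#'     (unknown prefixes yield WARNING);}
#'   \item{i4}{a declared or explicit reference length equals the interval
#'     span (del/dup/inv/delins);}
#'   \item{i5}{edit arity matches its kind (a substitution covers one base).}
#' }
#'
#' @param v an `hgvs_variant`.
#' @param strict raise `hgvs_validation_error` when the report's overall
#'   level is WARNING or worse (default: always return the report).
#' @return a [validation_report()].
#' @export
validate_intrinsic <- function(v, strict = FALSE) {
  stopifnot(inherits(v, "hgvs_variant"))
  out <- list()
  iv <- v$posedit$interval
  e <- v$posedit$edit
  nt <- v$type %in% c("g", "m", "n", "c")

  # i1: ordering
  if (nt) {
    cmp <- compare_positions(iv$start, iv$end)
    out[[length(out) + 1L]] <- if (cmp > 0L) {
      outcome("i1", "ERROR", "interval start is after its end")
    } else outcome("i1", "VALID", "start <= end")
  } else if (!is.null(iv)) {
    out[[length(out) + 1L]] <- if (iv$start$pos > iv$end$pos) {
      outcome("i1", "ERROR", "interval start is after its end")
    } else outcome("i1", "VALID", "start <= end")
  }

  # i2: insertion flanks adjacent
  if (e$kind == "ins" && nt) {
    adj <- positions_adjacent(iv$start, iv$end)
    out[[length(out) + 1L]] <- if (isTRUE(adj)) {
      outcome("i2", "VALID", "insertion flanks are adjacent")
    } else if (is.na(adj)) {
      outcome("i2", "WARNING", "insertion flank adjacency cannot be evaluated intrinsically")
    } else {
      outcome("i2", "ERROR", "insertion interval must span exactly two adjacent positions")
    }
  }

  # i3: accession prefix vs type
  pre <- sub("^([A-Za-z]+)_.*$", "\\1", v$ac)
  known <- pre %in% names(AC_PREFIX_TYPES) && grepl("_", v$ac, fixed = TRUE)
  out[[length(out) + 1L]] <- if (!known) {
    outcome("i3", "WARNING", sprintf("accession family of '%s' is not recognized", v$ac))
  } else if (v$type %in% AC_PREFIX_TYPES[[pre]]) {
    outcome("i3", "VALID", "accession is appropriate for the variant type")
  } else {
    outcome("i3", "ERROR", sprintf("accession '%s' is not a %s. reference", v$ac, v$type))
  }

  # i4: declared/explicit ref length vs interval span
  if (nt && e$kind %in% c("del", "dup", "inv", "delins")) {
    span <- interval_span(iv)
    declared <- if (!is.na(e$ref_len)) e$ref_len
      else if (!is.na(e$ref) && nzchar(e$ref)) nchar(e$ref)
      else NA_integer_
    if (!is.na(declared)) {
      out[[length(out) + 1L]] <- if (is.na(span)) {
        outcome("i4", "WARNING", "interval span cannot be computed intrinsically")
      } else if (span != declared) {
        outcome("i4", "ERROR", sprintf("interval spans %d bases but the reference is declared as %d",
                                       span, declared))
      } else outcome("i4", "VALID", "declared reference length matches the interval span")
    }
  }

  # i5: edit arity
  if (nt && e$kind == "sub") {
    out[[length(out) + 1L]] <- if (!pos_eq(iv$start, iv$end)) {
      outcome("i5", "ERROR", "a substitution must address a single base")
    } else outcome("i5", "VALID", "edit arity matches its kind")
  }

  rep <- validation_report(do.call(rbind, out))
  if (strict && rep$overall != "VALID") {
    stop_validation(sprintf("strict intrinsic validation failed (%s)", rep$overall), report = rep)
  }
  rep
}

#' Extrinsic validation
#'
#' Checks against the data provider, run after intrinsic validation:
#' \describe{
#'   \item{e1}{the interval lies within the bounds of the reference sequence
#'     (and, for intronic positions with an alignment, within the intron);}
#'   \item{e2}{the stated reference allele matches the provider sequence
#'     (transcript sequence for exonic c./n., genome for g./m. and -- when an
#'     alignment and genomic sequence exist -- for intronic positions;
#'     protein sequence for p.);}
#'   \item{e3}{an intronic transcript variant with no genomic context cannot
#'     be checked and yields WARNING.}
#' }
#'
#' @param v an `hgvs_variant` (intrinsically valid).
#' @param provider data provider.
#' @param strict raise on overall WARNING or worse.
#' @return a [validation_report()].
#' @export
validate_extrinsic <- function(v, provider, strict = FALSE) {
  stopifnot(inherits(v, "hgvs_variant"), inherits(provider, "hgvs_provider"))
  out <- list()
  e <- v$posedit$edit
  iv <- v$posedit$interval
  rep_out <- function(...) out[[length(out) + 1L]] <<- outcome(...)

  if (v$type == "p") {
    if (!has_seq(provider, v$ac)) {
      rep_out("e2", "WARNING", sprintf("protein sequence '%s' unavailable; reference not checked", v$ac))
    } else if (!is.null(iv)) {
      ps <- get_seq(provider, v$ac)
      n <- nchar(ps)
      bad_bounds <- iv$start$pos < 1L || iv$end$pos > n + 1L # n+1 = Ter position
      rep_out("e1", if (bad_bounds) "ERROR" else "VALID",
              if (bad_bounds) "position outside the protein sequence" else "interval within bounds")
      if (!bad_bounds) {
        ok <- TRUE
        for (p in list(iv$start, iv$end)) {
          actual <- if (p$pos == n + 1L) "*" else substr(ps, p$pos, p$pos)
          if (!is.na(p$aa) && nzchar(p$aa) && actual != p$aa) ok <- FALSE
        }
        rep_out("e2", if (ok) "VALID" else "ERROR",
                if (ok) "stated residues agree with the protein sequence"
                else "stated residue disagrees with the protein sequence")
      }
    }
    return(finish_report(out, strict))
  }

  # nucleotide types
  seq_ac <- v$ac
  if (!has_seq(provider, seq_ac)) {
    rep_out("e1", "WARNING", sprintf("sequence data not available for '%s'", seq_ac))
    return(finish_report(out, strict))
  }

  if (v$type %in% c("c", "n")) {
    rec <- if (has_transcript(provider, v$ac)) get_transcript(provider, v$ac) else NULL
    if (v$type == "c" && is.null(rec)) {
      rep_out("e1", "WARNING", "no transcript record; CDS-relative bounds not checked")
      return(finish_report(out, strict))
    }
    vn <- tryCatch(if (v$type == "c") c_to_n(v, rec) else v,
                   hgvs_error = function(cnd) NULL)
    if (is.null(vn)) {
      rep_out("e1", "ERROR", "position lies outside the bounds of the reference sequence")
      return(finish_report(out, strict))
    }
    txlen <- seq_length(provider, v$ac)
    ivn <- vn$posedit$interval
    oob <- ivn$start$base < 1L || ivn$end$base > txlen
    rep_out("e1", if (oob) "ERROR" else "VALID",
            if (oob) sprintf("the given coordinate is outside the bounds of the reference sequence (length %d)", txlen)
            else "interval within bounds")
    if (oob) return(finish_report(out, strict))

    intronic <- ivn$start$offset != 0L || ivn$end$offset != 0L
    if (intronic) {
      genomic_ctx <- !is.null(rec) && has_seq(provider, rec$g_ac)
      if (!genomic_ctx) {
        rep_out("e3", "WARNING",
                "variant refers to intronic sequence, which cannot be validated or refuted")
        return(finish_report(out, strict))
      }
      stated <- stated_ref(e)
      if (!is.na(stated)) {
        vg <- tryCatch(n_to_g(vn, rec, provider), hgvs_error = function(cnd) NULL)
        if (is.null(vg)) {
          rep_out("e3", "WARNING", "intronic position could not be projected; reference not checked")
        } else {
          ibg <- nt_interval_ib(vg)
          actual <- get_seq(provider, vg$ac, ibg[1L], ibg[2L])
          stated_g <- if (rec$strand < 0L) revcomp(stated) else stated
          rep_out("e2", if (identical(stated_g, actual)) "VALID" else "ERROR",
                  if (identical(stated_g, actual)) "stated reference agrees with the genomic sequence"
                  else sprintf("stated reference '%s' disagrees with genomic sequence '%s'", stated, if (rec$strand < 0L) revcomp(actual) else actual))
        }
      }
      return(finish_report(out, strict))
    }
    check_ref_against(provider, v$ac, vn, e, rep_out)
    return(finish_report(out, strict))
  }

  # g / m
  n <- seq_length(provider, seq_ac)
  ib <- nt_interval_ib(v)
  oob <- ib[1L] < 0L || ib[2L] > n || v$posedit$interval$start$base > n
  rep_out("e1", if (oob) "ERROR" else "VALID",
          if (oob) sprintf("the given coordinate is outside the bounds of the reference sequence (length %d)", n)
          else "interval within bounds")
  if (!oob) check_ref_against(provider, seq_ac, v, e, rep_out)
  finish_report(out, strict)
}

stated_ref <- function(e) {
  if (!is.na(e$ref) && nzchar(e$ref) && e$kind != "ins") e$ref else NA_character_
}

check_ref_against <- function(provider, ac, v, e, rep_out) {
  stated <- stated_ref(e)
  if (is.na(stated)) return(invisible(NULL))
  ib <- nt_interval_ib(v)
  actual <- get_seq(provider, ac, ib[1L], ib[2L])
  if (identical(stated, actual)) {
    rep_out("e2", "VALID", "stated reference agrees with the sequence")
  } else {
    rep_out("e2", "ERROR",
            sprintf("stated reference '%s' disagrees with sequence '%s'", stated, actual))
  }
}

finish_report <- function(out, strict) {
  rep <- validation_report(if (length(out)) do.call(rbind, out) else
    outcome(character(), character(), character())[0, ])
  if (strict && rep$overall != "VALID") {
    stop_validation(sprintf("strict validation failed (%s)", rep$overall), report = rep)
  }
  rep
}

#' Two-stage validation
#'
#' Runs intrinsic validation and, unless it already found an ERROR (the
#' extrinsic stage needs reference data and is the more expensive one),
#' extrinsic validation, and merges the reports. In the default mode the
#' report is always returned; in strict mode an overall level of WARNING or
#' ERROR raises `hgvs_validation_error` (carrying the report).
#'
#' @param v an `hgvs_variant`.
#' @param provider data provider.
#' @param strict raise on overall >= WARNING.
#' @return a [validation_report()].
#' @export
validate_variant <- function(v, provider, strict = FALSE) {
  ri <- validate_intrinsic(v)
  rep <- if (ri$overall == "ERROR") ri else merge_reports(ri, validate_extrinsic(v, provider))
  if (strict && rep$overall != "VALID") {
    stop_validation(sprintf("strict validation failed (%s)", rep$overall), report = rep)
  }
  rep
}
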