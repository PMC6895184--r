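#' @title Multi-valued table-cell parsing and index pairing
#' @description
#' Literature tables frequently put several absorption maxima (and their
#' extinction coefficients) in a *single* cell -- `"416, 514, 602"` against
#' `"3.0, 1.1, 0.8"` under a header like `"eps x 10^4"`.  Generic table
#' extraction stores these as isolated peak objects and loses the pairing.
#' This module parses such cells (plain, standard-form `x10^n`, and
#' logarithmic unit conventions), normalizes extinction values to
#' L mol-1 cm-1, and re-pairs wavelengths with extinctions by index when the
#' two lists have equal length.
#' @name tableparse
NULL

# unicode superscript digits and minus occasionally survive extraction
.SUPERSCRIPTS <- c("⁰" = "0", "¹" = "1", "²" = "2", "³" = "3",
                   "⁴" = "4", "⁵" = "5", "⁶" = "6", "⁷" = "7",
                   "⁸" = "8", "⁹" = "9", "⁻" = "-")

normalize_superscripts <- function(x) {
  for (k in names(.SUPERSCRIPTS)) x <- gsub(k, .SUPERSCRIPTS[[k]], x, fixed = TRUE)
  x
}

new_cell_parse <- function(values, unit = NA_character_,
                           form = c("plain", "standard_form", "log"),
                           exponent = NA_integer_) {
  form <- match.arg(form)
  structure(list(values = as.numeric(values), unit = unit, form = form,
                 exponent = as.integer(exponent)),
            class = "uvvis_cell")
}

#' @export
print.uvvis_cell <- function(x, ...) {
  cat("<uvvis_cell>", x$form,
      if (!is.na(x$exponent)) sprintf("(x10^%d)", x$exponent) else "",
      ": ", paste(x$values, collapse = ", "),
      if (!is.na(x$unit)) paste0(" [", x$unit, "]") else "", "\n", sep = "")
  invisible(x)
}

extract_numbers <- function(text) {
  # parenthesized annotations like "(sh)" are stripped before tokenization
  t <- gsub("\\([^)]*\\)", " ", text)
  t <- normalize_superscripts(t)
  toks <- regmatches(t, gregexpr("-?[0-9]+\\.?[0-9]*", t))[[1]]
  as.numeric(toks)
}

#' Parse a wavelength table cell
#'
#' Extracts comma/semicolon/slash/whitespace-separated numerals in printed
#' order; shoulder and other parenthetical annotations are ignored.
#'
#' @param text cell contents, non-empty.
#' @param header_unit unit taken from the column header when the cell
#'   carries none (typical; headers read "lambda max (nm)").
#' @return a `uvvis_cell` with `form = "plain"`.
#' @examples
#' parse_wavelength_cell("416, 514, 602")$values
#' @export
parse_wavelength_cell <- function(text, header_unit = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  vals <- extract_numbers(text)
  if (!length(vals)) {
    stop_uvvis(sprintf("no numeral found in wavelength cell '%s'", text),
               "uvvisdb_parse_error")
  }
  unit <- if (grepl("nm", text)) "nm" else header_unit
  new_cell_parse(vals, unit = unit, form = "plain")
}

# detects "x10^n" in free text; returns integer exponent or NA
detect_standard_form <- function(text) {
  t <- normalize_superscripts(text)
  m <- regmatches(t, regexec("[x×⋅*]\\s*10\\s*\\^?\\s*(-?[0-9]+)", t))[[1]]
  if (length(m)) return(as.integer(m[2]))
  m <- regmatches(t, regexec("\\b10\\s*\\^\\s*(-?[0-9]+)", t))[[1]]
  if (length(m)) return(as.integer(m[2]))
  NA_integer_
}

detect_log_marker <- function(text) {
  grepl("\\blog", text, ignore.case = TRUE)
}

#' Parse an extinction-coefficient table cell
#'
#' Handles the three unit conventions of the literature: plain values,
#' standard form (a `x10^n` factor in the cell or the header), and base-10
#' logarithms (a `log` marker).  Values are kept exactly as printed; scaling
#' is deferred to [standardize_extinction()].  When the cell and the header
#' both carry a standard-form exponent, the header wins (single-table
#' consistency).
#'
#' @param text cell contents, non-empty.
#' @param header_unit the column-header unit string, e.g. `"eps x10^4"` or
#'   `"log eps"`.
#' @return a `uvvis_cell`.
#' @examples
#' parse_extinction_cell("2.1, 1.3", "eps x10^4")$exponent  # 4
#' @export
parse_extinction_cell <- function(text, header_unit = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  hu <- if (is.na(header_unit)) "" else header_unit
  exp_header <- detect_standard_form(hu)
  log_header <- detect_log_marker(hu)
  # the cell body is scanned for markers before number extraction
  exp_cell <- detect_standard_form(text)
  log_cell <- detect_log_marker(text)

  is_log <- log_header || log_cell
  expo <- if (!is.na(exp_header)) exp_header else exp_cell
  if (is_log && !is.na(expo)) {
    stop_uvvis("cell mixes 'log' and 'x10^n' markers: ambiguous unit form",
               "uvvisdb_ambiguity_error")
  }

  body <- text
  if (!is.na(exp_cell)) {
    body <- normalize_superscripts(body)
    body <- gsub("[x×⋅*]\\s*10\\s*\\^?\\s*-?[0-9]+", " ", body)
    body <- gsub("\\b10\\s*\\^\\s*-?[0-9]+", " ", body)
  }
  body <- gsub("log", " ", body, ignore.case = TRUE)
  vals <- extract_numbers(body)
  if (!length(vals)) {
    stop_uvvis(sprintf("no numeral found in extinction cell '%s'", text),
               "uvvisdb_parse_error")
  }
  form <- if (is_log) "log" else if (!is.na(expo)) "standard_form" else "plain"
  new_cell_parse(vals, unit = if (nzchar(hu)) hu else NA_character_,
                 form = form, exponent = if (form == "standard_form") expo else NA_integer_)
}

#' Normalize parsed extinction values to L mol-1 cm-1
#'
#' Standard-form values are multiplied by `10^exponent`; log values are
#' mapped through `10^value`; plain values pass through.
#'
#' @param parse a `uvvis_cell` from [parse_extinction_cell()].
#' @return numeric vector in L mol-1 cm-1.
#' @examples
#' standardize_extinction(parse_extinction_cell("2.1", "eps x10^4"))  # 21000
#' @export
standardize_extinction <- function(parse) {
  stopifnot(inherits(parse, "uvvis_cell"))
  out <- switch(parse$form,
                plain = parse$values,
                standard_form = parse$values * 10^parse$exponent,
                log = 10^parse$values)
  if (any(!is.finite(out))) {
    stop_uvvis("extinction standardization overflowed to a non-finite value",
               "uvvisdb_overflow_error")
  }
  out
}

#' Pair wavelength and extinction cells by index
#'
#' When the two value lists have equal length n, the i-th wavelength is
#' paired with the i-th extinction into one peak.  Otherwise all values are
#' emitted as isolated peaks (wavelength-only first, then extinction-only),
#' preserving printed order: pairing never truncates or invents a value.
#'
#' @param lambda_cell `uvvis_cell` from [parse_wavelength_cell()].
#' @param eps_cell `uvvis_cell` from [parse_extinction_cell()], or `NULL`
#'   when the table column is absent.
#' @return list of [peak()] objects.
#' @examples
#' lam <- parse_wavelength_cell("416, 514, 602")
#' eps <- parse_extinction_cell("3.0, 1.1, 0.8", "eps x10^4")
#' length(pair_peaks(lam, eps))  # 3 paired peaks
#' @export
pair_peaks <- function(lambda_cell, eps_cell = NULL) {
  stopifnot(inherits(lambda_cell, "uvvis_cell"))
  lam <- lambda_cell$values
  lam_unit <- if (is.na(lambda_cell$unit)) "nm" else lambda_cell$unit
  if (is.null(eps_cell)) {
    return(lapply(lam, function(l) peak(l, wavelength_unit = lam_unit,
                                        raw_wavelength_unit = lambda_cell$unit)))
  }
  stopifnot(inherits(eps_cell, "uvvis_cell"))
  eps <- standardize_extinction(eps_cell)
  eps_unit <- "L mol-1 cm-1"
  if (length(lam) == length(eps)) {
    lapply(seq_along(lam), function(i) {
      peak(lam[i], wavelength_unit = lam_unit,
           extinction = eps[i], extinction_unit = eps_unit,
           raw_wavelength_unit = lambda_cell$unit)
    })
  } else {
    c(
      lapply(lam, function(l) peak(l, wavelength_unit = lam_unit,
                                   raw_wavelength_unit = lambda_cell$unit)),
      lapply(eps, function(x) {
        p <- peak(NA_real_, wavelength_unit = lam_unit,
                  extinction = x, extinction_unit = eps_unit)
        p
      })
    )
  }
}
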