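#' @title Compound records: PRISTINE/FILTERED document trees
#' @description
#' Data model and (de)serialization for the comparative database.  Each
#' compound is one document keyed by its InChIKey.  A `PRISTINE` branch
#' holds everything as extracted from the literature (SMILES spellings and
#' per-publication UV/vis entries); an optional `FILTERED` branch holds the
#' canonical trimmed structure, its electron count and HPC band, and any
#' computed excited-state blocks (`orca` for sTDA, `nwchem` for TD-DFT,
#' `mopac` for semi-empirical screening).  Missing experimental values are
#' an explicit null: JSON writes native `null`, CSV writes the literal
#' string `NULL`, and both (plus absent keys) read back as `NA`.
#' @name records
NULL

.TABLE1_KEYS <- c("inchikey", "doi", "lambda", "lambda_unit", "extinction",
                  "extinction_unit", "solvent", "amplitude",
                  "oscillator_strength")

#' Construct an absorption peak
#'
#' @param wavelength positive peak wavelength (lambda max).
#' @param wavelength_unit unit string, canonical `"nm"`.
#' @param extinction optional molar extinction coefficient.
#' @param extinction_unit optional unit string, canonical
#'   `"L mol-1 cm-1"`.
#' @param raw_wavelength_unit the unit exactly as printed in the source.
#' @return object of class `uvvis_peak`.
#' @export
peak <- function(wavelength, wavelength_unit = "nm",
                 extinction = NA_real_, extinction_unit = NA_character_,
                 raw_wavelength_unit = NA_character_) {
  wavelength <- scalar_or_na(wavelength, "numeric")
  extinction <- scalar_or_na(extinction, "numeric")
  if (!is.na(wavelength) && wavelength <= 0) {
    stop_uvvis("peak wavelength must be > 0", "uvvisdb_validation_error")
  }
  structure(list(
    wavelength = wavelength,
    wavelength_unit = scalar_or_na(wavelength_unit),
    extinction = extinction,
    extinction_unit = scalar_or_na(extinction_unit),
    raw_wavelength_unit = scalar_or_na(raw_wavelength_unit)
  ), class = "uvvis_peak")
}

#' Construct a UV/vis entry (one publication's set of peaks)
#'
#' @param peaks list of [peak()] objects (may be empty only for records
#'   flagged as false positives).
#' @param doi non-empty source-document DOI.
#' @param solvent optional solvent name as reported.
#' @return object of class `uvvis_entry`.
#' @export
uvvis_entry <- function(peaks, doi, solvent = NA_character_) {
  stopifnot(is.list(peaks))
  structure(list(peaks = peaks, solvent = scalar_or_na(solvent),
                 doi = scalar_or_na(doi)),
            class = "uvvis_entry")
}

#' Construct a computed excited state
#'
#' @param index state index (1 = longest-wavelength, lowest-energy
#'   excitation of its block).
#' @param wavelength computed wavelength in nm.
#' @param oscillator_strength dimensionless transition intensity, >= 0.
#' @param orbital_energies optional list of `(label, energy)` pairs.
#' @return object of class `uvvis_state`.
#' @export
computed_state <- function(index, wavelength, oscillator_strength,
                           orbital_energies = NULL) {
  structure(list(index = scalar_or_na(index, "integer"),
                 wavelength = scalar_or_na(wavelength, "numeric"),
                 oscillator_strength = scalar_or_na(oscillator_strength, "numeric"),
                 orbital_energies = orbital_energies),
            class = "uvvis_state")
}

#' Construct a computed block (one electronic-structure code's results)
#'
#' @param source `"orca"` (sTDA), `"nwchem"` (TD-DFT) or `"mopac"`.
#' @param states list of [computed_state()], ordered by index.
#' @param version optional software version string.
#' @return object of class `uvvis_block`.
#' @export
computed_block <- function(source = c("orca", "nwchem", "mopac"),
                           states = list(), version = NA_character_) {
  source <- match.arg(source)
  structure(list(source = source, states = states,
                 version = scalar_or_na(version)),
            class = "uvvis_block")
}

#' Construct a compound record
#'
#' @param inchikey 27-character hyphenated InChIKey.
#' @param smiles character vector of as-extracted SMILES spellings.
#' @param uvvis list of [uvvis_entry()] objects.
#' @param filtered optional FILTERED branch: a list with elements `smiles`
#'   (canonical trimmed SMILES), `nel`, `band` and `blocks` (list of
#'   [computed_block()]).
#' @param extras opaque named list of unknown keys preserved from loaded
#'   documents (never interpreted).
#' @param false_positive flag for records whose extraction was a false
#'   positive: only these may carry entries with no peaks.
#' @return object of class `uvvis_record`.
#' @export
compound_record <- function(inchikey, smiles = character(), uvvis = list(),
                            filtered = NULL, extras = list(),
                            false_positive = FALSE) {
  structure(list(inchikey = scalar_or_na(inchikey),
                 smiles = as.character(smiles),
                 uvvis = uvvis, filtered = filtered, extras = extras,
                 false_positive = isTRUE(false_positive)),
            class = "uvvis_record")
}

#' @export
print.uvvis_record <- function(x, ...) {
  np <- sum(vapply(x$uvvis, function(e) length(e$peaks), 1L))
  cat("<uvvis_record>", x$inchikey, "-", length(x$uvvis), "uvvis entr(ies),",
      np, "peak(s),", if (is.null(x$filtered)) "no" else "with", "FILTERED branch\n")
  invisible(x)
}

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Validate a compound record against the schema invariants
#'
#' Checks the InChIKey pattern, peak positivity/finiteness, DOI presence,
#' excited-state ordering and FILTERED-branch completeness.  Violations are
#' data, not exceptions.
#'
#' @param record a [compound_record()].
#' @return data.frame with columns `path` and `rule`; zero rows iff all
#'   invariants hold.
#' @export
validate_record <- function(record) {
  issues <- list()
  flag <- function(path, rule) issues[[length(issues) + 1L]] <<- c(path, rule)

  if (is.na(record$inchikey) || !grepl(.INCHIKEY_RE, record$inchikey)) {
    flag("inchikey", "must match the 14-10-1 hyphenated uppercase pattern")
  }
  for (ei in seq_along(record$uvvis)) {
    e <- record$uvvis[[ei]]
    ep <- sprintf("uvvis[%d]", ei)
    if (is.na(e$doi) || !nzchar(e$doi)) flag(paste0(ep, ".doi"), "doi must be non-empty")
    if (length(e$peaks) == 0L && !record$false_positive) {
      flag(paste0(ep, ".peaks"), "peaks may be empty only for false-positive records")
    }
    for (pi in seq_along(e$peaks)) {
      p <- e$peaks[[pi]]
      pp <- sprintf("%s.peaks[%d]", ep, pi)
      if (!is.na(p$wavelength) && (!is.finite(p$wavelength) || p$wavelength <= 0)) {
        flag(paste0(pp, ".wavelength"), "wavelength must be finite and > 0")
      }
      canon_eps <- !is.na(p$extinction_unit) &&
        grepl("mol", p$extinction_unit, ignore.case = TRUE)
      if (!is.na(p$extinction) && canon_eps &&
          (!is.finite(p$extinction) || p$extinction <= 0)) {
        flag(paste0(pp, ".extinction"), "canonical-unit extinction must be finite and > 0")
      }
    }
  }
  if (!is.null(record$filtered)) {
    f <- record$filtered
    if (is_null_marker(f$band)) flag("filtered.band", "FILTERED branch requires a band")
    if (is_null_marker(f$nel)) flag("filtered.nel", "FILTERED branch requires NEL")
    for (bi in seq_along(f$blocks)) {
      blk <- f$blocks[[bi]]
      idx <- vapply(blk$states, `[[`, 1L, "index")
      if (length(idx) && !identical(idx, seq_along(idx))) {
        flag(sprintf("filtered.%s.excited_states", blk$source),
             "states must be ordered by index starting at 1")
      }
      for (si in seq_along(blk$states)) {
        st <- blk$states[[si]]
        if (!is.na(st$wavelength) && st$wavelength <= 0) {
          flag(sprintf("filtered.%s.excited_states[%d].amplitude", blk$source, si),
               "computed wavelength must be > 0")
        }
        if (!is.na(st$oscillator_strength) && st$oscillator_strength < 0) {
          flag(sprintf("filtered.%s.excited_states[%d].oscillator_strength", blk$source, si),
               "oscillator strength must be >= 0")
        }
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(path = character(), rule = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, issues)
  data.frame(path = m[, 1], rule = m[, 2], stringsAsFactors = FALSE)
}

#' Generate an InChIKey from SMILES
#'
#' Canonicalizes through the toolkit and hashes the standard InChI: a
#' function of the molecule, not of the SMILES spelling.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of 27-character InChIKeys.
#' @examples
#' \dontrun{make_inchikey("CCO")  # "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"}
#' @export
make_inchikey <- function(smiles) {
  keys <- rdkit_inchikey(smiles)
  if (anyNA(keys)) {
    stop_uvvis(sprintf("could not resolve SMILES to InChIKey: %s",
                       paste(smiles[is.na(keys)], collapse = ", ")),
               "uvvisdb_resolution_error")
  }
  keys
}

#' Deduplicate records by InChIKey
#'
#' Merges all instances of one compound into a single record: UV/vis entries
#' are concatenated (each keeping its own DOI), SMILES spellings unioned,
#' and the first FILTERED branch retained.  Records with a null key are
#' routed to a rejects list, never merged.
#'
#' @param records list of [compound_record()] objects.
#' @return list of records, one per distinct key, in first-appearance order;
#'   rejected records are in `attr(, "rejects")`.
#' @export
dedupe_by_inchikey <- function(records) {
  keys <- vapply(records, function(r) {
    if (is_null_marker(r$inchikey)) NA_character_ else r$inchikey
  }, "")
  rejects <- records[is.na(keys)]
  records <- records[!is.na(keys)]
  keys <- keys[!is.na(keys)]
  out <- list()
  for (i in seq_along(records)) {
    k <- keys[i]; r <- records[[i]]
    if (is.null(out[[k]])) {
      out[[k]] <- r
    } else {
      out[[k]]$uvvis <- c(out[[k]]$uvvis, r$uvvis)
      out[[k]]$smiles <- union(out[[k]]$smiles, r$smiles)
      if (is.null(out[[k]]$filtered)) out[[k]]$filtered <- r$filtered
      out[[k]]$false_positive <- out[[k]]$false_positive && r$false_positive
    }
  }
  structure(unname(out), rejects = rejects)
}
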