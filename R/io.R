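#' @title Reading and writing the database
#' @description
#' JSON preserves the full nested PRISTINE/FILTERED tree and is the
#' MongoDB-compatible document form; CSV is the flat Table-1 projection
#' (one row per compound-peak pair) and is lossy by design: no excited-state
#' detail beyond the first sTDA state survives the flattening.
#' @name database-io
NULL

# ---- record -> document ----------------------------------------------------

record_to_doc <- function(r) {
  doc <- list(inchikey = r$inchikey)
  pristine <- list(SMI = as.list(r$smiles),
                   uvvis = lapply(r$uvvis, entry_to_doc))
  doc$PRISTINE <- pristine
  if (!is.null(r$filtered)) {
    f <- list(SMI = r$filtered$smiles, NEL = r$filtered$nel,
              band = r$filtered$band)
    for (blk in r$filtered$blocks %||% list()) {
      f[[blk$source]] <- block_to_doc(blk)
    }
    doc$FILTERED <- f
  }
  if (r$false_positive) doc$false_positive <- TRUE
  for (k in names(r$extras)) doc[[k]] <- r$extras[[k]]
  doc
}

entry_to_doc <- function(e) {
  list(doi = e$doi, solvent = e$solvent,
       peaks = lapply(e$peaks, function(p) {
         list(lambda = p$wavelength,
              lambda_unit = if (!is.na(p$raw_wavelength_unit)) p$raw_wavelength_unit
              else p$wavelength_unit,
              extinction = p$extinction,
              extinction_unit = p$extinction_unit)
       }))
}

block_to_doc <- function(blk) {
  list(version = blk$version,
       excited_states = lapply(blk$states, function(s) {
         st <- list(index = s$index, amplitude = s$wavelength,
                    oscillator_strength = s$oscillator_strength)
         if (!is.null(s$orbital_energies)) st$orbital_energy_list <- s$orbital_energies
         st
       }))
}

# ---- document -> record ----------------------------------------------------

.KNOWN_DOC_KEYS <- c("inchikey", "PRISTINE", "FILTERED", "false_positive")

doc_to_record <- function(doc) {
  if (!is.list(doc)) stop_uvvis("document is not an object", "uvvisdb_schema_error")
  pr <- doc$PRISTINE %||% list()
  uvvis <- lapply(pr$uvvis %||% list(), doc_to_entry)
  filtered <- NULL
  if (!is.null(doc$FILTERED)) {
    f <- doc$FILTERED
    blocks <- list()
    for (src in c("orca", "nwchem", "mopac")) {
      if (!is.null(f[[src]])) blocks[[length(blocks) + 1L]] <- doc_to_block(src, f[[src]])
    }
    filtered <- list(smiles = scalar_or_na(f$SMI),
                     nel = scalar_or_na(f$NEL, "integer"),
                     band = scalar_or_na(f$band),
                     blocks = blocks)
  }
  extras <- doc[setdiff(names(doc), .KNOWN_DOC_KEYS)]
  compound_record(
    inchikey = scalar_or_na(doc$inchikey),
    smiles = vapply(pr$SMI %||% list(), as.character, ""),
    uvvis = uvvis,
    filtered = filtered,
    extras = extras,
    false_positive = isTRUE(doc$false_positive)
  )
}

doc_to_entry <- function(e) {
  uvvis_entry(
    peaks = lapply(e$peaks %||% list(), function(p) {
      peak(wavelength = scalar_or_na(p$lambda, "numeric"),
           wavelength_unit = "nm",
           extinction = scalar_or_na(p$extinction, "numeric"),
           extinction_unit = scalar_or_na(p$extinction_unit),
           raw_wavelength_unit = scalar_or_na(p$lambda_unit))
    }),
    doi = scalar_or_na(e$doi),
    solvent = scalar_or_na(e$solvent)
  )
}

doc_to_block <- function(src, b) {
  computed_block(
    source = src,
    states = lapply(b$excited_states %||% list(), function(s) {
      computed_state(index = scalar_or_na(s$index, "integer"),
                     wavelength = scalar_or_na(s$amplitude, "numeric"),
                     oscillator_strength = scalar_or_na(s$oscillator_strength, "numeric"),
                     orbital_energies = s$orbital_energy_list)
    }),
    version = scalar_or_na(b$version)
  )
}

# ---- public API ------------------------------------------------------------

#' Load a database
#'
#' @param stream a file path, connection, or (for JSON) a literal JSON
#'   string.
#' @param format `"json"` or `"csv"`.
#' @return list of [compound_record()] objects.  Per-record schema errors do
#'   not abort the load: offending documents are skipped and the messages
#'   collected in `attr(, "errors")`.
#' @export
load_database <- function(stream, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    docs <- jsonlite::fromJSON(stream, simplifyVector = FALSE)
    errors <- character()
    records <- list()
    for (i in seq_along(docs)) {
      rec <- tryCatch(doc_to_record(docs[[i]]), error = function(e) e)
      if (inherits(rec, "error")) {
        errors <- c(errors, sprintf("document %d: %s", i, conditionMessage(rec)))
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
    structure(records, errors = errors)
  } else {
    df <- utils::read.csv(stream, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
    csv_to_records(df)
  }
}

#' Write a database
#'
#' @param records list of [compound_record()] objects.
#' @param path output file path, or `NULL` to return the serialized text.
#' @param format `"json"` (full tree) or `"csv"` (Table-1 flattening, one
#'   row per compound-peak pair, `NULL` literal for missing values).
#' @return the serialized text, invisibly when written to `path`.
#' @export
write_database <- function(records, path = NULL, format = c("json", "csv")) {
  format <- match.arg(format)
  txt <- if (format == "json") {
    docs <- lapply(records, record_to_doc)
    as.character(jsonlite::toJSON(docs, auto_unbox = TRUE, na = "null",
                                  null = "null", digits = NA, pretty = TRUE))
  } else {
    records_to_csv(records)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

records_to_csv <- function(records) {
  rows <- list()
  fmt <- function(x) if (is.na(x)) "NULL" else as.character(x)
  for (r in records) {
    amp <- NA_real_; osc <- NA_real_
    blks <- r$filtered$blocks %||% list()
    orca <- Filter(function(b) b$source == "orca", blks)
    if (length(orca) && length(orca[[1]]$states)) {
      amp <- orca[[1]]$states[[1]]$wavelength
      osc <- orca[[1]]$states[[1]]$oscillator_strength
    }
    for (e in r$uvvis) {
      for (p in e$peaks) {
        rows[[length(rows) + 1L]] <- c(
          inchikey = fmt(r$inchikey), doi = fmt(e$doi),
          lambda = fmt(p$wavelength),
          lambda_unit = fmt(if (!is.na(p$raw_wavelength_unit)) p$raw_wavelength_unit
                            else p$wavelength_unit),
          extinction = fmt(p$extinction),
          extinction_unit = fmt(p$extinction_unit),
          solvent = fmt(e$solvent),
          amplitude = fmt(amp), oscillator_strength = fmt(osc)
        )
      }
    }
  }
  lines <- paste(.TABLE1_KEYS, collapse = ",")
  if (length(rows)) {
    body <- vapply(rows, function(x) paste(x, collapse = ","), "")
    lines <- c(lines, body)
  }
  paste(lines, collapse = "\n")
}

csv_to_records <- function(df) {
  missing_cols <- setdiff(.TABLE1_KEYS, names(df))
  if (length(missing_cols)) {
    stop_uvvis(sprintf("CSV lacks required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "uvvisdb_schema_error")
  }
  nul <- function(x) ifelse(x == "NULL" | x == "", NA_character_, x)
  df[] <- lapply(df, nul)
  if (!nrow(df)) return(list())
  keys <- unique(df$inchikey)
  records <- vector("list", length(keys))
  for (ki in seq_along(keys)) {
    sub <- df[df$inchikey %in% keys[ki], , drop = FALSE]
    # consecutive rows sharing (doi, solvent) form one uvvis entry
    ekey <- paste(sub$doi, sub$solvent)
    grp <- cumsum(c(TRUE, ekey[-1] != ekey[-length(ekey)]))
    entries <- lapply(split(seq_len(nrow(sub)), grp), function(idx) {
      s <- sub[idx, , drop = FALSE]
      uvvis_entry(
        peaks = lapply(seq_len(nrow(s)), function(j) {
          peak(wavelength = as.numeric(s$lambda[j]),
               extinction = as.numeric(s$extinction[j]),
               extinction_unit = s$extinction_unit[j],
               raw_wavelength_unit = s$lambda_unit[j])
        }),
        doi = s$doi[1], solvent = s$solvent[1]
      )
    })
    filtered <- NULL
    amp <- sub$amplitude[1]; osc <- sub$oscillator_strength[1]
    if (!is.na(amp) || !is.na(osc)) {
      filtered <- list(smiles = NA_character_, nel = NA_integer_,
                       band = NA_character_,
                       blocks = list(computed_block("orca", list(
                         computed_state(1L, as.numeric(amp), as.numeric(osc))
                       ))))
    }
    records[[ki]] <- compound_record(keys[ki], uvvis = unname(entries),
                                     filtered = filtered)
  }
  records
}
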