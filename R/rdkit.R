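#' @title RDKit bridge
#' @description
#' Canonical SMILES and InChIKey generation are delegated to RDKit through a
#' batched Python subprocess (one interpreter start per vector of molecules).
#' All chemistry *logic* in this package runs on its own R-side molecular
#' graph; the bridge supplies only the two primitives the field never
#' reimplements: toolkit canonicalization and the InChI hash.
#' @name rdkit-bridge
NULL

bridge_script <- function() {
  p <- system.file("python", "chem_bridge.py", package = "uvvisdb")
  if (!nzchar(p)) {
    # during development (pkgload) inst/ is not yet installed flat
    p <- file.path("inst", "python", "chem_bridge.py")
  }
  p
}

#' Is the Python/RDKit bridge available?
#'
#' @return `TRUE` if a `python` interpreter with RDKit is on the PATH.
#' @export
rdkit_available <- function() {
  ok <- tryCatch(
    rdkit_call("canonical", smiles = "C"),
    error = function(e) NULL
  )
  identical(ok, "C")
}

#' Call the RDKit bridge
#'
#' Low-level entry point used by [make_inchikey()] and [sanitize_smiles()].
#'
#' @param op one of `"canonical"`, `"inchikey"`, `"randomize"`, `"electrons"`.
#' @param smiles character vector of SMILES strings.
#' @param ... extra request fields (e.g. `n`, `seed` for `"randomize"`).
#' @return op-dependent: character/integer vector parallel to `smiles`
#'   (with `NA` where RDKit could not parse), or a list of character vectors
#'   for `"randomize"`.
#' @keywords internal
rdkit_call <- function(op, smiles, ...) {
  req <- c(list(op = op, smiles = as.list(as.character(smiles))), list(...))
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  writeLines(jsonlite::toJSON(req, auto_unbox = TRUE, null = "null"), infile)
  out <- suppressWarnings(
    system2("python", bridge_script(), stdout = TRUE, stdin = infile, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RDKit bridge failed (python exit status ", status, ")", call. = FALSE)
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(res$ok)) {
    stop("RDKit bridge error: ", res$error, call. = FALSE)
  }
  if (op == "randomize") {
    lapply(res$result, function(x) {
      if (is.null(x)) NA_character_ else vapply(x, as.character, "")
    })
  } else if (op == "electrons") {
    vapply(res$result, function(x) if (is.null(x)) NA_integer_ else as.integer(x), 1L)
  } else {
    vapply(res$result, function(x) if (is.null(x)) NA_character_ else x, "")
  }
}

# memoized per-session canonicalization to keep repeated test calls cheap
.bridge_cache <- new.env(parent = emptyenv())

rdkit_canonical <- function(smiles) {
  key <- paste0("c:", smiles)
  miss <- !vapply(key, exists, TRUE, envir = .bridge_cache)
  if (any(miss)) {
    got <- rdkit_call("canonical", smiles[miss])
    for (i in seq_along(got)) assign(key[miss][i], got[i], envir = .bridge_cache)
  }
  vapply(key, get, "", envir = .bridge_cache, USE.NAMES = FALSE)
}

rdkit_inchikey <- function(smiles) {
  key <- paste0("i:", smiles)
  miss <- !vapply(key, exists, TRUE, envir = .bridge_cache)
  if (any(miss)) {
    got <- rdkit_call("inchikey", smiles[miss])
    for (i in seq_along(got)) assign(key[miss][i], got[i], envir = .bridge_cache)
  }
  vapply(key, get, "", envir = .bridge_cache, USE.NAMES = FALSE)
}
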