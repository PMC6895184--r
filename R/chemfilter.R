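#' @title Rule-based opto-electronic filter
#' @description
#' The five-rule screening stage that turns raw text-mined SMILES into a set
#' of neutral, conjugated organic chromophores cheap enough for
#' excited-state calculations: (1) sanitize and canonicalize the SMILES,
#' (2) reject heavy metals and charged species, (3) require significant
#' pi-conjugation, (4) trim long alkyl chains to methyl, and (5) count
#' electrons (NEL) and assign an HPC cost band.  Rules are applied strictly
#' in this order with short-circuiting; every molecule gets a
#' [FilterReport][run_filter] tracing its fate.
#' @name chemfilter
NULL

# elements admitted by the composition rule: the organic/organochalcogen
# palette of dye chemistry ("no heavy metals")
.ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                       "Se", "Br", "I")

#' Sanitize and canonicalize a SMILES string
#'
#' Bracket tokens containing characters outside the SMILES alphabet (notably
#' `<` and `>`) are removed, stray invalid characters are stripped, and the
#' remainder is canonicalized through the toolkit.  The result is stable
#' under re-application.
#'
#' @param raw character vector of raw SMILES strings.
#' @return character vector of canonical SMILES; `NA` where nothing
#'   parseable remains, with the rejection reason in
#'   `attr(, "reason")` (parallel character vector).
#' @examples
#' \dontrun{sanitize_smiles("[<S>]")   # NA: nothing parseable remains}
#' @export
sanitize_smiles <- function(raw) {
  stopifnot(is.character(raw), all(nzchar(raw) | is.na(raw)))
  cleaned <- gsub("\\[[^]]*[<>][^]]*\\]", "", raw)   # drop invalid bracket tokens
  cleaned <- gsub("[<>]", "", cleaned)               # stray invalid characters
  cleaned <- gsub("\\s", "", cleaned)
  out <- rep(NA_character_, length(raw))
  reason <- rep(NA_character_, length(raw))
  empty <- !nzchar(cleaned) | is.na(cleaned)
  reason[empty] <- "nothing parseable remains after removing invalid tokens"
  if (any(!empty)) {
    can <- rdkit_canonical(cleaned[!empty])
    out[!empty] <- can
    reason[!empty][is.na(can)] <- "SMILES not parseable by the toolkit"
  }
  attr(out, "reason") <- reason
  out
}

#' Composition check: organic, neutral compounds only
#'
#' Fails if any atom is outside the allowed organic element set, or if any
#' formal charge is nonzero (zwitterions included: net-zero but charged).
#'
#' @param mol a `uvvis_mol` or SMILES string.
#' @return logical scalar; on failure the reasons are in `attr(, "reasons")`.
#' @export
check_composition <- function(mol) {
  mol <- as_uvvis_mol(mol)
  reasons <- character()
  bad <- setdiff(unique(mol$atoms$element), .ALLOWED_ELEMENTS)
  if (length(bad)) {
    reasons <- c(reasons, sprintf("disallowed element(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(mol$atoms$charge != 0L)) {
    reasons <- c(reasons, "charged species (nonzero formal charge)")
  }
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Detect significant pi-conjugation
#'
#' Passes iff the molecule has at least one aromatic ring, or at least two
#' multiple bonds joined through a single bond (a conjugated path of length
#' >= 2 multiple bonds).  A single isolated double bond does not qualify.
#'
#' @param mol a `uvvis_mol` or SMILES string.
#' @return logical scalar.
#' @examples
#' detect_conjugation("C=CC=C")   # TRUE: 1,3-butadiene
#' detect_conjugation("C=CCC=C")  # FALSE: isolated diene
#' @export
detect_conjugation <- function(mol) {
  mol <- as_uvvis_mol(mol)
  if (any(mol$atoms$aromatic)) return(TRUE)
  b <- mol$bonds
  multi <- which(b$order >= 2)
  if (length(multi) < 2L) return(FALSE)
  single <- which(b$order == 1 & !b$aromatic)
  if (!length(single)) return(FALSE)
  ends <- function(k) c(b$from[k], b$to[k])
  for (s in single) {
    e <- ends(s)
    # a single bond whose two endpoints each carry a multiple bond links them
    m1 <- any(b$from[multi] == e[1] | b$to[multi] == e[1])
    m2 <- any(b$from[multi] == e[2] | b$to[multi] == e[2])
    if (m1 && m2) return(TRUE)
  }
  FALSE
}

#' Trim long alkyl chains to methyl
#'
#' Every acyclic, saturated, carbon-only substituent of two or more carbons
#' whose attachment atom is part of (or bonded to) the conjugated system is
#' replaced by a single methyl carbon.  Ring atoms, heteroatom-bearing
#' chains, and chains linking two conjugated fragments are never touched.
#' Alkyl substitution has negligible effect on optical absorption, so this
#' cuts the electron count (and hence compute cost) for free.
#'
#' @param mol a `uvvis_mol` or SMILES string.
#' @return the trimmed `uvvis_mol` (idempotent: trimming twice changes nothing).
#' @examples
#' write_smiles(trim_alkyl_chains("CCCCCCc1ccccc1"))  # toluene skeleton
#' @export
trim_alkyl_chains <- function(mol) {
  mol <- as_uvvis_mol(mol)
  n <- nrow(mol$atoms)
  if (n == 0L) return(mol)
  b <- mol$bonds
  inring <- ring_atom_mask(mol)
  multi_atoms <- unique(c(b$from[b$order >= 2], b$to[b$order >= 2]))
  conj <- which(mol$atoms$aromatic | seq_len(n) %in% multi_atoms)
  adj <- mol_adjacency(mol)
  near_conj <- unique(c(conj, unlist(adj[conj])))

  # candidate chain atoms: acyclic saturated uncharged carbons
  sat <- rep(TRUE, n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] >= 2 || b$aromatic[k]) {
      sat[b$from[k]] <- FALSE; sat[b$to[k]] <- FALSE
    }
  }
  cand <- which(mol$atoms$element == "C" & !mol$atoms$aromatic &
                  !inring & sat & mol$atoms$charge == 0L)
  if (!length(cand)) return(mol)

  # connected components of the candidate-induced subgraph
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in cand) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- adj[[v]]
      queue <- c(queue, nb[nb %in% cand & is.na(comp[nb])])
    }
  }

  drop_atoms <- integer()
  keep_methyl <- list()  # attachment core atom -> add one carbon
  for (g in seq_len(cur)) {
    members <- which(comp == g & !is.na(comp))
    if (length(members) < 2L) next   # methyl or lone chain atom: keep
    # attachment edges from the component to the rest of the molecule
    att <- unique(unlist(lapply(members, function(v) setdiff(adj[[v]], members))))
    if (length(att) != 1L) next      # free alkane fragment, or a linker: keep
    # count attachment *edges* (a double attachment to one atom implies a ring,
    # excluded already by acyclicity)
    if (!(att %in% near_conj)) next  # substituent far from the chromophore: keep
    drop_atoms <- c(drop_atoms, members)
    keep_methyl[[length(keep_methyl) + 1L]] <- att
  }
  if (!length(drop_atoms)) return(mol)

  keep <- setdiff(seq_len(n), drop_atoms)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bk <- b[b$from %in% keep & b$to %in% keep, , drop = FALSE]
  bonds <- data.frame(from = remap[bk$from], to = remap[bk$to],
                      order = bk$order, aromatic = bk$aromatic)
  for (att in keep_methyl) {
    atoms <- rbind(atoms, data.frame(element = "C", aromatic = FALSE,
                                     charge = 0L, hcount = NA_integer_,
                                     stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(from = remap[att], to = nrow(atoms),
                                     order = 1, aromatic = FALSE))
  }
  out <- structure(list(atoms = atoms, bonds = bonds), class = "uvvis_mol")
  out$atoms$hcount <- resolve_hcounts(out)
  out
}

#' Assign an HPC cost band from the electron count
#'
#' Bands: small (50 <= NEL <= 140), medium (141-220), large (221-300),
#' extra large (301-370).  Below 50 the molecule is too small to be a useful
#' chromophore target; above 370 it is too expensive to compute.
#'
#' @param nel integer electron count (NEL >= 1).
#' @return one of `"too_small"`, `"small"`, `"medium"`, `"large"`,
#'   `"xlarge"`, `"too_large"`.
#' @examples
#' assign_band(42)   # "too_small" (benzene)
#' assign_band(140)  # "small"; assign_band(141) is "medium"
#' @export
assign_band <- function(nel) {
  stopifnot(is.numeric(nel), all(nel >= 1))
  vapply(as.integer(nel), function(x) {
    if (x < 50L) "too_small"
    else if (x <= 140L) "small"
    else if (x <= 220L) "medium"
    else if (x <= 300L) "large"
    else if (x <= 370L) "xlarge"
    else "too_large"
  }, "")
}

#' Run the full five-rule filter
#'
#' Applies sanitize -> composition -> conjugation -> trim -> electron count /
#' band assignment in order, short-circuiting at the first failure.  NEL is
#' counted on the *trimmed* molecule (trimming precedes banding in the rule
#' order).  Multi-fragment inputs keep the largest fragment once all
#' fragments pass composition; salts fail composition outright.
#'
#' @param smiles character vector of raw SMILES strings.
#' @return a list of `uvvis_filter_report` objects, one per input, each with
#'   fields `input_smiles`, `canonical_smiles`, `rule_results` (named list of
#'   `list(pass, note)`, only for rules actually reached), `nel`, `band`,
#'   `accepted`.
#' @examples
#' \dontrun{
#' rep <- run_filter("CCCCCCc1ccccc1")[[1]]
#' rep$accepted  # TRUE; rep$nel is 50 (toluene after trimming)
#' }
#' @export
run_filter <- function(smiles) {
  stopifnot(is.character(smiles))
  sanitized <- sanitize_smiles(smiles)
  reasons <- attr(sanitized, "reason")
  lapply(seq_along(smiles), function(i) {
    filter_one(smiles[i], sanitized[i], reasons[i])
  })
}

filter_one <- function(input, canonical, san_reason) {
  rep <- structure(list(
    input_smiles = input, canonical_smiles = NA_character_,
    rule_results = list(), nel = NA_integer_, band = NA_character_,
    accepted = FALSE
  ), class = "uvvis_filter_report")

  fail <- function(rule, note) {
    rep$rule_results[[rule]] <- list(pass = FALSE, note = note)
    rep
  }
  pass <- function(rule, note = "") {
    rep$rule_results[[rule]] <<- list(pass = TRUE, note = note)
  }

  if (is.na(canonical)) return(fail("sanitize", san_reason))
  pass("sanitize", canonical)

  mol <- parse_smiles(canonical)
  comp <- check_composition(mol)
  if (!comp) {
    return(fail("composition", paste(attr(comp, "reasons"), collapse = "; ")))
  }
  pass("composition")

  # multi-fragment survivors of the composition check: keep largest fragment
  comps <- mol_components(mol)
  if (max(comps) > 1L) {
    sizes <- tabulate(comps)
    keepc <- which.max(sizes)
    keep <- which(comps == keepc)
    remap <- integer(nrow(mol$atoms)); remap[keep] <- seq_along(keep)
    bk <- mol$bonds[mol$bonds$from %in% keep & mol$bonds$to %in% keep, , drop = FALSE]
    mol <- structure(list(
      atoms = {a <- mol$atoms[keep, , drop = FALSE]; rownames(a) <- NULL; a},
      bonds = data.frame(from = remap[bk$from], to = remap[bk$to],
                         order = bk$order, aromatic = bk$aromatic)
    ), class = "uvvis_mol")
  }

  if (!detect_conjugation(mol)) {
    return(fail("conjugation", "no aromatic ring or conjugated multiple-bond path"))
  }
  pass("conjugation")

  trimmed <- trim_alkyl_chains(mol)
  n_removed <- nrow(mol$atoms) - nrow(trimmed$atoms)
  pass("trim", if (n_removed > 0) sprintf("removed %d chain carbon(s)", n_removed)
       else "no trimmable chains")
  canon_trimmed <- rdkit_canonical(write_smiles(trimmed))
  if (is.na(canon_trimmed)) canon_trimmed <- write_smiles(trimmed)  # defensive

  nel <- electron_count(trimmed)
  band <- assign_band(nel)
  rep$nel <- nel
  rep$band <- band
  ok <- band %in% c("small", "medium", "large", "xlarge")
  rep$rule_results[["band"]] <- list(
    pass = ok,
    note = sprintf("NEL = %d -> %s", nel, band)
  )
  if (ok) {
    rep$canonical_smiles <- canon_trimmed
    rep$accepted <- TRUE
  }
  rep
}

#' @export
print.uvvis_filter_report <- function(x, ...) {
  cat("<uvvis_filter_report> ", x$input_smiles, "\n", sep = "")
  for (r in names(x$rule_results)) {
    rr <- x$rule_results[[r]]
    cat(sprintf("  %-11s %s  %s\n", r, if (rr$pass) "pass" else "FAIL", rr$note))
  }
  if (!is.na(x$nel)) cat("  NEL:", x$nel, " band:", x$band, "\n")
  cat("  accepted:", x$accepted, "\n")
  invisible(x)
}

#' Summarize filter reports as a data frame
#'
#' @param reports list of `uvvis_filter_report` objects from [run_filter()].
#' @return data.frame with one row per molecule: input and canonical SMILES,
#'   the stage of failure (or `NA`), NEL, band, accepted.
#' @export
filter_report_table <- function(reports) {
  stage <- vapply(reports, function(r) {
    f <- names(r$rule_results)[!vapply(r$rule_results, `[[`, TRUE, "pass")]
    if (length(f)) f[1] else NA_character_
  }, "")
  data.frame(
    input_smiles = vapply(reports, `[[`, "", "input_smiles"),
    canonical_smiles = vapply(reports, `[[`, "", "canonical_smiles"),
    failed_at = stage,
    nel = vapply(reports, `[[`, 1L, "nel"),
    band = vapply(reports, `[[`, "", "band"),
    accepted = vapply(reports, `[[`, TRUE, "accepted"),
    stringsAsFactors = FALSE
  )
}
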