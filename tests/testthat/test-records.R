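test_that("worked example document loads to one validated record", {
  recs <- load_database(worked_example_json(), format = "json")
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_identical(r$inchikey, "WAJKAWOYYMLWNI-UHFFFAOYSA-N")
  expect_length(r$uvvis, 1)
  expect_identical(r$uvvis[[1]]$doi, "10.1039/c5ra22092k")
  expect_identical(r$uvvis[[1]]$peaks[[1]]$wavelength, 292)
  # explicit JSON null and the deposit's "NULL" string both map to NA
  expect_true(is.na(r$uvvis[[1]]$peaks[[1]]$extinction))
  expect_identical(nrow(validate_record(r)), 0L)
})

test_that("empty stream and malformed documents are handled per contract", {
  expect_identical(load_database("[]", format = "json"), structure(list(), errors = character()))
  # a malformed document is collected as an error; the load continues
  bad <- '[{"inchikey": "AAAAAAAAAAAAAA-BBBBBBBBBB-N", "PRISTINE": {"uvvis": []}}, "not an object"]'
  recs <- load_database(bad, format = "json")
  expect_length(recs, 1)
  expect_length(attr(recs, "errors"), 1)
})

test_that("JSON round-trip is lossless and a fixed point", {
  recs <- gen_records(fixture_spec(n_compounds = 10, seed = 3))
  txt <- write_database(recs, format = "json")
  back <- load_database(txt, format = "json")
  expect_length(back, 10)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]], recs[[i]], ignore_attr = TRUE)
  }
  # 100 records: JSON -> load -> JSON is byte-stable on the second pass
  recs100 <- gen_records(fixture_spec(n_compounds = 100, seed = 4))
  t1 <- write_database(recs100, format = "json")
  t2 <- write_database(load_database(t1, format = "json"), format = "json")
  expect_identical(t1, t2)
})

test_that("CSV flattening follows the Table-1 projection", {
  r <- compound_record(
    "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
    smiles = "c1ccccc1",
    uvvis = list(uvvis_entry(list(
      peak(416, extinction = 30000, extinction_unit = "L mol-1 cm-1"),
      peak(514)
    ), doi = "10.1000/x", solvent = "EtOH"))
  )
  txt <- write_database(list(r), format = "csv")
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], paste(c("inchikey", "doi", "lambda", "lambda_unit",
                                     "extinction", "extinction_unit", "solvent",
                                     "amplitude", "oscillator_strength"),
                                   collapse = ","))
  # one row per (compound, peak) pair, sharing the inchikey
  expect_length(lines, 3)
  expect_true(all(grepl("^AAAAAAAAAAAAAA-BBBBBBBBBB-N,", lines[2:3])))
  # missing extinction carries the NULL literal
  expect_match(lines[3], ",NULL,NULL,")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, f)
  back <- load_database(f, format = "csv")
  expect_length(back, 1)
  expect_length(back[[1]]$uvvis[[1]]$peaks, 2)
  # projection is a fixed point: write -> load -> write gives identical text
  expect_identical(write_database(back, format = "csv"), txt)
})

test_that("CSV round-trip preserves the projection for generated fixtures", {
  recs <- gen_records(fixture_spec(n_compounds = 25, seed = 9))
  recs <- gen_computed_overlay(recs, seed = 10)
  t1 <- write_database(recs, format = "csv")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(t1, f)
  expect_identical(write_database(load_database(f, format = "csv"), format = "csv"), t1)
})

test_that("dedupe merges by InChIKey and conserves uvvis entries", {
  e <- function(doi) uvvis_entry(list(peak(400)), doi = doi)
  k1 <- "AAAAAAAAAAAAAA-AAAAAAAAAA-N"
  k2 <- "BBBBBBBBBBBBBB-BBBBBBBBBB-N"
  two_same <- list(compound_record(k1, uvvis = list(e("10.1/a"))),
                   compound_record(k1, uvvis = list(e("10.1/b"))))
  merged <- dedupe_by_inchikey(two_same)
  expect_length(merged, 1)
  expect_length(merged[[1]]$uvvis, 2)
  expect_setequal(vapply(merged[[1]]$uvvis, `[[`, "", "doi"), c("10.1/a", "10.1/b"))

  distinct <- list(compound_record(k1), compound_record(k2),
                   compound_record("CCCCCCCCCCCCCC-CCCCCCCCCC-N"))
  expect_length(dedupe_by_inchikey(distinct), 3)

  # 50 records over 20 keys: counts and total entries conserved; idempotent
  set.seed(42)
  keys <- replicate(20, paste0(paste0(sample(LETTERS, 14, TRUE), collapse = ""),
                               "-", paste0(sample(LETTERS, 10, TRUE), collapse = ""), "-N"))
  recs <- lapply(1:50, function(i) {
    compound_record(sample(keys, 1), uvvis = list(e(sprintf("10.2/%d", i))))
  })
  out <- dedupe_by_inchikey(recs)
  expect_length(out, length(unique(vapply(recs, `[[`, "", "inchikey"))))
  n_entries <- function(rr) sum(vapply(rr, function(r) length(r$uvvis), 1L))
  expect_identical(n_entries(out), n_entries(recs))
  expect_equal(dedupe_by_inchikey(out), out, ignore_attr = TRUE)

  # null keys are routed to rejects, never merged
  with_null <- c(recs[1:3], list(compound_record(NA_character_, uvvis = list(e("10.3/x")))))
  out2 <- dedupe_by_inchikey(with_null)
  expect_length(attr(out2, "rejects"), 1)
})

test_that("make_inchikey is a function of the molecule with the standard format", {
  expect_identical(make_inchikey("OCC"), make_inchikey("CCO"))
  # frozen reference value from the standard InChI software for ethanol
  expect_identical(make_inchikey("CCO"), "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  keys <- make_inchikey(c("c1ccccc1", "C1=CC=CC=C1", "Cc1ccccc1"))
  expect_identical(keys[1], keys[2])
  expect_false(keys[1] == keys[3])
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", keys)))
  expect_error(make_inchikey("not_a_smiles((("), class = "uvvisdb_resolution_error")
})

test_that("atom-order permutations of fixture molecules map to one key", {
  pool <- random_molecule_pool()[1:10]
  spellings <- rdkit_call("randomize", pool, n = 10L, seed = 5L)
  for (i in seq_along(pool)) {
    keys <- unique(make_inchikey(spellings[[i]]))
    expect_length(keys, 1)
    expect_identical(keys, make_inchikey(pool[i]))
  }
})

test_that("validate_record names path and rule for each violation", {
  base <- load_database(worked_example_json(), format = "json")[[1]]

  r <- base
  r$uvvis[[1]]$peaks[[1]]$wavelength <- -5
  iss <- validate_record(r)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$path, "uvvis[1].peaks[1].wavelength")

  # five seeded violations -> exactly five issues
  r <- base
  r$inchikey <- "not-a-key"                                   # 1
  r$uvvis[[1]]$peaks[[1]]$wavelength <- -5                    # 2
  r$uvvis[[1]]$doi <- NA_character_                           # 3
  r$uvvis[[2]] <- uvvis_entry(list(), doi = "10.1/ok")        # 4 (empty peaks)
  r$filtered <- list(smiles = "c1ccccc1", nel = NA_integer_,  # 5 (missing NEL)
                     band = "small", blocks = list())
  expect_identical(nrow(validate_record(r)), 5L)

  # empty peaks are tolerated only on false-positive records
  fp <- base
  fp$uvvis[[1]]$peaks <- list()
  expect_identical(nrow(validate_record(fp)), 1L)
  fp$false_positive <- TRUE
  expect_identical(nrow(validate_record(fp)), 0L)
})
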