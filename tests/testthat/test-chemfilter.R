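test_that("sanitize_smiles removes invalid tokens and is idempotent", {
  expect_true(is.na(sanitize_smiles("[<S>]")))
  # the invalid bracket token goes; the rest of the molecule survives
  expect_identical(unname(sanitize_smiles("c1ccccc1[<Si>]")[1]), "c1ccccc1")
  can <- sanitize_smiles("C1=CC=CC=C1")
  expect_identical(unname(can[1]), "c1ccccc1")
  expect_identical(unname(sanitize_smiles(can)[1]), unname(can[1]))
  expect_true(is.na(sanitize_smiles("((((")))
})

test_that("toolkit-randomized spellings collapse to one canonical string each", {
  pool <- random_molecule_pool()
  set.seed(7)
  mols <- sample(pool, 10)
  spellings <- rdkit_call("randomize", mols, n = 10L, seed = 11L)
  canon <- unique(unlist(lapply(seq_along(mols), function(i) {
    unique(sanitize_smiles(spellings[[i]]))
  })))
  expect_length(canon, 10)
})

test_that("composition rejects metals and any formal charge", {
  expect_false(isTRUE(check_composition("[O-]c1ccccc1.[Na+]")))
  expect_true(isTRUE(check_composition("c1ccc2cc3ccccc3cc2c1")))   # anthracene
  expect_false(isTRUE(check_composition("[NH3+]CC(=O)[O-]")))      # zwitterion, net zero
  expect_false(isTRUE(check_composition(parse_smiles("CC[Sn](CC)(CC)CC"))))
  expect_match(attr(check_composition("[O-]c1ccccc1.[Na+]"), "reasons")[1], "element")
  # seeded faults: exactly the seeded subset fails
  set.seed(12)
  clean <- sample(random_molecule_pool(), 50, replace = TRUE)
  fault <- rep(FALSE, 50)
  fault[sample(50, 15)] <- TRUE
  smi <- ifelse(fault, paste0(clean, ".[Na+]"), clean)
  got <- !vapply(smi, function(s) isTRUE(check_composition(s)), TRUE)
  expect_identical(unname(got), fault)
})

test_that("conjugation requires an aromatic ring or a conjugated multi-bond path", {
  expect_false(detect_conjugation("CC"))
  expect_true(detect_conjugation("c1ccccc1"))
  expect_true(detect_conjugation("C=CC=C"))
  expect_false(detect_conjugation("C=CCC=C"))     # isolated diene
  expect_false(detect_conjugation("C=C"))         # single double bond
  expect_true(detect_conjugation("C#CC=C"))       # ene-yne
  expect_false(detect_conjugation("C=C=C"))       # cumulene: no single-bond link
  # property: polyene with a spacer of k saturated carbons is conjugated iff k = 1
  for (k in 1:4) {
    smi <- paste0("C=C", strrep("C", k - 1), "C=C")
    expect_identical(detect_conjugation(smi), k == 1, label = smi)
  }
})

test_that("trim_alkyl_chains reduces long chains to methyl and nothing else", {
  trim_to <- function(s) unname(rdkit_canonical(write_smiles(trim_alkyl_chains(s))))
  toluene <- unname(rdkit_canonical("Cc1ccccc1"))
  expect_identical(trim_to("CCCCCCc1ccccc1"), toluene)   # hexylbenzene
  expect_identical(trim_to("Cc1ccccc1"), toluene)        # already methyl
  # branched substituent collapses to methyl too
  expect_identical(trim_to("CC(C)(C)c1ccccc1"), toluene)
  # heteroatom-bearing chains are never trimmed
  expect_identical(trim_to("OCCc1ccccc1"), unname(rdkit_canonical("OCCc1ccccc1")))
  # saturated rings are never trimmed
  expect_identical(trim_to("C1CCCCC1c1ccccc1"), unname(rdkit_canonical("C1CCCCC1c1ccccc1")))
  # chains linking two conjugated fragments are never trimmed
  expect_identical(trim_to("c1ccccc1CCc1ccccc1"), unname(rdkit_canonical("c1ccccc1CCc1ccccc1")))
})

test_that("trim is idempotent and never increases NEL or touches the pi system", {
  set.seed(23)
  pool <- random_molecule_pool()
  mols <- sample(pool, 40, replace = TRUE)
  for (s in mols) {
    m <- parse_smiles(s)
    t1 <- trim_alkyl_chains(m)
    t2 <- trim_alkyl_chains(t1)
    expect_identical(write_smiles(t2), write_smiles(t1), label = s)
    expect_lte(electron_count(t1), electron_count(m))
    expect_identical(sum(t1$atoms$aromatic), sum(m$atoms$aromatic))
    expect_identical(sum(t1$bonds$order >= 2), sum(m$bonds$order >= 2))
  }
})

test_that("electron_count sums atomic numbers including implicit hydrogens", {
  expect_identical(electron_count("c1ccccc1"), 42L)                  # C6H6
  expect_identical(electron_count("c1ccc2cc3ccccc3cc2c1"), 94L)      # C14H10
  expect_identical(electron_count("Cc1ccccc1"), 50L)                 # C7H8
  # invariant under atom reordering
  spellings <- rdkit_call("randomize", "CCCCCCc1ccccc1", n = 8L, seed = 3L)[[1]]
  counts <- vapply(spellings, function(s) electron_count(parse_smiles(s)), 1L)
  expect_identical(unique(counts), electron_count("CCCCCCc1ccccc1"))
  expect_error(electron_count("[NH4+]"), class = "uvvisdb_precondition_error")
})

test_that("assign_band partitions the electron-count axis exactly as stated", {
  expect_identical(assign_band(42), "too_small")
  expect_identical(assign_band(c(49, 50, 140, 141, 220, 221, 300, 301, 370, 371)),
                   c("too_small", "small", "small", "medium", "medium", "large",
                     "large", "xlarge", "xlarge", "too_large"))
  # no gaps or overlaps over the whole useful range
  bands <- assign_band(1:500)
  runs <- rle(bands)
  expect_identical(runs$values,
                   c("too_small", "small", "medium", "large", "xlarge", "too_large"))
  expect_identical(runs$lengths, c(49L, 91L, 80L, 80L, 70L, 130L))
})

test_that("run_filter applies rules in order with short-circuiting", {
  reps <- run_filter(c("CC", "CCCCCCc1ccccc1", "[<S>]"))

  # a molecule failing rule k has no results for rules > k
  expect_named(reps[[1]]$rule_results, c("sanitize", "composition", "conjugation"))
  expect_false(reps[[1]]$rule_results$conjugation$pass)
  expect_false(reps[[1]]$accepted)

  expect_true(reps[[2]]$accepted)
  expect_identical(reps[[2]]$nel, 50L)       # NEL counted on the trimmed molecule
  expect_identical(reps[[2]]$band, "small")
  expect_identical(reps[[2]]$canonical_smiles, unname(rdkit_canonical("Cc1ccccc1")))

  expect_named(reps[[3]]$rule_results, "sanitize")

  tab <- filter_report_table(reps)
  expect_identical(tab$failed_at, c("conjugation", NA, "sanitize"))
})
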