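# shared helpers: fixtures are built in code, never stored

# the deposit-style worked example document: one compound, one uvvis entry
worked_example_json <- function() {
  paste0('[{
    "inchikey": "WAJKAWOYYMLWNI-UHFFFAOYSA-N",
    "PRISTINE": {
      "SMI": ["Cc1ccc(cc1)S(=O)(=O)O"],
      "uvvis": [{
        "doi": "10.1039/c5ra22092k",
        "solvent": "ethanol",
        "peaks": [
          {"lambda": 292.0, "lambda_unit": "nm",
           "extinction": null, "extinction_unit": null}
        ]
      }]
    }
  }]')
}

# render a list of (lambda, eps) pairs into table cells under a unit form;
# the independent "ground truth -> printed cell" direction of the pairing
# round-trip oracle
render_cells <- function(lambda, eps, form = c("plain", "standard_form", "log"),
                         exponent = 4L) {
  form <- match.arg(form)
  lam_cell <- paste(sprintf("%.10g", lambda), collapse = ", ")
  if (form == "plain") {
    list(lambda = lam_cell,
         eps = paste(sprintf("%.10g", eps), collapse = ", "),
         header = "epsilon (L mol-1 cm-1)")
  } else if (form == "standard_form") {
    list(lambda = lam_cell,
         eps = paste(sprintf("%.10g", eps / 10^exponent), collapse = ", "),
         header = sprintf("epsilon x10^%d", exponent))
  } else {
    list(lambda = lam_cell,
         eps = paste(sprintf("%.10g", log10(eps)), collapse = ", "),
         header = "log epsilon")
  }
}

# a deterministic pool of valid neutral organic SMILES for randomized tests
random_molecule_pool <- function() {
  # cores safe to decorate with an alkyl prefix (first atom can take a bond)
  cores <- c("c1ccccc1", "c1ccc2ccccc2c1", "c1ccsc1", "c1ccoc1", "c1ccncc1",
             "c1ccc2cc3ccccc3cc2c1", "c1ccc(-c2ccccc2)cc1", "C=CC=C",
             "C=CC=CC=C", "Oc1ccccc1", "COc1ccccc1")
  pool <- "N#Cc1ccccc1"
  for (k in 0:6) pool <- c(pool, paste0(strrep("C", k), cores))
  unique(pool)
}
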