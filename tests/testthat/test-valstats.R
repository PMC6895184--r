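test_that("histograms follow the left-closed right-open bin convention", {
  h <- build_histogram(c(5, 11.9, 12), 0, 12)
  expect_identical(h$counts, c(2L, 1L))
  expect_identical(h$n_total, 3L)
  expect_identical(build_histogram(431, 0, 12)$counts[36], 1L)
  expect_identical(build_histogram(numeric(0), 0, 12)$n_total, 0L)
  expect_error(build_histogram(c(-1, 5), 0, 12), class = "uvvisdb_domain_error")
  expect_identical(sum(build_histogram(runif(500, 0, 100), 0, 7)$counts), 500L)
})

test_that("uniform draws fill bins to binomial accuracy", {
  set.seed(31)
  h <- build_histogram(runif(1e4, 0, 120), 0, 12)
  expect_length(h$counts, 10)
  sigma <- sqrt(1e4 * 0.1 * 0.9)
  expect_true(all(abs(h$counts - 1e3) < 5 * sigma))
})

test_that("histogram intersection is a bounded symmetric proportion overlap", {
  set.seed(32)
  h1 <- build_histogram(runif(200, 0, 60), 0, 12)
  h2 <- build_histogram(runif(300, 30, 90), 0, 12)
  i12 <- histogram_intersection(h1, h2)
  expect_gt(i12, 0); expect_lt(i12, 1)
  expect_identical(i12, histogram_intersection(h2, h1))
  expect_identical(histogram_intersection(h1, h1), 1)
  # disjoint supports
  hd <- build_histogram(runif(100, 120, 180), 0, 12)
  expect_identical(histogram_intersection(h1, hd), 0)
  # direct sum-of-minima case: p1 = (.5,.5,0), p2 = (0,.5,.5)
  ha <- build_histogram(c(1, 13), 0, 12)
  hb <- build_histogram(c(13, 25), 0, 12)
  expect_identical(histogram_intersection(ha, hb), 0.5)
  expect_error(histogram_intersection(ha, build_histogram(1, 0, 6)),
               class = "uvvisdb_domain_error")
  expect_error(histogram_intersection(ha, build_histogram(numeric(0), 0, 12)),
               class = "uvvisdb_domain_error")
})

test_that("summary_stats computes the adjusted Fisher-Pearson skewness", {
  s <- summary_stats(c(1, 2, 3))
  expect_identical(s$skew, 0)
  expect_identical(s$median, 2)
  expect_gt(summary_stats(c(0, 0, 0, 10))$skew, 0)
  # lognormal fixture: sample skew approaches the closed form
  set.seed(33)
  sigma <- 0.4
  x <- rlnorm(1e4, 0, sigma)
  closed <- (exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)
  expect_lt(abs(summary_stats(x)$skew - closed) / closed, 0.10)
  expect_error(summary_stats(5), class = "uvvisdb_domain_error")
})

test_that("subsample_stability is seeded, exact at fraction 1, and stable", {
  set.seed(34)
  x <- 190 + rlnorm(2000, log(210) + 0.16, 0.4)
  t1 <- subsample_stability(x, c(0.25, 0.5, 0.75, 1), seed = 5)
  t2 <- subsample_stability(x, c(0.25, 0.5, 0.75, 1), seed = 5)
  expect_identical(t1, t2)
  full <- summary_stats(x)
  expect_identical(t1$mean[4], full$mean)
  expect_identical(t1$skew[4], full$skew)
  expect_error(subsample_stability(x, 1e-4), class = "uvvisdb_domain_error")
})

test_that("epsilon_flags applies the physical range and percentile rules", {
  expect_identical(epsilon_flags(5e5 + 1)$flag, "out_of_range")
  expect_identical(epsilon_flags(c(999, 1e3, 5e5))$flag[1], "out_of_range")
  # degenerate ranks: equal values are never flagged under strict thresholds
  expect_true(all(epsilon_flags(rep(2e4, 10))$flag == "ok"))
  # flag fractions sit within one rank of the nominal 20% / 10%
  set.seed(35)
  v <- 10^runif(1000, 3, log10(5e5))
  fl <- epsilon_flags(v)
  n <- length(attr(fl, "retained"))
  expect_lt(abs(sum(fl$flag == "low_percentile") / n - 0.20), 1 / n + 1e-9)
  expect_lt(abs(sum(fl$flag == "high_percentile") / n - 0.10), 1 / n + 1e-9)
  # seeded corruption at the bottom: flagged set contains the corrupted set
  spec <- fixture_spec(n_compounds = 800, seed = 36, eps_frac = 1, corrupt_frac = 0.2)
  recs <- gen_records(spec)
  eps <- experimental_epsilons(recs)
  corrupted <- attr(recs, "corrupted")
  fl <- epsilon_flags(eps)
  expect_true(all(fl$flag[corrupted] != "ok"))
})

test_that("epsilon_from_oscillator implements the empirical conversion", {
  expect_identical(epsilon_from_oscillator(0, 2), 0)
  expect_identical(epsilon_from_oscillator(1, 1), 2.699e4)
  expect_equal(epsilon_from_oscillator(0.5, 2.699e4), 0.5)
  expect_error(epsilon_from_oscillator(1, 0), class = "uvvisdb_domain_error")
  expect_error(epsilon_from_oscillator(-1, 1), class = "uvvisdb_domain_error")
})

test_that("mae matches the folded-normal expectation on biased fixtures", {
  expect_identical(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mae(c(1, 2, 3) + 7, c(1, 2, 3)), 7)
  set.seed(37)
  n <- 1e4; mu <- 50; s <- 10
  pred <- rnorm(n, mu, s)
  expected <- mu * (1 - 2 * pnorm(-mu / s)) + 2 * s * dnorm(mu / s)
  expect_lt(abs(mae(pred, rep(0, n)) - expected), 3 * s / sqrt(n))
  expect_error(mae(numeric(0), numeric(0)), class = "uvvisdb_domain_error")
})

test_that("regression_with_ci fits OLS with a mean-response band", {
  x <- 1:20
  fit <- regression_with_ci(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_lt(max(fit$band$upr - fit$band$lwr), 1e-8)
  set.seed(38)
  fit0 <- regression_with_ci(runif(2000), rnorm(2000))
  expect_lt(fit0$r_squared, 0.01)
  expect_error(regression_with_ci(rep(1, 5), rnorm(5)), class = "uvvisdb_domain_error")
})

test_that("98% confidence band covers the true mean response", {
  set.seed(39)
  hits <- 0L; total <- 0L
  for (rep in 1:500) {
    x <- runif(30, 0, 10)
    y <- 3 + 2 * x + rnorm(30, 0, 2)
    band <- regression_with_ci(x, y, conf = 0.98, newx = 5)$band
    truth <- 3 + 2 * 5
    hits <- hits + (band$lwr <= truth && truth <= band$upr)
    total <- total + 1L
  }
  # binomial 5-sigma window around 0.98
  expect_gt(hits / total, 0.98 - 5 * sqrt(0.98 * 0.02 / 500))
  expect_lte(hits / total, 1)
})

test_that("quartile_summary follows the Tukey box-plot convention", {
  q <- quartile_summary(1:100)
  expect_equal(q$median, 50.5)
  expect_equal(q$lower_quartile, 25.75)
  expect_equal(q$upper_quartile, 75.25)
  expect_length(q$outliers, 0)
  qe <- quartile_summary(rep(5, 10))
  expect_identical(qe$upper_quartile - qe$lower_quartile, 0)
  expect_length(qe$outliers, 0)
  qo <- quartile_summary(c(1:20, 1000))
  expect_identical(qo$outliers, 1000)
  expect_lte(qo$whisker_high, 20)
})

test_that("spearman_corr is the tie-aware rank correlation", {
  x <- c(2, 5, 9, 14, 20, 33)
  expect_equal(spearman_corr(x, x^3), 1)
  expect_equal(spearman_corr(x, rev(x)), -1)
  # brute-force rank formula on a small table with ties
  y <- c(3, 1, 4, 1, 5, 9)
  rx <- rank(x); ry <- rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_corr(x, y), brute)
  expect_error(spearman_corr(rep(1, 5), 1:5), class = "uvvisdb_domain_error")
})

test_that("solvent_tally canonicalizes aliases and counts per compound", {
  e <- function(doi, solvent) uvvis_entry(list(peak(400)), doi = doi, solvent = solvent)
  key <- function(i) sprintf("%s-%s-N", strrep(LETTERS[i], 14), strrep(LETTERS[i], 10))
  # EtOH / ethanol / Ethanol on three compounds -> one canonical entry, count 3
  recs <- list(compound_record(key(1), uvvis = list(e("10.1/a", "EtOH"))),
               compound_record(key(2), uvvis = list(e("10.1/b", "ethanol"))),
               compound_record(key(3), uvvis = list(e("10.1/c", "Ethanol"))))
  tal <- solvent_tally(recs, min_count = 1)
  expect_identical(tal$solvent, "ethanol")
  expect_identical(tal$count, 3L)
  # a compound measured twice in ethanol counts once
  recs2 <- list(compound_record(key(4), uvvis = list(e("10.2/a", "ethanol"),
                                                     e("10.2/b", "EtOH"))))
  expect_identical(solvent_tally(recs2, min_count = 1)$count, 1L)
  # ten canonical solvents order by increasing dielectric constant
  all10 <- c("toluene", "chloroform", "THF", "DCM", "acetone", "ethanol",
             "methanol", "acetonitrile", "DMF", "DMSO")
  recs3 <- lapply(seq_along(all10), function(i) {
    compound_record(key(i %% 20 + 1), uvvis = list(e(sprintf("10.3/%d", i), all10[i])))
  })
  tal3 <- solvent_tally(recs3, min_count = 1)
  expect_identical(tal3$solvent, all10)
  expect_false(is.unsorted(tal3$dielectric))
  # unknown solvent names land in the unrecognized bucket
  recs4 <- list(compound_record(key(5), uvvis = list(e("10.4/a", "supercritical xenon"))))
  tal4 <- solvent_tally(recs4, min_count = 1)
  expect_identical(nrow(tal4), 0L)
  expect_identical(names(attr(tal4, "unrecognized")), "supercritical xenon")
})
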