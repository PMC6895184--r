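#' @title Technical-validation statistics
#' @description
#' The statistics used to argue that the curated database is representative
#' and internally consistent: wavelength histograms and their intersection,
#' subsample stability of distribution moments, extinction-coefficient
#' range/percentile flagging, the empirical oscillator-strength conversion,
#' mean absolute error, OLS regression with a confidence band, Tukey
#' quartile summaries, Spearman rank correlation, and the per-compound
#' solvent tally ordered by dielectric constant.
#' @name valstats
NULL

#' Build a fixed-origin, fixed-width histogram
#'
#' Bins are left-closed right-open intervals `[origin + k*w, origin + (k+1)*w)`.
#'
#' @param values numeric vector; all values must be `>= origin`.
#' @param origin left edge of the first bin.
#' @param bin_width positive bin width (the wavelength analyses use 12 nm;
#'   extinction histograms use 6.25e3).
#' @return object of class `uvvis_histogram`: `origin`, `bin_width`,
#'   `counts`, `n_total`.
#' @examples
#' build_histogram(c(5, 11.9, 12), 0, 12)$counts  # c(2, 1)
#' @export
build_histogram <- function(values, origin, bin_width) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  values <- values[!is.na(values)]
  if (length(values) && any(values < origin)) {
    stop_uvvis("values below the histogram origin are not representable",
               "uvvisdb_domain_error")
  }
  if (!length(values)) {
    return(structure(list(origin = origin, bin_width = bin_width,
                          counts = integer(0), n_total = 0L),
                     class = "uvvis_histogram"))
  }
  k <- floor((values - origin) / bin_width)
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  structure(list(origin = origin, bin_width = bin_width,
                 counts = as.integer(counts), n_total = length(values)),
            class = "uvvis_histogram")
}

#' @export
print.uvvis_histogram <- function(x, ...) {
  cat("<uvvis_histogram> origin", x$origin, "width", x$bin_width,
      "bins", length(x$counts), "n", x$n_total, "\n")
  invisible(x)
}

#' Histogram intersection
#'
#' `I = sum_k min(p1_k, p2_k)` over bin *proportions* (each histogram
#' normalized by its own total, so unequal sample sizes compare fairly).
#' 0 means disjoint support, 1 identical distributions; symmetric.
#'
#' @param h1,h2 `uvvis_histogram` objects sharing origin and bin width
#'   (rebin first otherwise).
#' @return similarity in `[0, 1]`.
#' @export
histogram_intersection <- function(h1, h2) {
  stopifnot(inherits(h1, "uvvis_histogram"), inherits(h2, "uvvis_histogram"))
  if (h1$origin != h2$origin || h1$bin_width != h2$bin_width) {
    stop_uvvis("histograms must share origin and bin width; rebin first",
               "uvvisdb_domain_error")
  }
  if (h1$n_total == 0L || h2$n_total == 0L) {
    stop_uvvis("histogram intersection is undefined for an empty histogram",
               "uvvisdb_domain_error")
  }
  nb <- max(length(h1$counts), length(h2$counts))
  p1 <- c(h1$counts, rep(0L, nb - length(h1$counts))) / h1$n_total
  p2 <- c(h2$counts, rep(0L, nb - length(h2$counts))) / h2$n_total
  sum(pmin(p1, p2))
}

#' Core distribution statistics
#'
#' Mean, sample standard deviation, median and the adjusted Fisher-Pearson
#' coefficient of skewness (bias-adjusted third standardized moment,
#' `G1 = g1 * sqrt(n(n-1))/(n-2)`).
#'
#' @param values numeric vector, `n >= 2`.
#' @return object of class `uvvis_summary`: `mean`, `std`, `median`, `skew`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    stop_uvvis("summary statistics are undefined for n < 2", "uvvisdb_domain_error")
  }
  m <- mean(values)
  s2 <- mean((values - m)^2)              # population second moment
  g1 <- if (s2 == 0) 0 else mean((values - m)^3) / s2^1.5
  skew <- if (n > 2L) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
  structure(list(mean = m, std = stats::sd(values),
                 median = stats::median(values), skew = skew),
            class = "uvvis_summary")
}

#' @export
print.uvvis_summary <- function(x, ...) {
  cat(sprintf("<uvvis_summary> mean %.4g  std %.4g  median %.4g  skew %.4g\n",
              x$mean, x$std, x$median, x$skew))
  invisible(x)
}

#' Subsample stability of distribution statistics
#'
#' Draws simple random subsamples without replacement at each fraction and
#' recomputes [summary_stats()]; a representative dataset shows only a small
#' spread of means/medians across fractions.  Fraction 1.0 is the full set,
#' computed exactly (no sampling).
#'
#' @param values numeric vector.
#' @param fractions fractions in `(0, 1]`; the validation uses 1/4, 1/2, 3/4.
#' @param seed integer seed making the table reproducible.
#' @return data.frame with one row per fraction: `fraction`, `n`, `mean`,
#'   `std`, `median`, `skew`.
#' @export
subsample_stability <- function(values, fractions = c(0.25, 0.5, 0.75, 1),
                                seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  values <- values[!is.na(values)]
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    sub <- if (f == 1) values else {
      n_sub <- floor(f * length(values))
      if (n_sub < 2L) {
        stop_uvvis(sprintf("fraction %.3g yields n < 2", f), "uvvisdb_domain_error")
      }
      # derived sub-seed keeps fractions independent yet reproducible
      local_seed_sample(seed + i, values, n_sub)
    }
    st <- summary_stats(sub)
    data.frame(fraction = f, n = length(sub), mean = st$mean, std = st$std,
               median = st$median, skew = st$skew)
  })
  do.call(rbind, rows)
}

local_seed_sample <- function(seed, values, n_sub) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample(values, n_sub, replace = FALSE)
}

#' Range and percentile flagging of extinction coefficients
#'
#' Values outside `[1e3, 5e5]` L mol-1 cm-1 are physically unrealistic and
#' flagged `out_of_range` (they are excluded from percentile computation).
#' Among retained values, percentile ranks strictly below the 20th or
#' strictly above the 90th are flagged: the literature's dominant extinction
#' error mode is a dropped or garbled standard-form exponent, which throws
#' the value into an extreme percentile while leaving the mantissa correct.
#'
#' @param values numeric extinction coefficients in L mol-1 cm-1.
#' @param lower,upper physical range bounds (inclusive).
#' @param low_pct,high_pct percentile thresholds (strict inequalities).
#' @return data.frame `value`, `flag` (`ok`, `low_percentile`,
#'   `high_percentile`, `out_of_range`) in input order;
#'   `attr(, "retained")` gives the in-range values.
#' @export
epsilon_flags <- function(values, lower = 1e3, upper = 5e5,
                          low_pct = 20, high_pct = 90) {
  stopifnot(is.numeric(values))
  flag <- rep("ok", length(values))
  oor <- is.na(values) | values < lower | values > upper
  flag[oor] <- "out_of_range"
  retained <- values[!oor]
  if (length(retained) > 1L) {
    r <- rank(retained, ties.method = "average")
    pct <- 100 * (r - 1) / (length(retained) - 1)
    fl <- rep("ok", length(retained))
    fl[pct < low_pct] <- "low_percentile"
    fl[pct > high_pct] <- "high_percentile"
    flag[!oor] <- fl
  }
  structure(data.frame(value = values, flag = flag, stringsAsFactors = FALSE),
            retained = retained)
}

#' Convert an oscillator strength to a calculated extinction coefficient
#'
#' The empirical conversion `eps_calc = f * 2.699e4 / b`, with `b` the line
#' width of the absorption band: linear in `f`, inverse in `b`.
#'
#' @param f oscillator strength(s), `>= 0`.
#' @param b line width(s), `> 0`.
#' @return calculated extinction coefficient(s).
#' @examples
#' epsilon_from_oscillator(1, 1)  # 26990
#' @export
epsilon_from_oscillator <- function(f, b) {
  stopifnot(is.numeric(f), is.numeric(b))
  if (any(f < 0)) stop_uvvis("oscillator strength must be >= 0", "uvvisdb_domain_error")
  if (any(b <= 0)) stop_uvvis("line width must be > 0", "uvvisdb_domain_error")
  f * 2.699e4 / b
}

#' Mean absolute error
#'
#' @param pred,obs equal-length paired numeric vectors.
#' @return mean of `|pred - obs|`.
#' @export
mae <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (!length(pred)) stop_uvvis("MAE is undefined for empty input", "uvvisdb_domain_error")
  mean(abs(pred - obs))
}

#' Ordinary least squares with a pointwise confidence band
#'
#' @param x,y paired numeric vectors, `n >= 3`, `x` non-degenerate.
#' @param conf confidence level for the mean-response band (the validation
#'   plots use 98%).
#' @param newx abscissae at which to evaluate the band (defaults to `x`).
#' @return list: `slope`, `intercept`, `r_squared`, `band` (data.frame
#'   `x`, `fit`, `lwr`, `upr`).
#' @export
regression_with_ci <- function(x, y, conf = 0.98, newx = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) {
    stop_uvvis("regression is undefined for degenerate x (zero variance)",
               "uvvisdb_domain_error")
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (is.null(newx)) newx <- sort(unique(x))
  ci <- stats::predict(fit, newdata = data.frame(x = newx),
                       interval = "confidence", level = conf)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss == 0) 1 else 1 - rss / tss,
       band = data.frame(x = newx, fit = ci[, "fit"],
                         lwr = ci[, "lwr"], upr = ci[, "upr"]))
}

#' Tukey quartile summary (box-plot statistics)
#'
#' Quartiles by linear interpolation between closest ranks; whiskers at the
#' most extreme data points within 1.5 IQR of the quartiles; anything beyond
#' is an outlier.
#'
#' @param values numeric vector, `n >= 4`.
#' @return list: `lower_quartile`, `median`, `upper_quartile`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
quartile_summary <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 4L)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(lower_quartile = q[1], median = q[2], upper_quartile = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

#' Spearman rank correlation
#'
#' @param x,y equal-length numeric vectors, `n >= 3`; average ranks for ties.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop_uvvis("rank correlation is undefined with zero rank variance",
               "uvvisdb_domain_error")
  }
  stats::cor(rx, ry)
}

# ---- solvents --------------------------------------------------------------

#' Canonical solvent table
#'
#' The ten solvents that dominate reported UV/vis measurements, with their
#' static dielectric constants (handbook values near room temperature;
#' polarity rises left to right in the validation bar chart).
#'
#' @return data.frame `solvent`, `dielectric`, ordered by increasing
#'   dielectric constant.
#' @export
solvent_dielectrics <- function() {
  data.frame(
    solvent = c("toluene", "chloroform", "THF", "DCM", "acetone",
                "ethanol", "methanol", "acetonitrile", "DMF", "DMSO"),
    dielectric = c(2.38, 4.81, 7.58, 8.93, 20.7,
                   24.5, 32.7, 37.5, 38.25, 46.7),
    stringsAsFactors = FALSE
  )
}

#' Solvent alias map
#'
#' Literature spellings mapped to canonical names (matching is
#' case-insensitive after trimming).
#'
#' @return named character vector: alias -> canonical.
#' @export
solvent_aliases <- function() {
  c(
    "toluene" = "toluene", "toluol" = "toluene", "phme" = "toluene",
    "chloroform" = "chloroform", "chcl3" = "chloroform",
    "trichloromethane" = "chloroform",
    "thf" = "THF", "tetrahydrofuran" = "THF",
    "dcm" = "DCM", "dichloromethane" = "DCM", "methylene chloride" = "DCM",
    "ch2cl2" = "DCM",
    "acetone" = "acetone", "propanone" = "acetone", "me2co" = "acetone",
    "ethanol" = "ethanol", "etoh" = "ethanol", "ethyl alcohol" = "ethanol",
    "methanol" = "methanol", "meoh" = "methanol", "methyl alcohol" = "methanol",
    "acetonitrile" = "acetonitrile", "mecn" = "acetonitrile",
    "ch3cn" = "acetonitrile", "acn" = "acetonitrile",
    "dmf" = "DMF", "dimethylformamide" = "DMF",
    "n,n-dimethylformamide" = "DMF",
    "dmso" = "DMSO", "dimethylsulfoxide" = "DMSO",
    "dimethyl sulfoxide" = "DMSO"
  )
}

canonical_solvent <- function(name, aliases = solvent_aliases()) {
  key <- tolower(trimws(name))
  out <- unname(aliases[key])
  out[is.na(out) & !is.na(name)] <- NA_character_
  out
}

#' Per-compound solvent tally
#'
#' Counts each canonical solvent once per compound (multiple entries of one
#' compound in the same solvent do not inflate the count), applies the alias
#' map, drops solvents below the occurrence threshold, and orders the
#' result by increasing dielectric constant.
#'
#' @param records deduplicated list of [compound_record()] objects.
#' @param min_count occurrence threshold (the validation chart uses 100).
#' @param dielectrics data.frame as from [solvent_dielectrics()].
#' @param aliases named vector as from [solvent_aliases()].
#' @return data.frame `solvent`, `count`, `dielectric`, ordered by
#'   dielectric; unrecognized names and their counts in
#'   `attr(, "unrecognized")`.
#' @export
solvent_tally <- function(records, min_count = 100,
                          dielectrics = solvent_dielectrics(),
                          aliases = solvent_aliases()) {
  per_compound <- lapply(records, function(r) {
    raw <- vapply(r$uvvis, function(e) {
      if (is_null_marker(e$solvent)) NA_character_ else e$solvent
    }, "")
    raw <- raw[!is.na(raw)]
    canon <- canonical_solvent(raw, aliases)
    list(known = unique(canon[!is.na(canon)]),
         unknown = unique(tolower(trimws(raw[is.na(canon)]))))
  })
  known <- unlist(lapply(per_compound, `[[`, "known"))
  unknown <- unlist(lapply(per_compound, `[[`, "unknown"))
  tab <- table(known)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  keep <- counts[counts >= min_count]
  if (length(keep)) {
    df <- data.frame(solvent = names(keep), count = unname(keep),
                     stringsAsFactors = FALSE)
    df <- merge(df, dielectrics, by = "solvent", all.x = TRUE, sort = FALSE)
    df <- df[order(df$dielectric), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(solvent = character(), count = integer(),
                     dielectric = numeric(), stringsAsFactors = FALSE)
  }
  unrec <- sort(table(unknown), decreasing = TRUE)
  structure(df, unrecognized = unrec)
}

#' Paired experimental vs computed wavelengths
#'
#' Walks a record set and pairs each compound's first experimental peak
#' wavelength with the first excited state of the requested computed block.
#'
#' @param records list of [compound_record()] objects.
#' @param source `"orca"` (sTDA) or `"nwchem"` (TD-DFT).
#' @return data.frame `inchikey`, `exp`, `calc`, `f` (oscillator strength),
#'   one row per compound that has both quantities.
#' @export
paired_wavelengths <- function(records, source = c("orca", "nwchem")) {
  source <- match.arg(source)
  rows <- lapply(records, function(r) {
    lam <- first_experimental_lambda(r)
    if (is.na(lam) || is.null(r$filtered)) return(NULL)
    blk <- Filter(function(b) b$source == source, r$filtered$blocks %||% list())
    if (!length(blk) || !length(blk[[1]]$states)) return(NULL)
    st <- blk[[1]]$states[[1]]
    data.frame(inchikey = r$inchikey, exp = lam, calc = st$wavelength,
               f = st$oscillator_strength, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(inchikey = character(), exp = numeric(),
                      calc = numeric(), f = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

first_experimental_lambda <- function(r) {
  for (e in r$uvvis) for (p in e$peaks) {
    if (!is.na(p$wavelength)) return(p$wavelength)
  }
  NA_real_
}
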