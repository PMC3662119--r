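#' Construct a rater panel
#'
#' Subjects x raters matrix of percent-density ratings in `[0, 100]` with no
#' missing cells (every rater reads every image).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @param subject_ids,rater_ids identifiers; defaults are generated.
#' @return An object of class `rater_panel`.
#' @export
rater_panel <- function(ratings, subject_ids = NULL, rater_ids = NULL) {
  ratings <- as.matrix(ratings)
  if (length(ratings) == 0L) {
    md_stop("empty rater panel", "mammodensity_error_spec")
  }
  if (anyNA(ratings)) {
    md_stop("rater panel must have no missing cells",
            "mammodensity_error_spec")
  }
  if (any(ratings < 0 | ratings > 100)) {
    md_stop("ratings must lie in [0, 100]", "mammodensity_error_spec")
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(ratings)))
  if (is.null(rater_ids)) rater_ids <- sprintf("R%d", seq_len(ncol(ratings)))
  stopifnot(length(subject_ids) == nrow(ratings),
            length(rater_ids) == ncol(ratings))
  dimnames(ratings) <- list(subject_ids, rater_ids)
  structure(
    list(ratings = ratings, subject_ids = as.character(subject_ids),
         rater_ids = as.character(rater_ids)),
    class = "rater_panel"
  )
}

#' @export
print.rater_panel <- function(x, ...) {
  cat(sprintf("<rater_panel> %d subjects x %d raters\n",
              nrow(x$ratings), ncol(x$ratings)))
  invisible(x)
}

#' Reference standard from a rater panel
#'
#' The per-subject median of the raters' visual assessments. With an even
#' number of raters the mean of the two central values is used (the usual
#' median convention; a five-rater panel never hits this case).
#'
#' @param panel a [rater_panel()] or a ratings matrix.
#' @return Numeric vector of per-subject reference densities (percent).
#' @export
reference_standard <- function(panel) {
  ratings <- if (inherits(panel, "rater_panel")) panel$ratings else
    as.matrix(panel)
  if (length(ratings) == 0L) {
    md_stop("empty rater panel", "mammodensity_error_spec")
  }
  apply(ratings, 1L, median)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measurement ICC from the two-way random-effects
#' ANOVA decomposition,
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with the 95% confidence interval by the McGraw--Wong F-distribution
#' method. This is the absolute-agreement form, the one asymptotically
#' equivalent to a quadratically weighted kappa. Consistency ICC(3,1) is
#' available as an alternate.
#'
#' @param ratings subjects x raters numeric matrix, no missing cells,
#'   at least 2 subjects and 2 raters.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A list with `icc`, `ci_low`, `ci_high`, the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`) and `n_subjects`, `n_raters`.
#' @export
icc_two_way <- function(ratings, type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    md_stop("ICC needs at least 2 subjects and 2 raters",
            "mammodensity_error_spec")
  }
  if (anyNA(x)) md_stop("ICC requires complete data", "mammodensity_error_spec")

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- max(ss_err / ((n - 1) * (k - 1)), 0)

  eps <- 1e-12 * max(abs(x), 1)^2
  if (msr < eps && mse < eps) {
    md_stop("undefined ICC: no between-subject and no error variance",
            "mammodensity_error_undefined")
  }

  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse < eps) return(list(icc = 1, ci_low = 1, ci_high = 1,
                               ms_rows = msr, ms_cols = msc, ms_error = mse,
                               n_subjects = n, n_raters = k, type = type))
    f_obs <- msr / mse
    fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse < eps && msc < eps) {
      # all raters identical: perfect agreement, degenerate CI
      return(list(icc = 1, ci_low = 1, ci_high = 1,
                  ms_rows = msr, ms_cols = msc, ms_error = mse,
                  n_subjects = n, n_raters = k, type = type))
    }
    if (mse < eps) {
      # no residual variance but systematic rater offsets: the F-based CI is
      # undefined; report the point estimate as a degenerate interval.
      return(list(icc = icc, ci_low = icc, ci_high = icc,
                  ms_rows = msr, ms_cols = msc, ms_error = mse,
                  n_subjects = n, n_raters = k, type = type))
    }
    # McGraw-Wong CI for ICC(A,1)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
       ms_rows = msr, ms_cols = msc, ms_error = mse,
       n_subjects = n, n_raters = k, type = type)
}

#' Interpret an ICC value on the conventional kappa scale
#'
#' 0.00--0.20 poor, 0.21--0.40 fair, 0.41--0.60 moderate, 0.61--0.80
#' substantial, 0.81--1.00 excellent (to perfect). Over a continuous ICC the
#' integer bin edges are read as: poor up to and including 0.20, fair above
#' 0.20 up to 0.40, and so on. Negative values are labelled poor.
#'
#' @param icc numeric in `[-1, 1]`.
#' @return Character label.
#' @export
icc_interpretation <- function(icc) {
  if (anyNA(icc) || any(icc < -1 | icc > 1)) {
    md_stop("icc must lie in [-1, 1]", "mammodensity_error_spec")
  }
  labels <- c("poor", "fair", "moderate", "substantial", "excellent")
  labels[findInterval(icc, c(0.20, 0.40, 0.60, 0.80), left.open = TRUE) + 1L]
}

#' Quadratically weighted kappa
#'
#' Cohen's kappa with quadratic disagreement weights
#' `w_ij = (i - j)^2 / (K - 1)^2` over an ordered category grid:
#' `kappa_w = 1 - sum(w O) / sum(w E)` where `O` is the observed and `E` the
#' chance-expected cross-tabulation. On the 21-point density grid this is the
#' chance-corrected agreement asymptotically equivalent to the
#' absolute-agreement ICC.
#'
#' @param ratings_a,ratings_b vectors of ratings on the same grid.
#' @param grid the ordered category grid (default `seq(0, 100, 5)`, the
#'   21-point density scale).
#' @return The weighted kappa.
#' @export
quadratic_weighted_kappa <- function(ratings_a, ratings_b,
                                     grid = seq(0, 100, by = 5)) {
  if (length(ratings_a) != length(ratings_b)) {
    md_stop("rating vectors must have equal length", "mammodensity_error_spec")
  }
  fa <- factor(ratings_a, levels = grid)
  fb <- factor(ratings_b, levels = grid)
  if (anyNA(fa) || anyNA(fb)) {
    md_stop("ratings contain values off the category grid",
            "mammodensity_error_spec")
  }
  n <- length(ratings_a)
  O <- table(fa, fb) / n
  pa <- rowSums(O)
  pb <- colSums(O)
  E <- outer(pa, pb)
  K <- length(grid)
  idx <- seq_len(K)
  w <- outer(idx, idx, function(i, j) (i - j)^2 / (K - 1)^2)
  denom <- sum(w * E)
  if (denom <= 0) {
    md_stop("weighted kappa undefined: no chance-expected disagreement (constant ratings)",
            "mammodensity_error_undefined")
  }
  1 - sum(w * O) / denom
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the standard product-moment correlation.
#' Kept as an explicit operation because the evaluation methodology contrasts
#' it with the ICC: a perfect linear relation gives `rho = 1` even when
#' absolute agreement is poor.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return The correlation coefficient.
#' @export
pearson_rho <- function(x, y) {
  if (length(x) != length(y)) {
    md_stop("vectors must have equal length", "mammodensity_error_spec")
  }
  if (length(x) < 3L) {
    md_stop("correlation needs at least 3 observations",
            "mammodensity_error_spec")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    md_stop("correlation undefined for zero-variance input",
            "mammodensity_error_undefined")
  }
  cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `reference - algorithm` (a positive bias means
#' the reference standard reads denser than the algorithm). The limits of
#' agreement are `bias +/- 1.96 * sd(differences)` with the sample (n-1)
#' standard deviation.
#'
#' @param reference,algorithm numeric vectors of percent densities, equal
#'   length, n >= 2.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `differences`, `means`.
#' @export
bland_altman <- function(reference, algorithm) {
  if (length(reference) != length(algorithm)) {
    md_stop("reference and algorithm vectors must have equal length",
            "mammodensity_error_spec")
  }
  if (length(reference) < 2L) {
    md_stop("Bland-Altman needs at least 2 paired observations",
            "mammodensity_error_spec")
  }
  d <- reference - algorithm
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s, differences = d, means = (reference + algorithm) / 2),
    class = "bland_altman"
  )
}

#' Proportion of subjects within one BI-RADS category
#'
#' Categorises both vectors with [birads_category()] and returns the
#' proportion of subjects whose categories differ by at most one level.
#'
#' @param reference,algorithm numeric vectors of percent densities.
#' @return Proportion in `[0, 1]`.
#' @export
within_one_birads <- function(reference, algorithm) {
  if (length(reference) != length(algorithm)) {
    md_stop("vectors must have equal length", "mammodensity_error_spec")
  }
  mean(abs(birads_category(reference) - birads_category(algorithm)) <= 1L)
}

#' Reference-density distribution per algorithm category
#'
#' For each algorithm-derived BI-RADS category, the five-number summary of
#' the reference-standard densities that fell into it, plus Tukey whisker
#' bounds (most extreme observations within 1.5 IQR of the quartile box).
#' Quartiles use R's default (type 7) convention. Categories with no
#' subjects are marked absent rather than raising an error.
#'
#' @param reference numeric vector of reference densities (percent).
#' @param algorithm_categories integer vector of categories 1..4.
#' @return A data frame with one row per category 1..4: `category`, `n`,
#'   `present`, `min`, `q1`, `median`, `q3`, `max`, `whisker_low`,
#'   `whisker_high`.
#' @export
category_distribution_summary <- function(reference, algorithm_categories) {
  if (length(reference) != length(algorithm_categories)) {
    md_stop("vectors must have equal length", "mammodensity_error_spec")
  }
  if (any(!algorithm_categories %in% 1:4)) {
    md_stop("categories must be integers 1..4", "mammodensity_error_spec")
  }
  rows <- lapply(1:4, function(cat) {
    v <- reference[algorithm_categories == cat]
    if (length(v) == 0L) {
      return(data.frame(category = cat, n = 0L, present = FALSE,
                        min = NA_real_, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, max = NA_real_,
                        whisker_low = NA_real_, whisker_high = NA_real_))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    wl <- min(v[v >= q[1] - 1.5 * iqr])
    wh <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(category = cat, n = length(v), present = TRUE,
               min = min(v), q1 = q[1], median = q[2], q3 = q[3],
               max = max(v), whisker_low = wl, whisker_high = wh)
  })
  do.call(rbind, rows)
}

#' Full agreement evaluation of an algorithm against a rater panel
#'
#' Composes the complete evaluation methodology: inter-rater ICC(2,1) with
#' 95% CI on the panel, the per-subject median reference standard, the
#' algorithm-vs-reference ICC(2,1), Pearson correlation, Bland-Altman bias
#' and limits of agreement, the within-one-BI-RADS-category proportion, and
#' per-category reference distributions. The decision rule flags the
#' algorithm as *promising* when its agreement with the reference standard
#' falls within (or above) the 95% CI of the radiologists' inter-rater ICC --
#' implemented as algorithm-vs-reference ICC >= the CI's lower bound, so an
#' algorithm agreeing with the reference better than the radiologists agree
#' among themselves is not disqualified.
#'
#' @param panel a [rater_panel()] (ratings in percent).
#' @param algorithm_densities numeric vector of algorithm percent densities,
#'   aligned with the panel's subjects.
#' @param conf_level confidence level for ICC intervals.
#' @return An object of class `agreement_report`.
#' @examples
#' panel <- simulate_rater_panel(runif(40), rater_model(seed = 2))
#' alg <- reference_standard(panel) # a perfect algorithm
#' evaluate_agreement(panel, alg)
#' @export
evaluate_agreement <- function(panel, algorithm_densities,
                               conf_level = 0.95) {
  if (!inherits(panel, "rater_panel")) panel <- rater_panel(panel)
  alg <- as.numeric(algorithm_densities)
  if (length(alg) != nrow(panel$ratings)) {
    md_stop("algorithm densities must align with the panel subjects",
            "mammodensity_error_spec")
  }
  panel_icc <- icc_two_way(panel$ratings, conf_level = conf_level)
  ref <- reference_standard(panel)
  alg_icc <- icc_two_way(cbind(reference = ref, algorithm = alg),
                         conf_level = conf_level)
  ba <- bland_altman(ref, alg)
  structure(
    list(
      n_subjects = length(ref),
      panel_icc = panel_icc$icc,
      panel_icc_ci = c(panel_icc$ci_low, panel_icc$ci_high),
      panel_icc_label = icc_interpretation(max(min(panel_icc$icc, 1), -1)),
      icc = alg_icc$icc,
      icc_ci_low = alg_icc$ci_low,
      icc_ci_high = alg_icc$ci_high,
      icc_label = icc_interpretation(max(min(alg_icc$icc, 1), -1)),
      pearson_rho = pearson_rho(ref, alg),
      bias = ba$bias,
      loa_low = ba$loa_low,
      loa_high = ba$loa_high,
      within_one_birads = within_one_birads(ref, alg),
      category_summary = category_distribution_summary(
        ref, birads_category(alg)),
      promising = alg_icc$icc >= panel_icc$ci_low,
      reference = ref,
      algorithm = alg,
      bland_altman = ba
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  subjects: %d\n", x$n_subjects))
  cat(sprintf("  panel ICC(2,1): %.3f, 95%% CI (%.3f, %.3f) [%s]\n",
              x$panel_icc, x$panel_icc_ci[1], x$panel_icc_ci[2],
              x$panel_icc_label))
  cat(sprintf("  algorithm vs reference ICC(2,1): %.3f, 95%% CI (%.3f, %.3f) [%s]\n",
              x$icc, x$icc_ci_low, x$icc_ci_high, x$icc_label))
  cat(sprintf("  Pearson rho: %.3f\n", x$pearson_rho))
  cat(sprintf("  Bland-Altman bias %.2f%%, limits (%.2f, %.2f)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  within one BI-RADS category: %.1f%%\n",
              100 * x$within_one_birads))
  cat(sprintf("  promising (ICC >= panel CI lower bound): %s\n", x$promising))
  invisible(x)
}
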