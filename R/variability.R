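#' Coefficient of variation
#'
#' Sample standard deviation (\eqn{n-1} denominator, the convention of the
#' standard statistical toolchains) divided by the mean.
#'
#' @param x Numeric vector, `n >= 2`, nonzero mean.
#' @return Scalar CV.
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("cv needs at least 2 values")
  m <- mean(x)
  if (m == 0) abort("cv undefined for zero mean")
  sd(x) / m
}

#' Bootstrap confidence interval of the CV
#'
#' Percentile interval over resamples with replacement. The percentile
#' bootstrap is the minimal reading of "bootstrap resampling"; a
#' bias-corrected-accelerated (BCa) variant is available by flag.
#'
#' @param x Numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param type `"percentile"` (default) or `"bca"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
cv_bootstrap_ci <- function(x, n_boot = 10000, seed = 1, level = 0.95,
                            type = c("percentile", "bca")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("bootstrap CI needs at least 2 values")
  stat <- with_seed_restore(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1, function(i) {
      xi <- x[i]
      s <- sd(xi)
      if (mean(xi) == 0) NA_real_ else s / mean(xi)
    })
  })
  stat <- stat[!is.na(stat)]
  alpha <- (1 - level) / 2
  if (type == "percentile") {
    ci <- unname(quantile(stat, c(alpha, 1 - alpha), type = 7))
  } else {
    theta <- cv(x)
    z0 <- stats::qnorm(mean(stat < theta))
    jack <- vapply(seq_len(n), function(i) cv(x[-i]), numeric(1))
    jm <- mean(jack)
    a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
    p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    ci <- unname(quantile(stat, c(p1, p2), type = 7))
  }
  setNames(ci, c("lower", "upper"))
}

# sufficient statistics for the CV tests
cv_suff <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2)) abort("every group needs at least 2 values")
  xbar <- vapply(groups, mean, numeric(1))
  if (any(xbar == 0)) abort("a group has zero mean; CV undefined")
  s2 <- vapply(groups, var, numeric(1))
  list(k = length(groups), n = n, xbar = xbar, s2 = s2)
}

as_group_list <- function(data) {
  if (is.data.frame(data) || is.matrix(data)) {
    data <- as.data.frame(data)
    data <- data[vapply(data, is.numeric, logical(1))]
    as.list(data)
  } else if (is.list(data)) data else abort("groups must be a data frame, matrix or list")
}

# -2 log likelihood difference between unconstrained normal fits and the
# common-CV constrained fit, from sufficient statistics. For fixed tau the
# constrained group means solve tau^2 mu^2 + xbar mu - (s2*(n-1)/n + xbar^2)=0,
# so the likelihood is profiled over tau alone.
cv_lrt_stat <- function(n, xbar, s2) {
  sig2f <- (n - 1) * s2 / n
  l_full <- -0.5 * sum(n * log(2 * pi * sig2f) + n)
  prof <- function(ltau) {
    tau2 <- exp(2 * ltau)
    mu <- (-xbar + sqrt(xbar^2 + 4 * tau2 * ((n - 1) * s2 / n + xbar^2))) /
      (2 * tau2)
    sig2 <- tau2 * mu^2
    ss <- (n - 1) * s2 + n * (xbar - mu)^2
    0.5 * sum(n * log(2 * pi * sig2) + ss / sig2)
  }
  tau0 <- sum((n - 1) * sqrt(s2) / abs(xbar)) / sum(n - 1)
  o <- optimize(prof, log(tau0) + c(-3, 3), tol = 1e-10)
  tau2 <- exp(2 * o$minimum)
  mu <- (-xbar + sqrt(xbar^2 + 4 * tau2 * ((n - 1) * s2 / n + xbar^2))) /
    (2 * tau2)
  list(stat = max(0, 2 * (l_full + o$objective)), tau = sqrt(tau2), mu = mu)
}

#' Modified signed-likelihood-ratio test for equality of CVs
#'
#' Tests the null hypothesis that k normal populations share one coefficient
#' of variation. The likelihood-ratio statistic is computed by profiling the
#' constrained likelihood over the common CV (the group means have a closed
#' form given the CV), and is then Bartlett-corrected by parametric
#' bootstrap: `nr` datasets are simulated under the fitted null, the mean
#' null statistic estimated, and the modified statistic
#' \eqn{(k-1)\,\Lambda / \bar\Lambda_{null}} referred to a chi-squared
#' distribution with \eqn{k-1} degrees of freedom.
#'
#' @param data A data frame/matrix with one numeric column per group, or a
#'   list of numeric vectors.
#' @param nr Number of parametric-bootstrap replicates for the correction.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `cv_test`: `statistic`, `df`, `p_value`, plus the
#'   uncorrected `lrt` and the estimated common CV `tau`.
#' @examples
#' set.seed(1)
#' mslrt_equal_cv(data.frame(a = rnorm(30, 10, 1), b = rnorm(30, 20, 2)))
#' @export
mslrt_equal_cv <- function(data, nr = 2000, seed = 1) {
  groups <- as_group_list(data)
  s <- cv_suff(groups)
  if (any(s$s2 == 0)) abort("a group has zero variance; the CV test is degenerate")
  obs <- cv_lrt_stat(s$n, s$xbar, s$s2)
  null_stats <- with_seed_restore(seed, {
    vapply(seq_len(nr), function(r) {
      xb <- numeric(s$k); v <- numeric(s$k)
      for (i in seq_len(s$k)) {
        xi <- rnorm(s$n[i], obs$mu[i], obs$tau * abs(obs$mu[i]))
        xb[i] <- mean(xi); v[i] <- var(xi)
      }
      cv_lrt_stat(s$n, xb, v)$stat
    }, numeric(1))
  })
  stat <- (s$k - 1) * obs$stat / mean(null_stats)
  structure(list(statistic = stat, df = s$k - 1,
                 p_value = pchisq(stat, s$k - 1, lower.tail = FALSE),
                 lrt = obs$stat, tau = obs$tau, nr = nr, seed = seed,
                 method = "modified signed-likelihood ratio test (equal CVs)"),
            class = "cv_test")
}

# Feltz-Miller asymptotic chi-squared test of equal CVs
asymptotic_cv_test <- function(groups) {
  s <- cv_suff(groups)
  m <- s$n - 1
  tau_i <- sqrt(s$s2) / abs(s$xbar)
  tau <- sum(m * tau_i) / sum(m)
  # all groups constant: CVs all zero, trivially equal
  stat <- if (tau == 0) 0 else
    sum(m * (tau_i - tau)^2) / (tau^2 * (0.5 + tau^2))
  list(statistic = stat, df = s$k - 1,
       p_value = pchisq(stat, s$k - 1, lower.tail = FALSE))
}

#' Pairwise asymptotic tests for equality of CVs
#'
#' All pairwise Feltz-Miller asymptotic chi-squared tests, with Bonferroni
#' multiplication (capped at 1) across the \eqn{k(k-1)/2} comparisons.
#'
#' @inheritParams mslrt_equal_cv
#' @return A list of class `cv_pairwise`: symmetric matrix `p_adjusted`
#'   (unit diagonal), matrix `p_raw`, and a tidy tibble `pairs`.
#' @export
pairwise_cv_tests <- function(data) {
  groups <- as_group_list(data)
  k <- length(groups)
  if (k < 2) abort("need at least two groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  n_pairs <- k * (k - 1) / 2
  p_raw <- matrix(1, k, k, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      res <- asymptotic_cv_test(groups[c(i, j)])
      p_raw[i, j] <- p_raw[j, i] <- res$p_value
      rows[[length(rows) + 1]] <-
        tibble(group1 = nm[i], group2 = nm[j], statistic = res$statistic,
               p_value = res$p_value,
               p_adjusted = min(1, res$p_value * n_pairs))
    }
  }
  p_adj <- p_raw * n_pairs     # pmin() would drop the dim attribute
  p_adj[p_adj > 1] <- 1
  diag(p_adj) <- 1
  structure(list(p_adjusted = p_adj, p_raw = p_raw, pairs = bind_rows(rows)),
            class = "cv_pairwise")
}

#' Full coefficient-of-variation report
#'
#' Per-parameter CV with bootstrap confidence interval, the global MSLRT for
#' equality of CVs, and the Bonferroni-corrected pairwise asymptotic tests.
#'
#' @inheritParams mslrt_equal_cv
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param level Confidence level.
#' @return A list of class `cv_report` with elements `cv` (tibble: parameter,
#'   cv, lower, upper), `mslrt` ([mslrt_equal_cv()] result) and `pairwise`
#'   ([pairwise_cv_tests()] result).
#' @export
cv_report <- function(data, n_boot = 10000, seed = 1, nr = 2000, level = 0.95) {
  groups <- as_group_list(data)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  cvtab <- bind_rows(map2(groups, seq_along(groups), function(g, i) {
    ci <- cv_bootstrap_ci(g, n_boot = n_boot, seed = seed + i, level = level)
    tibble(parameter = nm[i], cv = cv(g), lower = ci[["lower"]],
           upper = ci[["upper"]])
  }))
  structure(list(cv = cvtab,
                 mslrt = mslrt_equal_cv(data, nr = nr, seed = seed),
                 pairwise = pairwise_cv_tests(data)),
            class = "cv_report")
}

#' @export
print.cv_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.3f, df = %d, p = %.3g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  print(x$cv)
  print(x$mslrt)
  invisible(x)
}

#' @describeIn cv_report Tidy per-parameter table with the global test
#'   attached as columns `mslrt_statistic`, `mslrt_p`.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  mutate(x$cv, mslrt_statistic = x$mslrt$statistic, mslrt_p = x$mslrt$p_value)
}
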