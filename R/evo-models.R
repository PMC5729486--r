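#' Compare models of multivariate trait evolution
#'
#' Maximum-likelihood fits of three models of continuous trait evolution on a
#' time-calibrated tree, compared by AIC weights:
#' \describe{
#'   \item{BM}{Brownian motion; tip covariance proportional to shared branch
#'     length.}
#'   \item{OU}{single-optimum Ornstein-Uhlenbeck with pull strength
#'     \eqn{\alpha}; requires an ultrametric tree for the closed-form
#'     covariance.}
#'   \item{EB}{early burst, rate decaying as \eqn{e^{r t}} with
#'     \eqn{r \le 0}; reduces to BM as \eqn{r \to 0}.}
#' }
#' All models share one tree transformation across traits with a full
#' (unstructured) among-trait rate matrix, estimated analytically given the
#' transformation; OU's \eqn{\alpha} and EB's \eqn{r} are profiled over a
#' multi-start bounded search. Non-convergence is reported per model, never
#' silently.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param x Species-by-trait matrix (or data frame with `species` column).
#' @param models Subset of `c("BM", "OU", "EB")`.
#' @return A list of class `evo_model_set`; use [tidy()] for the
#'   model-comparison table.
#' @examples
#' tree <- generate_tree(16, seed = 1)
#' X <- trait_matrix(simulate_traits(tree, "BM", seed = 1, n_traits = 2))
#' tidy(fit_evo_models(tree, X))
#' @export
fit_evo_models <- function(tree, x, models = c("BM", "OU", "EB")) {
  Y <- align_tips(tree, if (is.matrix(x)) x else trait_matrix(x))
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  C <- ape::vcv(tree)[rownames(Y), rownames(Y)]
  n <- nrow(Y); p <- ncol(Y)
  Tdepth <- max(diag(C))

  loglik_for <- function(Cm) {
    # matrix-normal likelihood with analytic root state and rate matrix
    ch <- tryCatch(chol(Cm), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Cinv <- chol2inv(ch)
    ldetC <- 2 * sum(log(diag(ch)))
    one <- rep(1, n)
    a <- colSums(Cinv %*% Y) / sum(Cinv)
    R <- sweep(Y, 2, a)
    Rate <- crossprod(R, Cinv %*% R) / n
    ldetR <- determinant(Rate, logarithm = TRUE)
    if (ldetR$sign <= 0) return(list(ll = -Inf))
    ll <- -0.5 * (n * p * log(2 * pi) + n * as.numeric(ldetR$modulus) +
                    p * ldetC + n * p)
    list(ll = ll, root = a, rate = Rate)
  }

  fit_profiled <- function(transform, lower, upper, par_name) {
    grid <- seq(lower, upper, length.out = 10)
    vals <- vapply(grid, function(th) loglik_for(transform(th))$ll, numeric(1))
    if (all(!is.finite(vals))) {
      return(list(converged = FALSE, ll = -Inf, par = NA_real_))
    }
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    o <- optimize(function(th) loglik_for(transform(th))$ll, c(lo, hi),
                  maximum = TRUE, tol = 1e-8)
    # the optimum may sit on a boundary (e.g. EB collapsing onto BM at r = 0)
    cand <- c(o$maximum, lower, upper)
    lls <- vapply(cand, function(th) loglik_for(transform(th))$ll, numeric(1))
    par <- cand[which.max(lls)]
    best <- loglik_for(transform(par))
    list(converged = is.finite(best$ll), ll = best$ll, par = par,
         root = best$root, rate = best$rate)
  }

  fits <- list()
  if ("BM" %in% models) {
    f <- loglik_for(C)
    fits$BM <- list(model = "BM", logLik = f$ll, par = NULL,
                    root = f$root, rate = f$rate,
                    n_par = p + p * (p + 1) / 2, converged = is.finite(f$ll))
  }
  if ("OU" %in% models) {
    if (!is_ultrametric_tol(tree, 1e-4)) {
      warn("tree is not ultrametric; OU covariance uses the ultrametric closed form")
    }
    ou_vcv <- function(alpha) {
      if (alpha < 1e-10) return(C)
      V <- exp(-2 * alpha * (Tdepth - C)) * (1 - exp(-2 * alpha * C)) /
        (2 * alpha)
      V
    }
    f <- fit_profiled(ou_vcv, 1e-8, 50 / Tdepth, "alpha")
    fits$OU <- c(list(model = "OU", logLik = f$ll,
                      par = c(alpha = f$par), root = f$root, rate = f$rate,
                      n_par = p + p * (p + 1) / 2 + 1, converged = f$converged))
  }
  if ("EB" %in% models) {
    eb_vcv <- function(r) {
      if (abs(r) < 1e-10) return(C)
      (exp(r * C) - 1) / r
    }
    f <- fit_profiled(eb_vcv, log(1e-5) / Tdepth, 0, "r")
    fits$EB <- c(list(model = "EB", logLik = f$ll, par = c(r = f$par),
                      root = f$root, rate = f$rate,
                      n_par = p + p * (p + 1) / 2 + 1, converged = f$converged))
  }
  for (nm in names(fits)) {
    if (!isTRUE(fits[[nm]]$converged)) {
      warn(sprintf("model %s did not converge", nm))
    }
  }
  aic <- vapply(fits, function(f) 2 * f$n_par - 2 * f$logLik, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-0.5 * delta)
  w <- w / sum(w)
  for (i in seq_along(fits)) {
    fits[[i]]$AIC <- aic[i]
    fits[[i]]$weight <- w[i]
  }
  structure(list(fits = fits, n = n, p = p), class = "evo_model_set")
}

#' @describeIn fit_evo_models Model-comparison tibble: model, logLik, number
#'   of parameters, AIC, AIC weight, profiled parameter.
#' @param x An `evo_model_set`.
#' @param ... Unused.
#' @method tidy evo_model_set
#' @export
tidy.evo_model_set <- function(x, ...) {
  bind_rows(map(x$fits, function(f) {
    tibble(model = f$model, logLik = f$logLik, n_par = f$n_par, AIC = f$AIC,
           weight = f$weight,
           parameter = if (is.null(f$par)) NA_real_ else unname(f$par),
           converged = f$converged)
  }))
}

#' @describeIn fit_evo_models One-row summary naming the best model by AIC
#'   weight.
#' @method glance evo_model_set
#' @export
glance.evo_model_set <- function(x, ...) {
  tab <- tidy(x)
  best <- tab[which.max(tab$weight), ]
  tibble(best_model = best$model, best_weight = best$weight,
         n_species = x$n, n_traits = x$p)
}

#' @export
print.evo_model_set <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}
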