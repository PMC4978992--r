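# Model curves. The sigmoid is the 3-parameter logistic; the generalized
# logistic is the 4-parameter Richards curve, which reproduces the sigmoid
# exactly at shape nu = 1.
.trend_curve <- function(model_id, t, par) {
  switch(model_id,
    linear = par[["a"]] + par[["b"]] * t,
    sigmoid = par[["K"]] / (1 + exp(-par[["r"]] * (t - par[["m"]]))),
    generalized_logistic =
      par[["K"]] / (1 + exp(-par[["r"]] * (t - par[["m"]])))^(1 / par[["nu"]]),
    stop("unknown model_id: ", model_id))
}

.trend_par_names <- list(
  linear = c("a", "b"),
  sigmoid = c("K", "r", "m"),
  generalized_logistic = c("K", "r", "m", "nu"))

# Gaussian profile log-likelihood given residual sum of squares.
.gauss_loglik <- function(rss, n) {
  sigma2 <- max(rss / n, 1e-20)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)` with `k` the number of free
#' parameters including the residual scale.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of parameters (including sigma).
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a trend model to a cumulative range curve
#'
#' Maximum-likelihood fit under iid Gaussian residuals of a linear, sigmoid
#' (3-parameter logistic), or generalized logistic (Richards) curve to a
#' cumulative total-range series. The curve is normalised by its maximum
#' before fitting (so parameters are comparable across clades); pass
#' `normalize = FALSE` for raw-scale fits. Nonlinear models use multi-start
#' Nelder-Mead/BFGS optimisation with seeded random restarts.
#'
#' @param t time since clade origin (Myr), increasing.
#' @param y cumulative total range values (km^2 or normalised).
#' @param model_id `"linear"`, `"sigmoid"` or `"generalized_logistic"`.
#' @param normalize divide `y` by `max(y)` before fitting (default `TRUE`).
#' @param n_starts number of random restarts for nonlinear fits.
#' @param seed RNG seed for the restarts.
#' @return a `trend_model_fit` list: `model_id`, `parameters`, `sigma`,
#'   `loglik`, `aicc`, `n_params`, `converged`.
#' @export
fit_trend <- function(t, y, model_id = c("linear", "sigmoid",
                                         "generalized_logistic"),
                      normalize = TRUE, n_starts = 10L, seed = 1L) {
  model_id <- match.arg(model_id)
  stopifnot(length(t) == length(y), length(t) >= 5)
  if (normalize) y <- y / max(y)
  n <- length(y)
  if (model_id == "linear") {
    fit <- stats::lm.fit(cbind(1, t), y)
    rss <- sum(fit$residuals^2)
    par <- c(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]))
    ll <- .gauss_loglik(rss, n)
    k <- 3L
    out <- list(model_id = model_id, parameters = par,
                sigma = sqrt(max(rss / n, 0)), loglik = ll,
                aicc = aicc(ll, k, n), n_params = k, converged = TRUE)
    class(out) <- "trend_model_fit"
    return(out)
  }
  pn <- .trend_par_names[[model_id]]
  # optimise on transformed scale: K, r, nu > 0 via log.
  to_par <- function(theta) {
    p <- c(K = exp(theta[1]), r = exp(theta[2]), m = theta[3])
    if (model_id == "generalized_logistic") p <- c(p, nu = exp(theta[4]))
    p
  }
  obj <- function(theta) {
    p <- to_par(theta)
    mu <- .trend_curve(model_id, t, as.list(p))
    if (any(!is.finite(mu))) return(1e10)
    sum((y - mu)^2)
  }
  rng <- range(t)
  base_start <- c(log(max(y)), log(2 / max(diff(rng), 1)), mean(rng))
  if (model_id == "generalized_logistic") base_start <- c(base_start, 0)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th0 <- if (s == 1) base_start else
      base_start + stats::rnorm(length(base_start),
                                sd = c(0.3, 1, diff(rng) / 4,
                                       1)[seq_along(base_start)])
    o <- tryCatch(
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o)) {
      o <- tryCatch(
        stats::optim(o$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) o)
    }
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("trend fit failed to converge for ", model_id,
         " after ", n_starts, " starts")
  par <- to_par(best$par)
  names(par) <- pn
  rss <- best$value
  ll <- .gauss_loglik(rss, n)
  k <- length(pn) + 1L
  out <- list(model_id = model_id, parameters = par,
              sigma = sqrt(max(rss / n, 0)), loglik = ll,
              aicc = aicc(ll, k, n), n_params = k,
              converged = isTRUE(best$convergence == 0))
  class(out) <- "trend_model_fit"
  out
}

#' Select the best trend model by AICc
#'
#' Returns the model with the smallest AICc; ties (difference below `tol`)
#' are broken toward the model with fewer parameters.
#'
#' @param fits list of `trend_model_fit` objects on identical data.
#' @param tol AICc tie tolerance.
#' @return the winning `model_id`.
#' @export
select_best <- function(fits, tol = 0.01) {
  stopifnot(length(fits) >= 1)
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  cand <- which(a <= min(a) + tol)
  winner <- cand[which.min(k[cand])]
  fits[[winner]]$model_id
}

#' Fit all three trend models and pick the best
#'
#' @inheritParams fit_trend
#' @return list with per-model fits and `best_model`.
#' @export
compare_trends <- function(t, y, normalize = TRUE, n_starts = 10L, seed = 1L) {
  fits <- lapply(c("linear", "sigmoid", "generalized_logistic"),
                 function(m) fit_trend(t, y, m, normalize = normalize,
                                       n_starts = n_starts, seed = seed))
  names(fits) <- c("linear", "sigmoid", "generalized_logistic")
  list(fits = fits, best_model = select_best(fits))
}
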