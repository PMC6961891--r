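#' Deterministic Ricker map
#'
#' One step of the discrete-time Ricker model
#' \deqn{N_{t+1} = N_t \exp\{r (1 - N_t / K)\},}
#' the density-dependent expectation used both for fitting segments and
#' for simulating series. `n` equal to `K` is the fixed point; `r = 0`
#' is the identity.
#'
#' @param n Current abundance, positive and finite (vectorised).
#' @param r Intrinsic per-step growth rate (dimensionless).
#' @param k Carrying capacity, in abundance units; must be > 0.
#' @return Expected abundance at the next step (no noise added).
#' @examples
#' ricker_step(3000, r = 2, k = 2000)  # 3000 * exp(-1)
#' @export
ricker_step <- function(n, r, k) {
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("abundance `n` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(r) || !is.finite(k) || k <= 0) {
    stop("need finite `r` and `k` > 0", call. = FALSE)
  }
  n * exp(r * (1 - n / k))
}

#' Fit the Ricker model to one contiguous segment
#'
#' Least-squares fit of the Ricker map to the transition pairs of a
#' segment, by Levenberg-Marquardt (via \pkg{minpack.lm}), minimising
#' \eqn{\sum_t (N_{t+1} - N_t e^{r(1 - N_t/K)})^2}. The segment is
#' addressed in break coordinates: `[start_year, end_year]` contributes
#' the transitions `start_year -> start_year+1`, ..., `end_year-1 ->
#' end_year`, so `n_obs = end_year - start_year` and consecutive
#' segments that share a boundary year never share a transition.
#'
#' Starting values are `r = 1` and `K = mean(abundance)` over the
#' segment; `K` is bounded below at a tiny positive multiple of the mean
#' to prevent sign-flip degeneracy, `r` is unbounded. Standard errors
#' come from the Jacobian-based covariance at the solution scaled by
#' `rss / (n_obs - 2)`, the usual nonlinear least-squares estimate. A
#' series sitting exactly at equilibrium fits every `r` equally well;
#' such non-identifiability surfaces as huge or `NA` standard errors,
#' not as an error.
#'
#' @param series A [population_series] (or data.frame with `year`,
#'   `abundance`).
#' @param start_year,end_year Segment bounds in break coordinates
#'   (defaults: the whole series).
#' @return An object of class `segment_fit`: list with elements
#'   `start_year`, `end_year`, `r`, `k`, `sigma` (`sqrt(rss/n_obs)`),
#'   `se_r`, `se_k`, `rss`, `n_obs`, `converged`, `message`.
#' @export
fit_ricker <- function(series, start_year = NULL, end_year = NULL) {
  series <- as_population_series(series)
  if (is.null(start_year)) start_year <- series$year[1L]
  if (is.null(end_year)) end_year <- series$year[nrow(series)]
  i0 <- match(start_year, series$year)
  i1 <- match(end_year, series$year)
  if (is.na(i0) || is.na(i1) || i1 <= i0) {
    stop("segment [", start_year, ", ", end_year,
         "] is not within the series", call. = FALSE)
  }
  nt <- series$abundance[i0:(i1 - 1L)]
  nt1 <- series$abundance[(i0 + 1L):i1]
  n_obs <- length(nt)
  if (n_obs < 3L) {
    stop("segment has ", n_obs, " transition pair(s); need at least 3 ",
         "(4 sequential data points)", call. = FALSE)
  }
  kbar <- mean(c(nt, nt1))
  resid_fun <- function(p) nt1 - nt * exp(p[[1L]] * (1 - nt / p[[2L]]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(r = 1, K = kbar),
      lower = c(-Inf, 1e-9 * kbar),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  out <- list(start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              r = NA_real_, k = NA_real_, sigma = NA_real_,
              se_r = NA_real_, se_k = NA_real_,
              rss = NA_real_, n_obs = n_obs,
              converged = FALSE, message = "")
  class(out) <- "segment_fit"
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  out$r <- unname(fit$par[1L])
  out$k <- unname(fit$par[2L])
  out$rss <- fit$deviance
  out$sigma <- sqrt(fit$deviance / n_obs)
  out$message <- fit$message
  out$converged <- fit$info %in% c(1L, 2L, 3L, 4L) &&
    all(is.finite(unlist(fit$par))) && is.finite(fit$deviance)
  se <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance / max(n_obs - 2L, 1L)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  out$se_r <- unname(se[1L])
  out$se_k <- unname(se[2L])
  out
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("Ricker segment fit [%d, %d] (%d transitions)\n",
              x$start_year, x$end_year, x$n_obs))
  cat(sprintf("  r = %.4g +/- %.3g   K = %.4g +/- %.3g\n",
              x$r, x$se_r, x$k, x$se_k))
  cat(sprintf("  rss = %.6g   sigma = %.4g   converged: %s\n",
              x$rss, x$sigma, x$converged))
  invisible(x)
}

#' Information criterion of a fitted segment
#'
#' Gaussian least-squares form with `n` the number of transition pairs
#' and `k = 3` estimated parameters (r, K, residual variance):
#' `AIC = n log(rss/n) + 2k`, and
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`. Lower is better. AICc requires
#' `n >= k + 2`; shorter segments raise an error instructing the caller
#' to raise the minimum segment size or switch to AIC.
#'
#' `rss_floor` (absolute, same units as rss) guards the log for
#' near-perfect fits: the rss entering the criterion is
#' `max(rss, rss_floor)`. The detector sets it from the series scale so
#' that on noiseless data the ranking degrades gracefully to the
#' parsimony penalty instead of comparing logs of rounding error.
#'
#' @param fit A `segment_fit` (from [fit_ricker]), or any list with
#'   finite `rss` and `n_obs`.
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @param rss_floor Non-negative lower bound applied to the rss.
#' @return The criterion value (scalar).
#' @export
segment_ic <- function(fit, criterion = c("AICc", "AIC"), rss_floor = 0) {
  criterion <- match.arg(criterion)
  k <- 3
  n <- fit$n_obs
  rss <- max(fit$rss, rss_floor)
  if (!isTRUE(fit$converged) && !is.null(fit$converged)) {
    return(Inf)
  }
  if (!is.finite(rss) || rss < 0 || !is.finite(n) || n < 1) {
    return(Inf)
  }
  aic <- n * log(rss / n) + 2 * k
  if (criterion == "AIC") return(aic)
  if (n - k - 1 <= 0) {
    stop("AICc undefined for a segment with ", n, " transition pairs ",
         "(need n >= ", k + 2, "); raise `min_segment` or use ",
         "criterion = \"AIC\"", call. = FALSE)
  }
  aic + 2 * k * (k + 1) / (n - k - 1)
}
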