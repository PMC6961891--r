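#' Simulate a Ricker population time series with dynamic shifts
#'
#' Iterates the stochastic Ricker map
#' `N[t+1] = N[t] * exp(r * (1 - N[t]/K)) * (1 + eta[t])` with
#' multiplicative Gaussian noise `eta ~ Normal(0, tau)`, i.e. noise
#' scales with the expected population size. At each break position the
#' current parameters are shifted by the given percentages — a break
#' "after point j" means the transition from point j to point j+1
#' already runs under the new rule, matching the segment convention of
#' the detector. Successive shifts compound multiplicatively on the
#' current values. The sign of each shift is drawn uniformly at random
#' per break and per parameter unless given via `signs`.
#'
#' A noise draw that would push abundance to zero or below is redrawn
#' (rather than truncated, which would bias the noise mean); this is
#' only conceivable at extreme `tau`.
#'
#' @param length Number of annual time steps (default 20).
#' @param n1 Initial abundance (default 3000; away from `k` so the
#'   approach to equilibrium identifies the parameters).
#' @param r,k Initial growth rate and carrying capacity (defaults 2 and
#'   2000).
#' @param breaks Integer break positions ("after point j"), `1 <= j <
#'   length`; must leave every run of points at least `min_segment`
#'   long.
#' @param delta_r,delta_k Per-break fractional changes of `r` and `k`
#'   (defaults 0.25 and 0.75, i.e. +/-25% and +/-75%); 0 means the
#'   parameter does not shift.
#' @param tau Noise standard deviation as a fraction of the expected
#'   population size (default 0.02).
#' @param start_year First year label (default 1).
#' @param min_segment Admissibility check for `breaks` (default 4).
#' @param seed Optional integer seed; the global RNG state is restored
#'   on exit.
#' @param signs Optional list with elements `r` and `k`, each a vector
#'   of +/-1 per break, overriding the random sign draw.
#' @return A [population_series] with attributes `true_breaks` (break
#'   years), `regimes` (data.frame of per-regime parameters) and
#'   `scenario` (the generating parameters).
#' @examples
#' simulate_ricker(length = 20, breaks = c(8, 14), seed = 7)
#' @export
simulate_ricker <- function(length = 20, n1 = 3000, r = 2, k = 2000,
                            breaks = integer(), delta_r = 0.25,
                            delta_k = 0.75, tau = 0.02, start_year = 1,
                            min_segment = 4, seed = NULL, signs = NULL) {
  length <- as.integer(length)
  breaks <- sort(as.integer(breaks))
  if (length < 4L) stop("`length` must be at least 4", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (n1 <= 0 || k <= 0) stop("`n1` and `k` must be > 0", call. = FALSE)
  if (length(breaks)) {
    if (any(breaks < 1L) || any(breaks >= length)) {
      stop("break positions must lie in [1, length - 1]", call. = FALSE)
    }
    parts <- diff(c(0L, breaks, length))
    if (any(parts < min_segment)) {
      stop("inadmissible breaks: every segment needs at least ",
           min_segment, " data points", call. = FALSE)
    }
  }
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  nb <- length(breaks)
  if (is.null(signs)) {
    signs <- list(r = sample(c(-1, 1), nb, replace = TRUE),
                  k = sample(c(-1, 1), nb, replace = TRUE))
  }
  stopifnot(length(signs$r) == nb, length(signs$k) == nb)
  cur_r <- r
  cur_k <- k
  regimes <- data.frame(start = 1L, end = length,
                        r = cur_r, k = cur_k)
  abundance <- numeric(length)
  abundance[1L] <- n1
  for (t in seq_len(length - 1L)) {
    bi <- match(t, breaks)
    if (!is.na(bi)) {
      cur_r <- cur_r * (1 + signs$r[bi] * delta_r)
      cur_k <- cur_k * (1 + signs$k[bi] * delta_k)
      regimes$end[nrow(regimes)] <- t
      regimes <- rbind(regimes, data.frame(start = t, end = length,
                                           r = cur_r, k = cur_k))
    }
    expected <- ricker_step(abundance[t], cur_r, cur_k)
    repeat {
      eta <- if (tau > 0) stats::rnorm(1L, 0, tau) else 0
      nxt <- expected * (1 + eta)
      if (is.finite(nxt) && nxt > 0) break
    }
    abundance[t + 1L] <- nxt
  }
  years <- seq.int(start_year, length.out = length)
  out <- population_series(years, abundance)
  attr(out, "true_breaks") <- if (nb) years[breaks] else integer(0)
  attr(out, "true_break_positions") <- breaks
  regimes$start_year <- years[regimes$start]
  regimes$end_year <- years[regimes$end]
  attr(out, "regimes") <- regimes
  attr(out, "scenario") <- list(length = length, n1 = n1, r = r, k = k,
                                delta_r = delta_r, delta_k = delta_k,
                                tau = tau, breaks = breaks,
                                signs = signs, seed = seed)
  out
}

#' True break years of a simulated series
#'
#' @param series A series produced by [simulate_ricker].
#' @return Integer vector of break years (possibly empty).
#' @export
true_breaks <- function(series) {
  tb <- attr(series, "true_breaks")
  if (is.null(tb)) stop("series carries no ground-truth break record",
                        call. = FALSE)
  tb
}

#' Draw random break locations
#'
#' Uniform draw from the set of admissible break sets of the requested
#' size — every segment keeps at least `min_segment` data points. When
#' a `criterion` is given, the draw is further restricted to break sets
#' whose every segment carries enough transition pairs for that
#' criterion to be finite, so that simulated truths stay inside the
#' model space the detector searches.
#'
#' @param series_length Number of data points.
#' @param n_breaks Number of breaks to place.
#' @param min_segment Minimum data points per segment (default 4).
#' @param criterion Optional `"AICc"` or `"AIC"` (see above).
#' @return Sorted integer vector of break positions.
#' @examples
#' random_breaks(8, 1)  # always "after point 4"
#' @export
random_breaks <- function(series_length, n_breaks, min_segment = 4,
                          criterion = NULL) {
  sets <- if (is.null(criterion)) {
    enumerate_breaks(series_length, min_segment)
  } else {
    scoreable_breaks(series_length, min_segment, criterion)
  }
  sets <- sets[lengths(sets) == n_breaks]
  if (!length(sets)) {
    stop("no admissible placement of ", n_breaks, " break(s) in ",
         series_length, " points with minimum segment ", min_segment,
         if (!is.null(criterion)) paste0(" under ", criterion) else "",
         call. = FALSE)
  }
  sets[[sample.int(length(sets), 1L)]]
}

#' The full simulation scenario grid
#'
#' Builds the 94-scenario design used to benchmark the detector:
#' 40 scenarios crossing starting growth rate `r0 in {0.5, 1, 1.5, 2}`
#' with five percent-changes in `r` and five in `K`; 50 crossing noise
#' `tau in {1, 2, 5, 10, 15}%` with the same two change grids; and 4
#' varying series length in `{15, 20, 25, 30}`. Parameters not being
#' varied sit at base values: `N1 = 3000`, `K = 2000`, `r0 = 2`,
#' `delta_r = 25%`, `delta_k = 75%`, `tau = 2%`, length 20. The base
#' combination recurs across families by construction, exactly as the
#' grid is counted.
#'
#' @return A data.frame with one row per scenario: `scenario_id`,
#'   `family`, `r0`, `delta_r`, `delta_k`, `tau`, `length`, `n1`, `k0`.
#' @export
scenario_grid <- function() {
  base <- list(r0 = 2, delta_r = 0.25, delta_k = 0.75, tau = 0.02,
               length = 20L, n1 = 3000, k0 = 2000)
  deltas <- c(0, 0.10, 0.25, 0.50, 0.75)
  rows <- list()
  add <- function(family, ...) {
    v <- utils::modifyList(base, list(...))
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, r0 = v$r0, delta_r = v$delta_r,
      delta_k = v$delta_k, tau = v$tau, length = v$length,
      n1 = v$n1, k0 = v$k0
    )
  }
  for (r0 in c(0.5, 1, 1.5, 2)) {
    for (dr in deltas) add("r0 x delta_r", r0 = r0, delta_r = dr)
    for (dk in deltas) add("r0 x delta_k", r0 = r0, delta_k = dk)
  }
  for (tau in c(0.01, 0.02, 0.05, 0.10, 0.15)) {
    for (dr in deltas) add("tau x delta_r", tau = tau, delta_r = dr)
    for (dk in deltas) add("tau x delta_k", tau = tau, delta_k = dk)
  }
  for (len in c(15L, 20L, 25L, 30L)) add("length", length = len)
  out <- do.call(rbind, rows)
  out$scenario_id <- seq_len(nrow(out))
  out[c("scenario_id", "family", "r0", "delta_r", "delta_k", "tau",
        "length", "n1", "k0")]
}

#' Write a simulated series plus its ground truth to disk
#'
#' Emits the series as a two-column CSV (year, abundance) and a JSON
#' sidecar (`<path>.truth.json`) recording the generating scenario,
#' true break years and seed — the fixture format consumed by
#' [read_series_csv] and downstream regression tests.
#'
#' @param series Output of [simulate_ricker].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_simulated_series <- function(series, path) {
  write_series_csv(series, path)
  sc <- attr(series, "scenario")
  truth <- list(
    true_breaks = as.integer(attr(series, "true_breaks")),
    scenario = sc[c("length", "n1", "r", "k", "delta_r", "delta_k",
                    "tau")],
    signs = sc$signs,
    seed = sc$seed
  )
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
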