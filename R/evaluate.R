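#' Is the true break set among the top candidates?
#'
#' Detection requires the *exact* ground-truth break set (set equality,
#' not containment) to appear among the equivalence-set combinations —
#' the top-ranked combination and those within the equivalence window
#' of it. A combination with the true breaks plus an extra one does not
#' count.
#'
#' @param ranking A `shift_ranking` from [detect_shifts].
#' @param true_break_years Integer vector of true break years (empty
#'   for a no-shift series).
#' @return Logical flag.
#' @export
contains_true_breaks <- function(ranking, true_break_years) {
  stopifnot(inherits(ranking, "shift_ranking"))
  truth <- sort(as.integer(true_break_years))
  eq <- ranking$candidates$breaks[ranking$candidates$in_equivalence]
  any(vapply(eq, function(b) identical(sort(as.integer(b)), truth),
             logical(1)))
}

# Deterministic per-replicate seed, kept below 2^31.
derive_seed <- function(seed, scenario_id, n_breaks, rep) {
  (((seed %% 1e6) * 1000003 + scenario_id * 97561 +
      n_breaks * 1299721 + rep * 7919) %% 2147483629) + 1
}

#' Run one simulation scenario through the detector
#'
#' For each break count and replicate: draw a ground-truth break set
#' uniformly from the sets the configured criterion can score (so that
#' the simulated truth always lies inside the detector's model space),
#' simulate the series, run [detect_shifts], and record whether the
#' exact true break set appears in the equivalence set, together with
#' every reported break weight partitioned into true vs erroneous by
#' exact year match. Break counts with no admissible placement for the
#' scenario's series length are skipped with a message; replicates
#' where the detector fails outright are counted separately and
#' excluded from the accuracy denominator.
#'
#' @param scenario One row of [scenario_grid()] (or a list with fields
#'   `r0`, `delta_r`, `delta_k`, `tau`, `length`, `n1`, `k0`, and
#'   optionally `scenario_id`).
#' @param n_breaks Integer vector of break counts to simulate (default
#'   `0:3`).
#' @param n_reps Replicates per break count (default 100; the full
#'   study design uses 250).
#' @param seed Base seed; every replicate derives its own seed from it.
#' @param criterion,min_segment Passed to [detect_shifts] and used for
#'   truth placement.
#' @return A list of class `scenario_result`: `replicates` (one row per
#'   replicate: detected flag, failure flag, true breaks), `weights`
#'   (one row per reported break: year, weight, true/erroneous) and
#'   `scenario`.
#' @export
run_scenario <- function(scenario, n_breaks = 0:3, n_reps = 100,
                         seed = 1, criterion = "AICc", min_segment = 4) {
  sc <- as.list(scenario)
  sid <- if (!is.null(sc$scenario_id)) sc$scenario_id else 0L
  len <- as.integer(sc$length)
  feasible <- vapply(n_breaks, function(nb) {
    sets <- scoreable_breaks(len, min_segment, criterion)
    any(lengths(sets) == nb)
  }, logical(1))
  if (any(!feasible)) {
    message("scenario ", sid, ": skipping infeasible break count(s) ",
            paste(n_breaks[!feasible], collapse = ", "),
            " for series length ", len)
  }
  reps <- list()
  wts <- list()
  for (nb in n_breaks[feasible]) {
    for (rep in seq_len(n_reps)) {
      rseed <- derive_seed(seed, sid, nb, rep)
      set.seed(rseed)
      truth_pos <- if (nb > 0) {
        random_breaks(len, nb, min_segment, criterion)
      } else integer(0)
      series <- simulate_ricker(
        length = len, n1 = sc$n1, r = sc$r0, k = sc$k0,
        breaks = truth_pos, delta_r = sc$delta_r, delta_k = sc$delta_k,
        tau = sc$tau, min_segment = min_segment
      )
      truth_years <- true_breaks(series)
      ranking <- tryCatch(
        suppressWarnings(detect_shifts(series, criterion = criterion,
                                       min_segment = min_segment)),
        error = function(e) NULL
      )
      failed <- is.null(ranking)
      detected <- if (failed) NA else contains_true_breaks(ranking,
                                                           truth_years)
      reps[[length(reps) + 1L]] <- data.frame(
        scenario_id = sid, n_breaks = nb, rep = rep, seed = rseed,
        failed = failed, detected = detected,
        n_true = length(truth_years)
      )
      if (!failed && nrow(ranking$break_table)) {
        bt <- ranking$break_table
        wts[[length(wts) + 1L]] <- data.frame(
          scenario_id = sid, n_breaks = nb, rep = rep,
          year = bt$year, weight = bt$weight,
          true = bt$year %in% truth_years
        )
      }
    }
  }
  structure(list(
    replicates = do.call(rbind, reps),
    weights = if (length(wts)) do.call(rbind, wts) else
      data.frame(scenario_id = integer(), n_breaks = integer(),
                 rep = integer(), year = integer(), weight = numeric(),
                 true = logical()),
    scenario = sc,
    config = list(n_breaks = n_breaks, n_reps = n_reps, seed = seed,
                  criterion = criterion, min_segment = min_segment)
  ), class = "scenario_result")
}

#' Detection accuracy of a scenario run
#'
#' The fraction of (non-failed) replicates whose equivalence set
#' contained the exact true break set, with a Monte-Carlo standard
#' error, overall and per break count.
#'
#' @param result A `scenario_result` from [run_scenario].
#' @return List with `accuracy`, `mc_se`, `n`, `n_failed` and a
#'   per-break-count data.frame `by_n_breaks`.
#' @export
scenario_accuracy <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  r <- result$replicates
  ok <- !r$failed
  acc <- mean(r$detected[ok])
  n <- sum(ok)
  by_nb <- do.call(rbind, lapply(split(r[ok, ], r$n_breaks[ok]),
                                 function(d) {
    data.frame(n_breaks = d$n_breaks[1L], n = nrow(d),
               accuracy = mean(d$detected),
               mc_se = stats::sd(d$detected) / sqrt(nrow(d)))
  }))
  rownames(by_nb) <- NULL
  list(accuracy = acc, mc_se = stats::sd(r$detected[ok]) / sqrt(n),
       n = n, n_failed = sum(r$failed), by_n_breaks = by_nb)
}

#' Average weights of true vs erroneous reported breaks
#'
#' Pools every break reported across replicates and averages the break
#' weights within the two ground-truth partitions: breaks whose year
#' exactly matches a simulated break ("true") and all others
#' ("erroneous"). An empty partition is reported as `NA` (absent), not
#' zero.
#'
#' @param result A `scenario_result`, or a data.frame with columns
#'   `weight` and `true`.
#' @return List with `true_avg`, `erroneous_avg`, `n_true`,
#'   `n_erroneous`.
#' @export
average_break_weights <- function(result) {
  w <- if (inherits(result, "scenario_result")) result$weights else result
  stopifnot(all(c("weight", "true") %in% names(w)))
  tw <- w$weight[w$true]
  ew <- w$weight[!w$true]
  list(true_avg = if (length(tw)) mean(tw) else NA_real_,
       erroneous_avg = if (length(ew)) mean(ew) else NA_real_,
       n_true = length(tw), n_erroneous = length(ew))
}

#' @export
print.scenario_result <- function(x, ...) {
  a <- scenario_accuracy(x)
  b <- average_break_weights(x)
  cat(sprintf("Scenario run: %d replicates (%d failed), criterion %s\n",
              nrow(x$replicates), a$n_failed, x$config$criterion))
  cat(sprintf("  accuracy (exact true set in top set): %.3f +/- %.3f\n",
              a$accuracy, a$mc_se))
  cat(sprintf("  mean break weight: true %.3f (n=%d), erroneous %.3f (n=%d)\n",
              b$true_avg, b$n_true, b$erroneous_avg, b$n_erroneous))
  invisible(x)
}

#' Benchmark the detector across a scenario grid
#'
#' Runs [run_scenario] for each row of a scenario grid and returns one
#' tidy row per scenario x break count — the structure behind the
#' accuracy and break-weight summaries of the simulation study.
#'
#' @param grid A data.frame as returned by [scenario_grid()] (any
#'   subset of rows).
#' @inheritParams run_scenario
#' @return data.frame with scenario parameters, accuracy, Monte-Carlo
#'   standard error, failure count and mean true/erroneous break
#'   weights per break count.
#' @export
benchmark_grid <- function(grid, n_breaks = 0:3, n_reps = 100, seed = 1,
                           criterion = "AICc", min_segment = 4) {
  out <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_scenario(grid[i, ], n_breaks = n_breaks, n_reps = n_reps,
                        seed = seed, criterion = criterion,
                        min_segment = min_segment)
    a <- scenario_accuracy(res)
    do.call(rbind, lapply(seq_len(nrow(a$by_n_breaks)), function(j) {
      nb <- a$by_n_breaks$n_breaks[j]
      w <- average_break_weights(
        res$weights[res$weights$n_breaks == nb, ])
      cbind(grid[i, ], data.frame(
        run_n_breaks = nb, n = a$by_n_breaks$n[j],
        accuracy = a$by_n_breaks$accuracy[j],
        mc_se = a$by_n_breaks$mc_se[j],
        n_failed = sum(res$replicates$failed[
          res$replicates$n_breaks == nb]),
        true_weight = w$true_avg, erroneous_weight = w$erroneous_avg
      ))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
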