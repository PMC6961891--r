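#' Enumerate admissible break-point combinations
#'
#' A break "after point j" splits the series between the j-th and
#' (j+1)-th data points. A combination is admissible when every
#' resulting run of sequential data points contains at least
#' `min_segment` points, i.e. admissible break sets are exactly the
#' compositions of `n_points` into parts `>= min_segment`. The empty
#' set (no break) is always included. Enumeration is constructive
#' (recursive placement of the next break), not subset filtering.
#'
#' @param n_points Number of data points in the series.
#' @param min_segment Minimum number of sequential data points per
#'   segment (default 4, the overfitting guard).
#' @param max_breaks Optional cap on the number of breaks, for long
#'   series where exhaustive enumeration grows combinatorially.
#' @return List of strictly increasing integer vectors of break
#'   positions, in canonical order: by number of breaks, then
#'   lexicographically.
#' @examples
#' enumerate_breaks(12, 4)  # 7 combinations
#' @export
enumerate_breaks <- function(n_points, min_segment = 4, max_breaks = NULL) {
  n_points <- as.integer(n_points)
  min_segment <- as.integer(min_segment)
  if (n_points < min_segment) {
    stop("series of ", n_points, " points is shorter than the minimum ",
         "segment (", min_segment, ")", call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 64L)
  acc$n <- 0L
  push <- function(v) {
    if (acc$n == length(acc$out)) acc$out <- c(acc$out, vector("list", acc$n))
    acc$n <- acc$n + 1L
    acc$out[[acc$n]] <- v
  }
  gen <- function(prefix, offset, remaining, depth) {
    push(prefix)
    if (!is.null(max_breaks) && depth >= max_breaks) return(invisible())
    if (remaining >= 2L * min_segment) {
      for (p in min_segment:(remaining - min_segment)) {
        gen(c(prefix, offset + p), offset + p, remaining - p, depth + 1L)
      }
    }
  }
  gen(integer(0), 0L, n_points, 0L)
  out <- acc$out[seq_len(acc$n)]
  key <- vapply(out, function(v) {
    paste(formatC(v, width = 6, flag = "0"), collapse = "-")
  }, character(1))
  out[order(lengths(out), key)]
}

# Segment bounds in point coordinates under the shared-boundary
# convention: segments are [1, j1], [j1, j2], ..., [jk, n], so each
# segment's transition-pair count is end - start.
segment_bounds <- function(breaks, n_points) {
  starts <- c(1L, as.integer(breaks))
  ends <- c(as.integer(breaks), n_points)
  cbind(start = starts, end = ends)
}

# Break sets whose every segment carries enough transition pairs for
# the chosen criterion to be finite (AICc needs n_obs >= k + 2 = 5).
scoreable_breaks <- function(n_points, min_segment = 4,
                             criterion = c("AICc", "AIC"),
                             max_breaks = NULL) {
  criterion <- match.arg(criterion)
  combos <- enumerate_breaks(n_points, min_segment, max_breaks)
  min_obs <- if (criterion == "AICc") 5L else 3L
  keep <- vapply(combos, function(b) {
    bd <- segment_bounds(b, n_points)
    all(bd[, "end"] - bd[, "start"] >= min_obs)
  }, logical(1))
  combos[keep]
}

#' Akaike weights from a vector of information-criterion scores
#'
#' `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with `d_i` the difference
#' from the best (lowest) score. Non-finite scores are excluded before
#' weighting and get `NA` weights.
#'
#' @param scores Numeric IC scores (lower is better).
#' @return Numeric vector of weights, same length as `scores`, summing
#'   to 1 over the finite entries.
#' @examples
#' akaike_weights(c(0, 2))  # 0.7311, 0.2689
#' @export
akaike_weights <- function(scores) {
  w <- rep(NA_real_, length(scores))
  ok <- is.finite(scores)
  if (!any(ok)) stop("need at least one finite score", call. = FALSE)
  d <- scores[ok] - min(scores[ok])
  e <- exp(-d / 2)
  w[ok] <- e / sum(e)
  w
}

#' Fit and score one break-point combination
#'
#' Partitions the series at the given break years, fits the Ricker
#' model to each segment (consecutive segments share the boundary year
#' but no transition pair; see [fit_ricker]) and sums the per-segment
#' information criteria.
#'
#' @param series A [population_series].
#' @param breaks Integer vector of break years ("break after year y");
#'   may be empty.
#' @inheritParams segment_ic
#' @param rss_floor_rel Residual floor, relative to mean abundance (see
#'   [detect_shifts]).
#' @param cache Optional environment used to share segment fits across
#'   combinations of the same series.
#' @return A list of class `break_combination`: `breaks`, `fits`,
#'   `total_ic`, `scoreable`, `reason`.
#' @export
score_breaks <- function(series, breaks = integer(),
                         criterion = c("AICc", "AIC"),
                         rss_floor_rel = 1e-6, cache = NULL) {
  series <- as_population_series(series)
  criterion <- match.arg(criterion)
  n <- nrow(series)
  breaks <- sort(as.integer(breaks))
  pos <- match(breaks, series$year)
  if (anyNA(pos) || any(pos < 1L) || any(pos >= n)) {
    stop("break years must be interior years of the series", call. = FALSE)
  }
  floor_per_obs <- (rss_floor_rel * mean(series$abundance))^2
  bd <- segment_bounds(pos, n)
  fits <- vector("list", nrow(bd))
  ics <- numeric(nrow(bd))
  for (i in seq_len(nrow(bd))) {
    key <- paste0(bd[i, 1L], ":", bd[i, 2L])
    f <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(f)) {
      fit <- fit_ricker(series, series$year[bd[i, 1L]], series$year[bd[i, 2L]])
      ic <- if (fit$converged) {
        segment_ic(fit, criterion, rss_floor = fit$n_obs * floor_per_obs)
      } else Inf
      f <- list(fit = fit, ic = ic)
      if (!is.null(cache)) cache[[key]] <- f
    }
    fits[[i]] <- f$fit
    ics[i] <- f$ic
  }
  bad <- !vapply(fits, `[[`, logical(1), "converged") | !is.finite(ics)
  structure(list(
    breaks = breaks,
    fits = fits,
    total_ic = if (any(bad)) Inf else sum(ics),
    scoreable = !any(bad),
    reason = if (any(bad)) "segment fit failed to converge" else ""
  ), class = "break_combination")
}

#' Detect dynamic shifts in a population time series
#'
#' The full detection pipeline: enumerate every admissible break-point
#' combination, fit the Ricker model to each segment of each
#' combination (each distinct segment is fitted once and shared), sum
#' the per-segment information criteria, rank combinations, and weigh
#' the evidence. Combinations within `equivalence_delta` (default 2 IC
#' units) of the best are the *equivalence set* of top candidates.
#' Akaike weights are computed over all scorable combinations;
#' combinations with weight below `prune_threshold` (default 0.001) are
#' then dropped — except equivalence-set members, which are always
#' retained — and the retained weights are renormalized. The *break
#' weight* of a year is the summed weight of all retained combinations
#' containing a break after that year.
#'
#' Under AICc the small-sample correction is undefined for segments
#' with fewer than 5 transition pairs, so such combinations are outside
#' the scored model space even when `min_segment = 4` admits them; the
#' effective constraint is reported in the result.
#'
#' @param series A [population_series] (or anything [read_series_csv]
#'   returns).
#' @param criterion `"AICc"` (default, guards against overfitting short
#'   series) or `"AIC"` (more sensitive).
#' @param min_segment Minimum data points per segment (default 4).
#' @param equivalence_delta IC-unit window defining the top set
#'   (default 2).
#' @param prune_threshold Minimum Akaike weight retained (default
#'   0.001).
#' @param supported_threshold,erroneous_threshold Break-weight decision
#'   rules: above the first a break is labelled "supported", below the
#'   second "erroneous", otherwise "ambiguous" (defaults 0.8 / 0.2).
#' @param max_breaks Optional cap on breaks per combination.
#' @param rss_floor_rel Per-observation residual floor as a fraction of
#'   the mean abundance (default 1e-6); only active for near-noiseless
#'   data, where it makes the log-likelihood finite so ranking falls
#'   back on the parsimony penalty.
#' @return An object of class `shift_ranking`; see
#'   [summary.shift_ranking] and [break_weights].
#' @examples
#' s <- simulate_ricker(length = 20, breaks = 10, tau = 0.02, seed = 42)
#' detect_shifts(s)
#' @export
detect_shifts <- function(series,
                          criterion = c("AICc", "AIC"),
                          min_segment = 4,
                          equivalence_delta = 2,
                          prune_threshold = 0.001,
                          supported_threshold = 0.8,
                          erroneous_threshold = 0.2,
                          max_breaks = NULL,
                          rss_floor_rel = 1e-6) {
  series <- as_population_series(series)
  criterion <- match.arg(criterion)
  n <- nrow(series)
  combos <- scoreable_breaks(n, min_segment, criterion, max_breaks)
  if (!length(combos)) {
    stop("series too short to fit a single segment under criterion ",
         criterion, call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  scored <- lapply(combos, function(pos) {
    score_breaks(series, series$year[pos], criterion,
                 rss_floor_rel = rss_floor_rel, cache = cache)
  })
  scoreable <- vapply(scored, `[[`, logical(1), "scoreable")
  n_unscorable <- sum(!scoreable)
  if (n_unscorable > 0) {
    warning(n_unscorable, " combination(s) dropped: segment fit did not ",
            "converge", call. = FALSE)
  }
  scored <- scored[scoreable]
  if (!length(scored)) {
    stop("no break-point combination could be scored", call. = FALSE)
  }
  total_ic <- vapply(scored, `[[`, numeric(1), "total_ic")
  brks <- lapply(scored, `[[`, "breaks")
  key <- vapply(brks, function(v) {
    paste(formatC(v, width = 9, flag = "0"), collapse = "-")
  }, character(1))
  o <- order(total_ic, lengths(brks), key)
  scored <- scored[o]
  total_ic <- total_ic[o]
  brks <- brks[o]
  delta <- total_ic - total_ic[1L]
  w_raw <- akaike_weights(total_ic)
  in_eq <- delta < equivalence_delta
  retain <- w_raw >= prune_threshold | in_eq
  n_pruned <- sum(!retain)
  w <- w_raw[retain] / sum(w_raw[retain])
  cand <- data.frame(
    rank = seq_len(sum(retain)),
    n_breaks = lengths(brks[retain]),
    total_ic = total_ic[retain],
    delta_ic = delta[retain],
    weight = w,
    in_equivalence = in_eq[retain]
  )
  cand$breaks <- brks[retain]
  bw <- compute_break_weights(cand$breaks, cand$weight)
  labels <- classify_break(bw,
                           erroneous_threshold = erroneous_threshold,
                           supported_threshold = supported_threshold)
  top <- scored[[1L]]
  structure(list(
    candidates = cand,
    break_weights = bw,
    break_table = data.frame(
      year = as.integer(names(bw)),
      weight = unname(bw),
      label = unname(labels)
    ),
    top_breaks = top$breaks,
    segments = segment_table(top$fits, criterion),
    n_scored = length(scored),
    n_unscorable = n_unscorable,
    n_pruned = n_pruned,
    series = series,
    config = list(criterion = criterion, min_segment = min_segment,
                  equivalence_delta = equivalence_delta,
                  prune_threshold = prune_threshold,
                  supported_threshold = supported_threshold,
                  erroneous_threshold = erroneous_threshold,
                  max_breaks = max_breaks,
                  rss_floor_rel = rss_floor_rel)
  ), class = "shift_ranking")
}

compute_break_weights <- function(break_list, weights) {
  years <- sort(unique(unlist(break_list)))
  if (!length(years)) return(stats::setNames(numeric(0), character(0)))
  bw <- vapply(years, function(y) {
    sum(weights[vapply(break_list, function(b) y %in% b, logical(1))])
  }, numeric(1))
  stats::setNames(pmin(bw, 1), years)
}

#' Break weights of a ranking
#'
#' The weight of a break year is the sum of the (renormalized) Akaike
#' weights of every retained combination in which that break appears —
#' the relative-variable-importance summary of the evidence that a
#' shift occurred after that year.
#'
#' @param ranking A `shift_ranking` from [detect_shifts].
#' @return Named numeric vector, names are break years; each weight is
#'   in `[0, 1]`.
#' @export
break_weights <- function(ranking) {
  stopifnot(inherits(ranking, "shift_ranking"))
  ranking$break_weights
}

#' Classify a break weight against the decision rules
#'
#' Weights above the upper threshold indicate a break that can
#' reasonably be treated as real ("supported"); below the lower
#' threshold, as an artefact ("erroneous"); in between, the weight
#' itself quantifies the strength of evidence ("ambiguous").
#'
#' @param weight Numeric weight(s) in `[0, 1]`.
#' @param erroneous_threshold,supported_threshold Decision thresholds
#'   (defaults 0.2 and 0.8).
#' @return Character vector of labels.
#' @examples
#' classify_break(c(0.85, 0.56, 0.1))
#' @export
classify_break <- function(weight, erroneous_threshold = 0.2,
                           supported_threshold = 0.8) {
  if (any(!is.finite(weight)) || any(weight < 0) || any(weight > 1)) {
    stop("break weights must lie in [0, 1]", call. = FALSE)
  }
  ifelse(weight > supported_threshold, "supported",
         ifelse(weight < erroneous_threshold, "erroneous", "ambiguous"))
}

segment_table <- function(fits, criterion) {
  first <- fits[[1L]]$start_year
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      start_year = if (f$start_year == first) f$start_year
                   else f$start_year + 1L,
      end_year = f$end_year,
      r = f$r, se_r = f$se_r,
      k = f$k, se_k = f$se_k,
      sigma = f$sigma, n_obs = f$n_obs, rss = f$rss,
      converged = f$converged
    )
  }))
}

#' @export
print.shift_ranking <- function(x, ...) {
  cat("Dynamic-shift ranking (criterion:", x$config$criterion, ")\n")
  cat(sprintf("  %d combination(s) scored, %d pruned (< %g weight), %d unscorable\n",
              x$n_scored, x$n_pruned, x$config$prune_threshold,
              x$n_unscorable))
  cat("  best combination: ",
      if (length(x$top_breaks)) {
        paste("break(s) after", paste(x$top_breaks, collapse = ", "))
      } else "no break", "\n", sep = "")
  eq <- x$candidates[x$candidates$in_equivalence, ]
  cat(sprintf("  equivalence set (delta < %g): %d combination(s)\n",
              x$config$equivalence_delta, nrow(eq)))
  for (i in seq_len(nrow(eq))) {
    b <- eq$breaks[[i]]
    cat(sprintf("    %-24s IC = %9.3f  delta = %5.2f  w = %.3f\n",
                if (length(b)) paste("{", paste(b, collapse = ", "), "}")
                else "{ no break }",
                eq$total_ic[i], eq$delta_ic[i], eq$weight[i]))
  }
  if (nrow(x$break_table)) {
    cat("  break weights:\n")
    for (i in seq_len(nrow(x$break_table))) {
      cat(sprintf("    after %d: %.3f (%s)\n", x$break_table$year[i],
                  x$break_table$weight[i], x$break_table$label[i]))
    }
  }
  invisible(x)
}

#' @rdname print.shift_ranking
#' @param object,x A `shift_ranking`.
#' @param ... Unused.
#' @export
summary.shift_ranking <- function(object, ...) {
  cat("Segment parameter estimates (best combination):\n")
  print(format(object$segments, digits = 3), row.names = FALSE)
  invisible(object)
}
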