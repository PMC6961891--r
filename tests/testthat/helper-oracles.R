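# Independent oracles used across tests. These deliberately do NOT call
# package internals for the quantity they check.

# Brute force: test all 2^(n-1) subsets of candidate break positions
# against the minimum-segment constraint.
brute_force_breaks <- function(n_points, min_segment) {
  positions <- seq_len(n_points - 1L)
  out <- list(integer(0))
  for (size in seq_along(positions)) {
    if (size * min_segment + min_segment > n_points) break
    sets <- utils::combn(positions, size, simplify = FALSE)
    keep <- Filter(function(s) {
      all(diff(c(0L, s, n_points)) >= min_segment)
    }, sets)
    out <- c(out, keep)
  }
  out
}

break_set_key <- function(v) paste(v, collapse = "-")

# Deterministic Ricker iteration written directly from the formula,
# independent of ricker_step / simulate_ricker.
iterate_ricker_formula <- function(n1, r, k, length) {
  n <- numeric(length)
  n[1] <- n1
  for (t in 1:(length - 1)) n[t + 1] <- n[t] * exp(r * (1 - n[t] / k))
  n
}

# A population_series from a plain abundance vector.
series_from <- function(abundance, start_year = 1) {
  population_series(seq(start_year, length.out = length(abundance)),
                    abundance)
}

# Minimal ranking stub for functions that only need the candidate
# table (contains_true_breaks).
stub_ranking <- function(break_sets, in_equivalence) {
  structure(list(candidates = data.frame(
    in_equivalence = in_equivalence
  ) |> (\(d) { d$breaks <- break_sets; d })()),
  class = "shift_ranking")
}
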