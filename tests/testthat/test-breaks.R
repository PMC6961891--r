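test_that("enumeration matches its spec examples", {
  expect_equal(enumerate_breaks(7, 4), list(integer(0)))
  e8 <- enumerate_breaks(8, 4)
  expect_length(e8, 2)
  expect_equal(e8[[2]], 4L)
  # compositions of 12 into parts >= 4: 1 no-break + 5 one-break + 1
  e12 <- enumerate_breaks(12, 4)
  expect_length(e12, 7)
  expect_equal(table(lengths(e12)), table(c(0, 1, 1, 1, 1, 1, 2)),
               ignore_attr = TRUE)
  expect_error(enumerate_breaks(3, 4), "shorter")
})

test_that("enumeration agrees with the brute-force subset oracle", {
  for (min_segment in c(4, 5, 6)) {
    for (n in 4:16) {
      if (n < min_segment) next
      got <- enumerate_breaks(n, min_segment)
      want <- brute_force_breaks(n, min_segment)
      expect_setequal(vapply(got, break_set_key, character(1)),
                      vapply(want, break_set_key, character(1)))
    }
  }
})

test_that("enumeration order is canonical and max_breaks caps depth", {
  e <- enumerate_breaks(20, 4)
  nb <- lengths(e)
  expect_true(!is.unsorted(nb))  # by number of breaks first
  for (k in unique(nb)) {
    keys <- vapply(e[nb == k], function(v) {
      paste(formatC(v, width = 6, flag = "0"), collapse = "-")
    }, character(1))
    expect_true(!is.unsorted(keys))
  }
  capped <- enumerate_breaks(20, 4, max_breaks = 1)
  expect_true(all(lengths(capped) <= 1))
  expect_identical(enumerate_breaks(16, 4), enumerate_breaks(16, 4))
})

test_that("akaike_weights implements the relative-likelihood formula", {
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  expect_equal(akaike_weights(7), 1)
  expect_equal(akaike_weights(c(0, 2)), c(0.7311, 0.2689),
               tolerance = 1e-4)
  set.seed(12)
  for (i in 1:10) {
    w <- akaike_weights(runif(sample(2:30, 1), -50, 50))
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
  }
  w <- akaike_weights(c(1, Inf, 3))
  expect_true(is.na(w[2]))
  expect_equal(sum(w, na.rm = TRUE), 1)
  expect_error(akaike_weights(c(Inf, NA)), "finite")
})

test_that("scoring a combination sums per-segment criteria exactly", {
  s <- simulate_ricker(length = 20, breaks = 10, tau = 0.05, seed = 8)
  comb <- score_breaks(s, breaks = 10, criterion = "AICc")
  expect_length(comb$fits, 2)
  floor_per_obs <- (1e-6 * mean(s$abundance))^2
  ics <- vapply(comb$fits, function(f) {
    segment_ic(f, "AICc", rss_floor = f$n_obs * floor_per_obs)
  }, numeric(1))
  expect_equal(comb$total_ic, sum(ics))
  # empty break set: total equals the whole-series segment score
  whole <- score_breaks(s, criterion = "AICc")
  f <- fit_ricker(s)
  expect_equal(whole$total_ic,
               segment_ic(f, "AICc", rss_floor = f$n_obs * floor_per_obs))
  expect_error(score_breaks(s, breaks = 20), "interior")
})

test_that("segments partition the transition pairs exactly once", {
  s <- simulate_ricker(length = 24, breaks = c(8, 16), tau = 0.05,
                       seed = 31)
  comb <- score_breaks(s, breaks = c(8, 16))
  n_obs <- vapply(comb$fits, `[[`, numeric(1), "n_obs")
  expect_equal(sum(n_obs), nrow(s) - 1)
  starts <- vapply(comb$fits, `[[`, integer(1), "start_year")
  ends <- vapply(comb$fits, `[[`, integer(1), "end_year")
  # consecutive segments share the boundary year, nothing else
  expect_equal(starts[-1], ends[-length(ends)])
})

test_that("splitting never increases the total residual sum of squares", {
  set.seed(55)
  for (i in 1:5) {
    s <- simulate_ricker(length = 16, breaks = 8, tau = 0.10,
                         delta_k = 0.5)
    whole <- sum(vapply(score_breaks(s)$fits, `[[`, numeric(1), "rss"))
    split <- sum(vapply(score_breaks(s, 8)$fits, `[[`, numeric(1), "rss"))
    expect_lte(split, whole + 1e-6)
  }
})

test_that("a real shift scores better split than merged", {
  s <- simulate_ricker(length = 20, breaks = 10, delta_r = 0,
                       delta_k = 0.75, tau = 0, seed = 17)
  expect_lt(score_breaks(s, 10)$total_ic, score_breaks(s)$total_ic)
})

test_that("detect_shifts ranks, weighs and classifies coherently", {
  s <- simulate_ricker(length = 20, breaks = 10, tau = 0.02, seed = 42)
  r <- detect_shifts(s)
  cand <- r$candidates
  expect_equal(cand$delta_ic[1], 0)
  expect_true(!is.unsorted(cand$total_ic))
  expect_equal(sum(cand$weight), 1, tolerance = 1e-9)
  expect_true(all(r$break_weights >= 0 & r$break_weights <= 1))
  expect_true(all(cand$in_equivalence ==
                    (cand$delta_ic < r$config$equivalence_delta)))
  # a break weight of 1 means every retained combination contains it
  for (y in as.integer(names(r$break_weights[r$break_weights == 1]))) {
    expect_true(all(vapply(cand$breaks, function(b) y %in% b,
                           logical(1))))
  }
  # deterministic: identical input, identical ranking
  expect_identical(detect_shifts(s)$candidates, cand)
  # AICc excludes segments too short for the correction
  expect_true(all(vapply(cand$breaks, function(b) {
    all(diff(c(1L, b, 20L)) >= 5L)
  }, logical(1))))
})

test_that("single-regime noiseless series rank no-break on top", {
  s <- series_from(iterate_ricker_formula(3000, 1.5, 2000, 20))
  r <- detect_shifts(s)
  expect_length(r$top_breaks, 0)
  s2 <- simulate_ricker(length = 20, tau = 0, seed = 3)
  expect_length(detect_shifts(s2)$top_breaks, 0)
})

test_that("break weights sum combination weights containing each year", {
  # hand-summed example: {y}: 0.3, {y,z}: 0.5, {}: 0.2
  bw <- shiftdetector:::compute_break_weights(
    list(10L, c(10L, 15L), integer(0)), c(0.3, 0.5, 0.2))
  expect_equal(bw[["10"]], 0.8)
  expect_equal(bw[["15"]], 0.5)
  bw2 <- shiftdetector:::compute_break_weights(
    list(integer(0), 7L), c(0.4, 0.6))
  expect_equal(unname(bw2), 0.6)
})

test_that("classification follows the 0.8 / 0.2 decision rules", {
  expect_equal(classify_break(c(0.85, 0.56, 0.1)),
               c("supported", "ambiguous", "erroneous"))
  expect_equal(classify_break(0.2), "ambiguous")
  expect_equal(classify_break(0.8), "ambiguous")
  expect_error(classify_break(1.2), "\\[0, 1\\]")
  expect_error(classify_break(-0.1), "\\[0, 1\\]")
})

test_that("series too short for the criterion raise an input error", {
  s <- population_series(1:5, c(100, 150, 170, 160, 155))
  expect_error(detect_shifts(s, criterion = "AICc"), "too short")
  # but AIC can still score a 5-point series (4 transitions)
  r <- detect_shifts(s, criterion = "AIC")
  expect_equal(r$n_scored, 1)
})
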