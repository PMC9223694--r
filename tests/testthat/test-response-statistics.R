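grid_3h <- seq(-1 / 6, 4, by = 1 / 6)

flat_trace <- function(level, cell_id) {
  make_trace(grid_3h, rep(level, length(grid_3h)), cell_id)
}

test_that("responder calling uses a strict threshold on peak F in the window", {
  trs <- list(flat_trace(0.005, "low"), flat_trace(0.05, "high"),
              flat_trace(0.01, "edge"))
  calls <- call_responders(trs)
  expect_equal(calls$is_positive[calls$cell_id == "low"], FALSE)
  expect_equal(calls$is_positive[calls$cell_id == "high"], TRUE)
  # F exactly at the detection limit does not count (strict F > 1 %)
  expect_equal(calls$is_positive[calls$cell_id == "edge"], FALSE)
  # the call looks only inside the window
  spike_outside <- make_trace(grid_3h,
                              ifelse(grid_3h > 3.5, 0.5, 0), "late")
  expect_false(call_responders(list(spike_outside))$is_positive)
  expect_error(call_responders(list()), "no trajectories")
})

test_that("responder fraction counts positives and is order-invariant", {
  trs <- c(lapply(1:3, function(i) flat_trace(0.05, paste0("p", i))),
           lapply(1:7, function(i) flat_trace(0.001, paste0("n", i))))
  calls <- call_responders(trs)
  expect_equal(responder_fraction(calls), 0.3)
  expect_equal(responder_fraction(calls[sample(nrow(calls)), ]), 0.3)
  # split-and-merge gives the same count
  expect_equal(sum(call_responders(trs[1:4])$is_positive) +
                 sum(call_responders(trs[5:10])$is_positive),
               sum(calls$is_positive))
})

test_that("Hill eye-guide curve round-trips exactly Hill-shaped data", {
  temps <- seq(40.5, 45, by = 0.5)
  hill <- function(T, t50, h, pl) pl * (T - 37)^h / ((t50 - 37)^h + (T - 37)^h)
  fr <- hill(temps, 42.5, 8, 1)
  fit <- fit_hill_curve(temps, fr)
  expect_false(fit$degenerate)
  expect_equal(fit$t50, 42.5, tolerance = 1e-6)
  expect_equal(fit$hill, 8, tolerance = 1e-6)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
  # fitted curve is monotone on the stress range
  curve <- hill(seq(41, 44, by = 0.05), fit$t50, fit$hill, fit$plateau)
  expect_true(all(diff(curve) > 0))
  # no response at all is flagged, not extrapolated
  expect_true(fit_hill_curve(temps, rep(0, length(temps)))$degenerate)
})

test_that("mean dynamics average only responding cells, once called", {
  up <- make_trace(grid_3h, seq(0, 0.5, length.out = length(grid_3h)), "up")
  down <- make_trace(grid_3h, seq(0.5, 0, length.out = length(grid_3h)),
                     "down")
  neg <- flat_trace(0.0, "neg")
  calls <- call_responders(list(up, down, neg))
  m1 <- mean_foci_dynamics(list(up), calls[calls$cell_id == "up", ])
  expect_equal(m1$mean_f, up$f_values)
  m2 <- mean_foci_dynamics(list(up, down), calls)
  expect_equal(m2$mean_f, (up$f_values + down$f_values) / 2)
  # a negative cell does not perturb the responder-restricted mean
  m3 <- mean_foci_dynamics(list(up, down, neg), calls)
  expect_equal(m3$mean_f, m2$mean_f)
  expect_warning(
    empty <- mean_foci_dynamics(list(neg), calls[calls$cell_id == "neg", ]),
    "no positive")
  expect_equal(nrow(empty), 0)
})

test_that("amplitude summaries match the sort-based percentile oracle", {
  f_at_1h <- (1:99) / 100
  trs <- lapply(seq_along(f_at_1h), function(i) {
    flat_trace(f_at_1h[i], sprintf("c%02d", i))
  })
  # decouple from responder calling: summarize all cells
  calls <- data.frame(cell_id = vapply(trs, `[[`, "", "cell_id"),
                      is_positive = TRUE)
  amp <- amplitude_distribution(trs, calls, time_points = c(1, 3))
  expect_equal(amp$p50[1], 0.50)
  # interpolation between order statistics puts the quartiles of 1..99 %
  # at 25.5 % and 74.5 %; the round numbers hold to half a grid step
  expect_equal(amp$p25[1], 0.25, tolerance = 0.025)
  expect_equal(amp$p75[1], 0.75, tolerance = 0.025)
  expect_equal(amp$p25[1], oracle_percentile(f_at_1h, 0.25))
  expect_equal(amp$p75[1], oracle_percentile(f_at_1h, 0.75))
  expect_true(all(amp$p09 <= amp$p25 & amp$p25 <= amp$p50 &
                    amp$p50 <= amp$p75 & amp$p75 <= amp$p91))
  expect_equal(amp$p09[1], oracle_percentile(f_at_1h, 0.09))
  expect_equal(amp$p91[1], oracle_percentile(f_at_1h, 0.91))

  # identical traces collapse every percentile
  same <- lapply(1:10, function(i) flat_trace(0.2, paste0("s", i)))
  amp2 <- amplitude_distribution(same, call_responders(same))
  expect_true(all(abs(amp2[1, c("p09", "p25", "p50", "p75", "p91")] - 0.2)
                  < 1e-12))
  expect_error(amplitude_distribution(trs[1], calls[1, ]), "two positive")
})

test_that("relaxation index distinguishes adaptation, plateau and increase", {
  shape <- function(f1, f3) {
    f <- rep(0, length(grid_3h))
    f[which.min(abs(grid_3h - 1))] <- f1
    f[which.min(abs(grid_3h - 3))] <- f3
    make_trace(grid_3h, f)
  }
  expect_equal(relaxation_index(shape(0.10, 0.10)), 1.0)   # plateau
  expect_equal(relaxation_index(shape(0.10, 0.00)), 0.0)   # perfect adaptation
  expect_equal(relaxation_index(shape(0.10, 0.15)), 1.5)   # increase
  expect_message(eta <- relaxation_index(shape(0, 0.1)), "undefined")
  expect_true(is.na(eta))
})

test_that("relaxation histogram uses four contiguous half-open bins", {
  h <- relaxation_histogram(c(0.0, 1.0, 2.0))
  expect_equal(h$counts, c(1L, 0L, 1L, 1L))
  # boundary goes to the upper bin (half-open convention)
  expect_equal(relaxation_histogram(0.25)$counts, c(0L, 1L, 0L, 0L))
  expect_equal(relaxation_histogram(1.25)$counts, c(0L, 0L, 0L, 1L))
  # conservation over arbitrary samples
  set.seed(5)
  etas <- c(rexp(200), NA, NA)
  h2 <- relaxation_histogram(etas)
  expect_equal(sum(h2$counts), 200L)
  expect_equal(h2$n_cells, 200L)
  expect_error(relaxation_histogram(-0.1), "negative")
})

test_that("activation function bins by log ratio and suppresses sparse classes", {
  # all cells at one ratio: a single class with that F distribution
  f <- seq(0.01, 0.2, length.out = 200)
  one <- activation_function_by_ratio(f, rep(2, 200), rep(1, 200))
  expect_equal(nrow(one), 1L)
  expect_equal(one$p50, oracle_percentile(f, 0.5))

  # a class with exactly 30 cells is suppressed ("more than 30")
  ratio <- c(rep(1, 30), rep(100, 31))
  f2 <- c(runif(30), runif(31))
  two <- activation_function_by_ratio(f2, ratio, rep(1, 61))
  expect_equal(nrow(two), 1L)
  expect_equal(two$n_cells, 31L)

  # F a decreasing function of the ratio: class medians decrease
  set.seed(9)
  r <- 10^runif(1000, -1, 1)
  fdec <- 0.2 / (1 + r^2)
  act <- activation_function_by_ratio(fdec, r, rep(1, 1000),
                                      min_class_size = 30)
  expect_true(all(diff(act$p50) < 0))
  # non-positive expression excluded with a message
  expect_message(
    activation_function_by_ratio(fdec, replace(r, 1, -1), rep(1, 1000)),
    "excluded")
})
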