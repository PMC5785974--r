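# A hand-built trajectory: cytosolic Smac rising linearly 0 -> S_max over
# 10 h, then flat; total Smac pool equals S_max so release counts as MOMP.
ramp_trajectory <- function(smax = 1000, horizon = 24, dt = 0.25) {
  times <- seq(0, horizon, by = dt)
  smac <- pmin(times / 10, 1) * smax
  states <- cbind(cSmac = smac, cSmac_XIAP = 0, mSmac = smax - smac)
  structure(list(times = times, states = states, success = TRUE,
                 observables = list(cytosolic_smac = c("cSmac", "cSmac_XIAP"))),
            class = "cell_trajectory")
}

test_that("time to death is the interpolated 90% Smac crossing", {
  expect_equal(time_to_death(ramp_trajectory()), 9.0)
  # grid refinement changes nothing beyond interpolation tolerance
  expect_lt(abs(time_to_death(ramp_trajectory(dt = 0.125)) -
                time_to_death(ramp_trajectory(dt = 0.25))), 1 / 60)
  # no release at all: censored
  tr0 <- ramp_trajectory()
  tr0$states[, "cSmac"] <- 0
  expect_true(is.na(time_to_death(tr0)))
  # partial release below the floor: censored
  trp <- ramp_trajectory()
  trp$states[, "cSmac"] <- trp$states[, "cSmac"] * 0.3
  trp$states[, "mSmac"] <- 1000 - trp$states[, "cSmac"]
  expect_true(is.na(time_to_death(trp, release_floor = 0.5)))
})

test_that("threshold calibration matches a brute-force search", {
  rates <- 1:10
  th <- calibrate_threshold(rates, 0.3)
  expect_true(th >= 7 && th < 8)
  expect_equal(mean(rates > th), 0.3)
  # oracle: over every candidate threshold, none gets closer to the target
  cand <- c(rates, min(rates) - 1)
  best <- min(abs(vapply(cand, function(t) mean(rates > t), 0) - 0.3))
  expect_equal(abs(mean(rates > th) - 0.3), best)

  expect_lt(calibrate_threshold(rates, 1), min(rates))
  expect_gte(calibrate_threshold(rates, 0), max(rates))
  expect_error(calibrate_threshold(numeric(0), 0.5), "non-empty")
  expect_error(calibrate_threshold(rates, 1.5), "0, 1")

  # ties break toward the smaller apoptotic fraction
  th_t <- calibrate_threshold(c(1, 2, 2, 2, 5), 0.5)
  expect_lte(mean(c(1, 2, 2, 2, 5) > th_t), 0.5)
})

test_that("within-horizon calibration counts only released cells", {
  rates <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  release <- c(5, NA, 6, NA, 4, 3, 7, NA, 2, 8)  # some high-rate cells never release
  th <- calibrate_threshold(rates, 0.3, release_times = release)
  got <- mean(rates > th & !is.na(release) & release <= 24)
  expect_equal(got, 0.3)
})

test_that("classification is a pure per-cell rule", {
  rates <- c(5, 1, 9, 3)
  rel <- c(2, NA, 30, 1)
  ft <- classify(rates, theta = 2, release_times = rel, mito = 1:4, dose = 32)
  expect_equal(ft$fate, c("apoptotic", "survivor", "apoptotic", "apoptotic"))
  expect_equal(ft$t_death_h, c(2, NA, NA, 1))   # release at 30 h is censored
  expect_equal(ft$censored, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(apoptotic_fraction(ft), 0.5)
  expect_equal(apoptotic_fraction(ft, within_horizon = FALSE), 0.75)

  expect_equal(classify(rates, -Inf)$fate, rep("apoptotic", 4))
  expect_equal(classify(rates, Inf)$fate, rep("survivor", 4))

  # permuting cells permutes rows only
  p <- c(3, 1, 4, 2)
  ftp <- classify(rates[p], 2, rel[p], (1:4)[p])
  expect_equal(sort(ftp$t_death_h, na.last = TRUE),
               sort(ft$t_death_h, na.last = TRUE))
  expect_equal(apoptotic_fraction(ftp), apoptotic_fraction(ft))
  expect_error(classify(rates, 2, release_times = c(1, 2)), "length")
})

test_that("apoptotic fraction is non-increasing in the threshold", {
  set.seed(8)
  rates <- rlnorm(500, 8, 1)
  thetas <- quantile(rates, seq(0, 1, 0.1))
  fr <- vapply(thetas, function(th) mean(rates > th), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("the RHS-based activation rate agrees with finite differences", {
  net <- default_network()
  tr <- cached("fine_committing_traj",
               simulate_cell(net, committing_init(net), horizon = 8,
                             dt = 0.05))
  cum <- trajectory_observable(tr, "casp8_active")
  fd <- (cum[-c(1, 2)] - cum[-c(length(cum) - 1, length(cum))]) /
    (2 * 0.05)                     # centred differences, molecules/h
  rhs_max <- casp8_max_activation_rate(tr, net)
  expect_equal(rhs_max, max(fd), tolerance = 0.02)
  # the flux-only reading coincides when activation is production-only
  expect_equal(casp8_max_activation_rate(tr, net, flux_only = TRUE), rhs_max)
})

test_that("the maximum activation rate increases with dose for a fixed cell", {
  net <- default_network()
  r4 <- casp8_max_activation_rate(cached("mean_traj_4",
    simulate_cell(net, cell_init(net, trail_copies = trail_copies_from_dose(4)))), net)
  r250 <- casp8_max_activation_rate(cached("mean_traj_250",
    simulate_cell(net, cell_init(net, trail_copies = trail_copies_from_dose(250)))), net)
  expect_gte(r250, r4)
})
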