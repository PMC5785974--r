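test_that("without ligand the pathway stays silent for 24 hours", {
  net <- default_network()
  tr <- cached("zero_dose_traj",
               simulate_cell(net, cell_init(net, trail_copies = 0)))
  expect_true(tr$success)
  expect_lt(max(trajectory_observable(tr, "casp8_active")), 1e-3)
  expect_lt(max(trajectory_observable(tr, "cytosolic_smac")), 1e-3)
  expect_equal(casp8_max_activation_rate(tr, net), 0, tolerance = 1e-6)
  expect_true(is.na(time_to_death(tr)))
})

test_that("conserved moieties stay constant and states stay non-negative", {
  net <- default_network()
  for (tr in list(committing_traj(),
                  cached("mean_traj_32",
                         simulate_cell(net, cell_init(
                           net, trail_copies = trail_copies_from_dose(32)))))) {
    expect_true(tr$success)
    expect_lt(max(moiety_drift(net, tr)), 1e-6)
    expect_gt(min(tr$states), -1e-3)  # within solver tolerance of zero
  }
})

test_that("the compiled derivative matches the plain-R right-hand side", {
  net <- default_network()
  init <- committing_init(net)
  ref <- simulate_cell(net, init, horizon = 3, dt = 0.25)
  rfun <- function(t, y, parms) list(network_rhs(net, y))
  y0 <- as.numeric(init)[match(net$species, names(init))]
  names(y0) <- net$species
  out <- deSolve::ode(y0, seq(0, 3, 0.25) * 3600, rfun, NULL,
                      method = "lsoda", atol = 1e-6, rtol = 1e-6)
  states_r <- unclass(out)[, -1]
  scale <- max(abs(ref$states))
  expect_lt(max(abs(ref$states - states_r)) / scale, 1e-4)
})

test_that("stiff solution agrees with a fixed-step 4th-order integrator", {
  net <- default_network()
  init <- committing_init(net)
  stiff <- simulate_cell(net, init, horizon = 8, dt = 0.25)
  install_network <- getFromNamespace("install_network", "mitoapop")
  install_network(net)
  y0 <- as.numeric(init)[match(net$species, names(init))]
  names(y0) <- net$species
  out <- deSolve::ode(y0, stiff$times * 3600, func = "C_ma_deriv",
                      parms = numeric(0), dllname = "mitoapop",
                      initfunc = "C_ma_init",
                      method = deSolve::rkMethod("rk4"), hini = 0.25)
  sm_rk <- rowSums(unclass(out)[, -1][, net$observables$cytosolic_smac])
  sm_st <- trajectory_observable(stiff, "cytosolic_smac")
  expect_lt(max(abs(sm_st - sm_rk)) / max(sm_rk), 0.02)
  # saturating release approaches the initial mitochondrial Smac pool
  expect_gt(max(sm_st), 0.75 * 1e5)
})

test_that("death time is stable under grid refinement and tighter tolerances", {
  net <- default_network()
  init <- committing_init(net)
  t1 <- time_to_death(simulate_cell(net, init, dt = 0.25))
  t2 <- time_to_death(simulate_cell(net, init, dt = 0.125))
  t3 <- time_to_death(simulate_cell(net, init, dt = 0.25,
                                    atol = 5e-7, rtol = 5e-7))
  expect_lt(abs(t1 - t2), 1 / 60)
  expect_lt(abs(t1 - t3), 1 / 60)
})

test_that("the activation trigger grows with TRAIL dose for a fixed cell", {
  net <- default_network()
  peaks <- vapply(c(4, 32, 250), function(d) {
    tr <- cached(paste0("mean_traj_", d),
                 simulate_cell(net, cell_init(
                   net, trail_copies = trail_copies_from_dose(d))))
    max(trajectory_observable(tr, "casp8_active"))
  }, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("trajectories export to CSV with one column per species", {
  tr <- committing_traj()
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(df)[1], "time_h")
  expect_equal(ncol(df), 1 + ncol(tr$states))
  expect_equal(nrow(df), length(tr$times))
})
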