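test_that("seed streams are deterministic, isolated, and restore the RNG", {
  expect_identical(child_seed(42, "mito"), child_seed(42, "mito"))
  expect_false(child_seed(42, "mito") == child_seed(42, "Bid"))
  expect_false(child_seed(42, "mito") == child_seed(43, "mito"))

  set.seed(99)
  ref <- rnorm(3)
  set.seed(99)
  invisible(sample_mito_levels(10, seed = 7))
  expect_identical(rnorm(3), ref)  # package sampling left the session RNG alone
})

test_that("mitochondrial levels follow the requested log-normal", {
  lv <- sample_mito_levels(1e5, mito_params(1, 0.45), seed = 3)
  expect_equal(mean(lv), 1, tolerance = 0.01)
  expect_equal(sd(lv) / mean(lv), 0.45, tolerance = 0.02)
  expect_identical(as.numeric(lv),
                   as.numeric(sample_mito_levels(1e5, mito_params(1, 0.45),
                                                 seed = 3)))
  expect_equal(as.numeric(sample_mito_levels(5, mito_params(2, 0), seed = 1)),
               rep(2, 5))
  expect_error(mito_params(1, -0.1), "non-negative")
  expect_error(mito_params(0, 0.4), "positive")
})

test_that("conditional sampling recovers marginal moments and correlation", {
  mp <- mito_params(1, 0.45)
  mito <- sample_mito_levels(1e5, mp, seed = 11)
  grid <- expand.grid(mean = c(1e3, 5e4), cv = c(0.15, 0.25), rho = c(0, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- protein_spec("p", g$mean, g$cv, g$rho, role = "pro")
    x <- sample_protein_given_mito(mito, sp, seed = 100 + i)
    expect_equal(mean(x), g$mean, tolerance = 0.02)
    expect_equal(sd(x) / mean(x), g$cv, tolerance = 0.02 * max(1, 1 / g$cv))
    expect_equal(cor(log(x), log(mito)), g$rho, tolerance = 0.01)
  }
})

test_that("the degenerate correlations behave exactly", {
  mito <- sample_mito_levels(2e4, seed = 5)
  sp1 <- protein_spec("p", 1e4, 0.25, rho = 1, role = "pro")
  x1 <- sample_protein_given_mito(mito, sp1, seed = 6)
  # deterministic, strictly increasing in mito
  o <- order(mito)
  expect_true(all(diff(x1[o]) > 0))
  x1b <- sample_protein_given_mito(mito, sp1, seed = 999)
  expect_equal(x1, x1b)  # zero conditional variance: seed is irrelevant

  sp0 <- protein_spec("p", 1e4, 0.25, rho = 0, role = "pro")
  x0 <- sample_protein_given_mito(sample_mito_levels(1e5, seed = 7), sp0,
                                  seed = 8)
  expect_lt(abs(cor(log(x0), log(sample_mito_levels(1e5, seed = 7)))), 0.01)
  expect_error(protein_spec("p", 10, 0.2, rho = 1.2), "rho")
})

test_that("ensembles are reproducible and streams are independent", {
  specs <- default_protein_specs(default_network())
  e1 <- build_ensemble(200, specs, seed = 21)
  e2 <- build_ensemble(200, specs, seed = 21)
  expect_identical(e1$copies, e2$copies)
  expect_identical(e1$mito, e2$mito)

  # dropping one protein leaves every other stream bit-identical
  e3 <- build_ensemble(200, specs[names(specs) != "Bax"], seed = 21)
  shared <- setdiff(colnames(e1$copies), "Bax")
  expect_identical(e1$copies[, shared], e3$copies[, shared])

  expect_error(build_ensemble(10, c(specs, specs["Bid"]), seed = 1),
               "duplicate")
  expect_true(all(e1$copies >= 0))
  expect_true(all(e1$copies == round(e1$copies)))
})

test_that("mitochondria couple proteins according to their correlations", {
  net <- default_network()
  specs0 <- default_protein_specs(net, rho = 0)
  e0 <- build_ensemble(2e4, specs0, seed = 31)
  lc <- cor(log(pmax(e0$copies[, c("Bid", "Mcl1", "Bax", "XIAP")], 1)))
  expect_lt(max(abs(lc[upper.tri(lc)])), 0.03)

  specs1 <- default_protein_specs(net, rho = 1)
  e1 <- build_ensemble(500, specs1, seed = 32)
  rk <- cor(e1$copies[, "Bid"], e1$copies[, "Bcl2"], method = "spearman")
  expect_gt(rk, 0.999)

  eexp <- build_ensemble(2e4, default_protein_specs(net), seed = 33)
  r_bid <- cor(log(eexp$copies[, "Bid"]), log(eexp$mito))
  r_mcl <- cor(log(eexp$copies[, "Mcl1"]), log(eexp$mito))
  expect_gt(r_bid, r_mcl)  # pro-apoptotic Bid couples tighter than Mcl-1
})

test_that("the MCV inversion has the right closed form and round trip", {
  expect_equal(rho_from_mcv(0), 0)
  expect_equal(rho_from_mcv(100), 1)
  expect_equal(rho_from_mcv(50), sqrt(1 - 0.25))
  expect_equal(rho_from_mcv(50), 0.8660254, tolerance = 1e-7)
  expect_error(rho_from_mcv(101), "0, 100")

  # sampled ensembles recover MCV = 100 * (1 - sqrt(1 - rho^2)) within 2 pts;
  # rho is the log-space correlation, so the matching de-trend is log-space
  mp <- mito_params(1, 0.45)
  mito <- sample_mito_levels(1e5, mp, seed = 41)
  for (rho in c(0, 0.25, 0.5, 0.75, 0.9)) {
    sp <- protein_spec("p", 1e3, 0.25, rho, role = "pro")
    x <- sample_protein_given_mito(mito, sp, seed = 42)
    got <- mcv(x, as.numeric(mito), log_space = TRUE)$mcv
    expect_lt(abs(got - 100 * (1 - sqrt(1 - rho^2))), 2,
              label = sprintf("|MCV error| at rho = %g", rho))
  }
  # rho = 1 with matched log-sds is exactly linear: MCV = 100 in both spaces
  sp1 <- protein_spec("p", 1e3, 0.45, 1, role = "pro")
  x1 <- sample_protein_given_mito(mito, sp1, seed = 42)
  expect_equal(mcv(x1, as.numeric(mito))$mcv, 100, tolerance = 1e-6)
})
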