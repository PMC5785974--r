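# Memoized expensive objects shared across test files. Helpers are loaded
# once per test run, so the environment persists and each object is built at
# most once.
.mitoapop_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .mitoapop_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .mitoapop_test_cache)
  }
  get(key, envir = .mitoapop_test_cache, inherits = FALSE)
}

default_network <- function() cached("network", build_network())

# Calibrated study at the acceptance scale (2000 cells at the sensitive dose).
acceptance_study <- function() cached("acceptance_study", {
  calibrate_study(apop_study(network = default_network()), n = 2000,
                  seed = 101L)
})

# Per-cell fate statistics for an ensemble at one dose, memoized by key.
fate_run <- function(key, dose, n, seed, specs = NULL, study = NULL) {
  cached(key, {
    st <- if (is.null(study)) acceptance_study() else study
    if (is.null(specs)) specs <- st$specs
    ens <- build_ensemble(n, specs, st$mparams, seed)
    f <- simulate_ensemble_fates(st$network, ens, dose = dose)
    attr(f, "ensemble") <- ens
    f
  })
}

# A single committing cell (reduced Bcl2) used by trajectory-level tests:
# the calibrated model leaves the mean cell surviving at every dose, so a
# pro-apoptotic initial condition is needed to exercise MOMP and release.
committing_init <- function(net) {
  cell_init(net, copies = c(Bcl2 = 4000),
            trail_copies = trail_copies_from_dose(250))
}

committing_traj <- function() cached("committing_traj", {
  simulate_cell(default_network(), committing_init(default_network()))
})
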