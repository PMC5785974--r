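#' Install a network into the compiled mass-action right-hand side
#'
#' Copies the rate constants, reactant indices and sparse stoichiometry of a
#' network into the package's compiled derivative function. Called
#' automatically by [simulate_cell()]; only one network is active at a time.
#'
#' @param network A `reaction_network`.
#' @return The number of reactions, invisibly.
#' @keywords internal
install_network <- function(network) {
  S <- network$stoichiometry
  nrx <- ncol(S)
  ptr <- integer(nrx + 1L)
  spi <- integer(0)
  sto <- numeric(0)
  nz <- lapply(seq_len(nrx), function(j) which(S[, j] != 0))
  ptr[1] <- 0L
  for (j in seq_len(nrx)) {
    idx <- nz[[j]]
    spi <- c(spi, idx)
    sto <- c(sto, S[idx, j])
    ptr[j + 1L] <- ptr[j] + length(idx)
  }
  invisible(.Call(C_ma_set_network, as.integer(nrow(S)),
                  as.numeric(network$k),
                  as.integer(network$reactant_idx[1, ]),
                  as.integer(network$reactant_idx[2, ]),
                  as.integer(ptr), as.integer(spi), as.numeric(sto)))
}

#' Construct a single-cell initial condition
#'
#' @param network A `reaction_network`.
#' @param copies Named numeric vector of initial copy numbers overriding the
#'   network's mean initial values (e.g. the sampled protein levels of one
#'   cell). Unmentioned species keep their configured means; complexes and
#'   active forms start at zero by construction of the default means.
#' @param trail_copies Ligand molecules/cell; overrides species `L`.
#' @param mito Dimensionless mitochondrial level stored with the cell (it
#'   does not enter the dynamics directly; it acts through the sampled
#'   copy numbers).
#' @return A `cell_init` object (named state vector plus attributes).
#' @export
cell_init <- function(network, copies = NULL, trail_copies = NULL,
                      mito = NA_real_) {
  y <- network$initial_means
  if (!is.null(copies)) {
    bad <- setdiff(names(copies), network$species)
    if (length(bad)) stop("unknown species in copies: ",
                          paste(bad, collapse = ", "))
    y[names(copies)] <- copies
  }
  if (!is.null(trail_copies)) y[["L"]] <- trail_copies
  if (any(y < 0)) stop("initial copy numbers must be non-negative")
  structure(y, mito = mito, class = "cell_init")
}

#' Integrate the apoptosis network for one cell
#'
#' Integrates the mass-action ODE system with a stiff solver (`deSolve`
#' `lsoda`) and reports the state on a dense regular grid (default 15-minute
#' resolution, matching a typical live-imaging cadence). Rate constants are
#' per second internally; the external time unit is hours.
#'
#' @param network A `reaction_network`.
#' @param init A `cell_init`, or a named state vector.
#' @param horizon Simulation horizon in hours (default 24).
#' @param dt Reporting resolution in hours (default 0.25).
#' @param atol,rtol Solver tolerances (defaults 1e-6, 1e-6).
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A `cell_trajectory`: list with `times` (hours), `states`
#'   (time x species matrix, molecules/cell), `success`, `diagnostics`,
#'   `network_species`, `observables`, and the `mito` level of the cell.
#'   Solver failures are returned flagged (`success = FALSE`), never silently.
#' @examples
#' net <- build_network()
#' tr <- simulate_cell(net, cell_init(net, trail_copies = 3000))
#' tail(trajectory_observable(tr, "cytosolic_smac"))
#' @export
simulate_cell <- function(network, init, horizon = 24, dt = 0.25,
                          atol = 1e-6, rtol = 1e-6, method = "lsoda") {
  stopifnot(inherits(network, "reaction_network"), horizon > 0, dt > 0)
  y0 <- as.numeric(init)[match(network$species, names(init))]
  if (anyNA(y0)) stop("init must provide every network species")
  names(y0) <- network$species
  install_network(network)
  times_h <- seq(0, horizon, by = dt)
  out <- try(deSolve::ode(
    y = y0, times = times_h * 3600, func = "C_ma_deriv",
    parms = numeric(0), dllname = "mitoapop", initfunc = "C_ma_init",
    method = method, atol = atol, rtol = rtol, maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error")) {
    return(structure(list(times = times_h, states = NULL, success = FALSE,
                          diagnostics = attr(out, "condition")$message,
                          network_species = network$species,
                          observables = network$observables,
                          mito = attr(init, "mito"),
                          atol = atol, rtol = rtol),
                     class = "cell_trajectory"))
  }
  states <- unclass(out)[, -1, drop = FALSE]
  success <- nrow(states) == length(times_h) && all(is.finite(states))
  diag_msg <- if (success) "ok" else "solver returned a truncated or non-finite solution"
  structure(list(times = times_h, states = states, success = success,
                 diagnostics = diag_msg,
                 network_species = network$species,
                 observables = network$observables,
                 mito = attr(init, "mito"),
                 atol = atol, rtol = rtol),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("Single-cell trajectory:",
      if (isTRUE(x$success)) "integrated" else paste("FAILED:", x$diagnostics),
      "\n")
  if (!is.null(x$states)) {
    cat(sprintf("  %d time points over [0, %g] h, %d species\n",
                length(x$times), max(x$times), ncol(x$states)))
  }
  invisible(x)
}

#' Sum an observable (a set of species) along a trajectory
#'
#' @param traj A `cell_trajectory`.
#' @param observable Name of an observable defined in the network
#'   configuration (e.g. `"casp8_active"`, `"cytosolic_smac"`), or a
#'   character vector of species names.
#' @return Numeric vector over the reporting grid.
#' @export
trajectory_observable <- function(traj, observable) {
  if (is.null(traj$states)) stop("trajectory has no states (solver failure)")
  sp <- if (length(observable) == 1L && observable %in% names(traj$observables)) {
    traj$observables[[observable]]
  } else {
    observable
  }
  missing <- setdiff(sp, colnames(traj$states))
  if (length(missing)) stop("species not in trajectory: ",
                            paste(missing, collapse = ", "))
  rowSums(traj$states[, sp, drop = FALSE])
}

#' Evaluate the model right-hand side in R
#'
#' A plain-R implementation of the mass-action derivative, used to compute
#' reaction-rate observables along stored trajectories (e.g. the Caspase-8
#' activation rate) and as an independent check of the compiled derivative.
#'
#' @param network A `reaction_network`.
#' @param states A named state vector or a time x species matrix.
#' @return Derivatives in molecules/cell/s with the same shape as `states`.
#' @export
network_rhs <- function(network, states) {
  one <- is.null(dim(states))
  m <- if (one) matrix(states, 1, dimnames = list(NULL, names(states)))
       else states
  m <- m[, network$species, drop = FALSE]
  ridx <- network$reactant_idx
  A <- matrix(1, nrow(m), ncol(ridx))
  has1 <- ridx[1, ] > 0
  has2 <- ridx[2, ] > 0
  A[, has1] <- m[, ridx[1, has1], drop = FALSE]
  A[, has2] <- A[, has2, drop = FALSE] * m[, ridx[2, has2], drop = FALSE]
  rates <- sweep(A, 2, network$k, "*")
  d <- rates %*% t(network$stoichiometry)
  if (one) drop(d) else d
}

#' Check conserved-moiety constancy along a trajectory
#'
#' @param network A `reaction_network`.
#' @param traj A `cell_trajectory`.
#' @return Named vector of maximum relative deviations of each moiety total
#'   from its initial value.
#' @export
moiety_drift <- function(network, traj) {
  vapply(network$conserved_moieties, function(w) {
    tot <- drop(traj$states[, names(w), drop = FALSE] %*% w)
    ref <- max(abs(tot[1]), 1)
    max(abs(tot - tot[1])) / ref
  }, 0)
}

#' Export a trajectory as a CSV table
#'
#' @param traj A `cell_trajectory`.
#' @param path Output path; columns `time_h` then one column per species.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (is.null(traj$states)) stop("trajectory has no states (solver failure)")
  df <- data.frame(time_h = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
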