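#' Bundle the study configuration for in-silico experiments
#'
#' Collects everything the simulated experiments share: the reaction
#' network, the sampled-protein specifications, the mitochondrial
#' distribution, the sensitive dose used for threshold calibration, and the
#' experimental death probability at that dose (the calibration target,
#' supplied via configuration rather than hard-coded).
#'
#' @param network A `reaction_network`.
#' @param specs Named list of `protein_spec`s.
#' @param mparams A [mito_params()].
#' @param sensitive_dose Dose (ng/ml) at which the threshold is calibrated
#'   (default 32).
#' @param target_fraction Experimental apoptotic fraction at the sensitive
#'   dose (default taken from [default_dose_response()]).
#' @param horizon Hours (default 24).
#' @return An `apop_study` object (uncalibrated; see [calibrate_study()]).
#' @export
apop_study <- function(network = build_network(),
                       specs = default_protein_specs(network),
                       mparams = mito_params(),
                       sensitive_dose = 32,
                       target_fraction = NULL,
                       horizon = 24) {
  if (is.null(target_fraction)) {
    dr <- default_dose_response()
    target_fraction <- dr$fraction[match(sensitive_dose, dr$dose)]
    if (is.na(target_fraction)) {
      stop("no default target fraction for dose ", sensitive_dose,
           "; supply target_fraction")
    }
  }
  structure(list(network = network, specs = specs, mparams = mparams,
                 sensitive_dose = sensitive_dose,
                 target_fraction = target_fraction,
                 horizon = horizon, theta = NULL),
            class = "apop_study")
}

#' Reference experimental dose-response table
#'
#' The measured fraction of dead HeLa cells after 24 h of TRAIL, as a
#' configuration table: near zero below 2 ng/ml, a sensitive region between
#' 4 and 63 ng/ml, and a plateau around 35% at higher doses. Used to supply
#' the calibration target at the sensitive dose; values are a smooth reading
#' of the published response curve, not model output.
#'
#' @return Data frame with columns `dose` (ng/ml) and `fraction`.
#' @export
default_dose_response <- function() {
  data.frame(
    dose = c(0, 2, 4, 8, 16, 32, 63, 125, 250),
    fraction = c(0, 0.02, 0.05, 0.10, 0.18, 0.27, 0.33, 0.35, 0.35)
  )
}

#' @export
print.apop_study <- function(x, ...) {
  cat("Apoptosis simulation study\n")
  cat(sprintf("  sensitive dose: %g ng/ml (target fraction %.2f)\n",
              x$sensitive_dose, x$target_fraction))
  cat(sprintf("  threshold: %s\n",
              if (is.null(x$theta)) "uncalibrated" else
                sprintf("%.4g molecules/cell/h", x$theta)))
  invisible(x)
}

# Simulate one ensemble at one dose; returns the per-cell fate statistics.
study_run <- function(study, dose, n, seed, specs = NULL) {
  ens <- build_ensemble(n, specs %||% study$specs, study$mparams, seed)
  f <- simulate_ensemble_fates(study$network, ens, dose = dose,
                               horizon = study$horizon)
  f$ensemble <- NULL
  attr(f, "ensemble") <- ens
  f
}

#' Calibrate the study's fate threshold at the sensitive dose
#'
#' Simulates an ensemble at the sensitive dose and fixes the Caspase-8
#' activation-rate threshold so that the fraction of cells dying within the
#' horizon reproduces the experimental death probability. The threshold is
#' then dose-independent for all subsequent experiments.
#'
#' @param study An `apop_study`.
#' @param n Ensemble size for calibration.
#' @param seed Integer seed.
#' @return The study with `theta` set.
#' @export
calibrate_study <- function(study, n = 2000, seed = 1L) {
  f <- study_run(study, study$sensitive_dose, n, child_seed(seed, "calibrate"))
  study$theta <- calibrate_threshold(f$max_c8_rate, study$target_fraction,
                                     release_times = f$release_time_h,
                                     horizon = study$horizon)
  study$calibration_n <- n
  study
}

require_theta <- function(study) {
  if (is.null(study$theta)) {
    stop("study threshold not calibrated; run calibrate_study() first")
  }
  study$theta
}

#' Simulated dose-response with bootstrap confidence intervals
#'
#' One freshly sampled ensemble per dose (shared protein specifications,
#' dose-specific child seeds); the apoptotic fraction counts cells above the
#' calibrated threshold whose Smac release occurs within the horizon.
#'
#' @param study A calibrated `apop_study`.
#' @param doses Doses in ng/ml.
#' @param n Cells per dose (default 10000; desk-scale analyses use less).
#' @param seed Integer seed.
#' @param boot_reps Bootstrap replicates for the fraction CIs.
#' @param level Confidence level.
#' @return A `dose_response` data frame: `dose`, `fraction`, `lo`, `hi`, `n`.
#' @export
run_dose_response <- function(study, doses = default_dose_response()$dose,
                              n = 10000, seed = 1L, boot_reps = 1000,
                              level = 0.95) {
  theta <- require_theta(study)
  rows <- lapply(doses, function(d) {
    f <- study_run(study, d, n, child_seed(seed, paste0("dose", d)))
    ft <- classify(f$max_c8_rate, theta, f$release_time_h, f$mito,
                   dose = d, horizon = study$horizon)
    dead <- as.numeric(ft$fate == "apoptotic" & !ft$censored)
    ci <- bootstrap_ci(mean, dead, reps = boot_reps,
                       seed = child_seed(seed, paste0("boot", d)),
                       level = level)
    data.frame(dose = d, fraction = mean(dead), lo = ci[1], hi = ci[2], n = n)
  })
  out <- do.call(rbind, rows)
  structure(out, seed = seed, class = c("dose_response", "data.frame"))
}

#' Mitochondrial content as a fate classifier across doses
#'
#' ROC/AUC of the initial mitochondrial level against the simulated fate
#' (apoptotic = positive class) at each dose.
#'
#' @inheritParams run_dose_response
#' @return Data frame: `dose`, `auc`, `n_pos`, `n_neg`; `auc` is `NA` (with
#'   a warning) when a dose yields no apoptotic or no surviving cells.
#' @export
run_fate_classifier <- function(study, doses = c(2, 4, 8, 16, 32, 63, 125, 250),
                                n = 10000, seed = 1L) {
  theta <- require_theta(study)
  rows <- lapply(doses, function(d) {
    f <- study_run(study, d, n, child_seed(seed, paste0("dose", d)))
    ap <- f$max_c8_rate > theta
    if (!any(ap) || all(ap)) {
      warning("AUC undefined at dose ", d, " (single-class ensemble)")
      return(data.frame(dose = d, auc = NA_real_, n_pos = sum(ap),
                        n_neg = sum(!ap)))
    }
    r <- roc_auc(f$mito[ap], f$mito[!ap])
    data.frame(dose = d, auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg)
  })
  do.call(rbind, rows)
}

#' Single-protein fate classifiers at the sensitive dose
#'
#' ROC/AUC of each sampled protein's initial copy number against simulated
#' fate, with protein levels either co-varying with mitochondria
#' (`correlated = TRUE`, the measured configuration) or sampled
#' independently of mitochondrial content (`correlated = FALSE`). The
#' surface receptor is excluded by default: the classifier panel mirrors the
#' immunolabelled apoptotic regulators, and the receptor level, like the
#' dose itself, sets the stimulus input rather than the cell's internal
#' apoptotic balance.
#'
#' @param study A calibrated `apop_study`.
#' @param dose Dose in ng/ml (default: the study's sensitive dose).
#' @param n Ensemble size.
#' @param correlated Logical; `FALSE` sets every mitochondria-protein
#'   correlation to zero.
#' @param seed Integer seed.
#' @param include_receptor Include the receptor in the reported panel.
#' @return Data frame: `protein`, `role`, `rho`, `auc`; attribute
#'   `mito_auc` holds the mitochondrial classifier on the same ensemble.
#' @export
run_protein_classifiers <- function(study, dose = study$sensitive_dose,
                                    n = 10000, correlated = TRUE, seed = 1L,
                                    include_receptor = FALSE) {
  theta <- require_theta(study)
  specs <- study$specs
  if (!correlated) {
    specs <- lapply(specs, function(s) { s$rho <- 0; s })
  }
  f <- study_run(study, dose, n, child_seed(seed, "protein_classifiers"),
                 specs = specs)
  ens <- attr(f, "ensemble")
  ap <- f$max_c8_rate > theta
  if (!any(ap) || all(ap)) stop("AUC undefined: single-class ensemble")
  panel <- names(specs)
  if (!include_receptor) {
    panel <- panel[vapply(specs, `[[`, "", "role") != "receptor"]
  }
  auc <- vapply(panel, function(p) {
    roc_auc(ens$copies[ap, p], ens$copies[!ap, p])$auc
  }, 0)
  out <- data.frame(
    protein = panel,
    role = vapply(specs[panel], `[[`, "", "role"),
    rho = vapply(specs[panel], `[[`, 0, "rho"),
    auc = unname(auc),
    stringsAsFactors = FALSE
  )
  attr(out, "mito_auc") <- roc_auc(f$mito[ap], f$mito[!ap])$auc
  out
}

#' Sensitivity of the mitochondrial AUC to each protein's correlation
#'
#' Central finite difference of the mitochondria-fate AUC with respect to
#' each protein's mitochondria correlation, holding the other correlations
#' at their configured values. Perturbed runs reuse the same seed (common
#' random numbers): the underlying mitochondria and per-protein Gaussian
#' draws are identical, so only the perturbed coupling changes and the
#' finite-difference noise is strongly reduced. When `rho +/- delta` leaves
#' `[-1, 1]`, a one-sided difference is used with a warning.
#'
#' @param study A calibrated `apop_study`.
#' @param dose Dose (default: sensitive dose).
#' @param n Ensemble size per evaluation.
#' @param delta Finite-difference step on rho (default 0.05).
#' @param seed Integer seed (shared across all perturbed runs).
#' @param proteins Subset of proteins to perturb (default all).
#' @return Data frame: `protein`, `role`, `rho`, `sensitivity` (dAUC/drho),
#'   `delta_used`.
#' @export
run_auc_sensitivity <- function(study, dose = study$sensitive_dose, n = 10000,
                                delta = 0.05, seed = 1L,
                                proteins = names(study$specs)) {
  require_theta(study)
  eval_auc <- function(specs) {
    f <- study_run(study, dose, n, child_seed(seed, "sensitivity"),
                   specs = specs)
    ap <- f$max_c8_rate > study$theta
    roc_auc(f$mito[ap], f$mito[!ap])$auc
  }
  rows <- lapply(proteins, function(p) {
    rho0 <- study$specs[[p]]$rho
    hi <- rho0 + delta
    lo <- rho0 - delta
    if (hi > 1 || lo < -1) {
      warning("one-sided difference for ", p, " (rho near the boundary)")
      hi <- min(hi, 1); lo <- max(lo, -1)
    }
    sp_hi <- study$specs; sp_hi[[p]]$rho <- hi
    sp_lo <- study$specs; sp_lo[[p]]$rho <- lo
    data.frame(protein = p, role = study$specs[[p]]$role, rho = rho0,
               sensitivity = (eval_auc(sp_hi) - eval_auc(sp_lo)) / (hi - lo),
               delta_used = (hi - lo) / 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' AUC surface over the MCV grid of a pro/anti-apoptotic pair
#'
#' Sweeps the mitochondrial contribution to variability (MCV) of the two
#' members of a pre-MOMP pair (Bax/Bcl-2 or Bid/Mcl-1) over a grid,
#' converting MCV to correlation via [rho_from_mcv()], while all other
#' correlations stay at their configured values. The configured
#' (experimental) point is marked in the result.
#'
#' @param study A calibrated `apop_study`.
#' @param pair Character pair: `c("Bax", "Bcl2")` or `c("Bid", "Mcl1")`.
#' @param mcv_grid Numeric MCV grid in `[0, 100]` applied to both members.
#' @param dose Dose (default: sensitive dose).
#' @param n Ensemble size per grid cell.
#' @param seed Integer seed (common random numbers across cells).
#' @return A `sweep_result`: list with `pair`, `mcv_grid`, `auc` (matrix,
#'   rows = pro-apoptotic member MCV, columns = anti member MCV),
#'   `experimental_mcv` (the pair's configured MCVs).
#' @export
run_pair_sweep <- function(study, pair = c("Bax", "Bcl2"),
                           mcv_grid = c(0, 25, 50, 75, 95),
                           dose = study$sensitive_dose, n = 10000,
                           seed = 1L) {
  require_theta(study)
  pair <- as.character(pair)
  allowed <- list(c("Bax", "Bcl2"), c("Bid", "Mcl1"))
  if (!any(vapply(allowed, function(a) identical(a, pair), TRUE))) {
    stop("pair must be c(\"Bax\", \"Bcl2\") or c(\"Bid\", \"Mcl1\")")
  }
  if (any(mcv_grid < 0 | mcv_grid > 100)) stop("mcv_grid must lie in [0, 100]")
  auc <- matrix(NA_real_, length(mcv_grid), length(mcv_grid),
                dimnames = list(pro = mcv_grid, anti = mcv_grid))
  for (i in seq_along(mcv_grid)) {
    for (j in seq_along(mcv_grid)) {
      specs <- study$specs
      specs[[pair[1]]]$rho <- rho_from_mcv(mcv_grid[i])
      specs[[pair[2]]]$rho <- rho_from_mcv(mcv_grid[j])
      f <- study_run(study, dose, n, child_seed(seed, "pair_sweep"),
                     specs = specs)
      ap <- f$max_c8_rate > study$theta
      auc[i, j] <- if (any(ap) && any(!ap)) {
        roc_auc(f$mito[ap], f$mito[!ap])$auc
      } else NA_real_
    }
  }
  exp_mcv <- vapply(pair, function(p) {
    100 * (1 - sqrt(1 - study$specs[[p]]$rho^2))
  }, 0)
  structure(list(pair = pair, mcv_grid = mcv_grid, auc = auc,
                 experimental_mcv = exp_mcv),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("MCV pair sweep (%s / %s), AUC surface:\n",
              x$pair[1], x$pair[2]))
  print(round(x$auc, 3))
  cat(sprintf("experimental point: MCV(%s) = %.0f, MCV(%s) = %.0f\n",
              x$pair[1], x$experimental_mcv[1],
              x$pair[2], x$experimental_mcv[2]))
  invisible(x)
}

#' Mitochondria / time-to-death scatter under correlation scenarios
#'
#' Simulates the three canonical coupling scenarios -- perfect correlation
#' (`rho = 1` for every protein), the configured (experimental)
#' correlations, and no correlation (`rho = 0`) -- and returns the
#' apoptotic cells' (mito, time-to-death) pairs for each.
#'
#' @param study A calibrated `apop_study`.
#' @param dose Dose (default: sensitive dose).
#' @param n Ensemble size per scenario.
#' @param seed Integer seed (common random numbers across scenarios).
#' @return Named list (`perfect`, `experimental`, `independent`) of data
#'   frames with columns `mito`, `t_death_h`.
#' @export
run_rho_scenarios <- function(study, dose = study$sensitive_dose, n = 10000,
                              seed = 1L) {
  theta <- require_theta(study)
  scen <- list(perfect = 1, experimental = NA, independent = 0)
  out <- lapply(scen, function(r) {
    specs <- study$specs
    if (!is.na(r)) specs <- lapply(specs, function(s) { s$rho <- r; s })
    f <- study_run(study, dose, n, child_seed(seed, "rho_scenarios"),
                   specs = specs)
    ft <- classify(f$max_c8_rate, theta, f$release_time_h, f$mito,
                   dose = dose, horizon = study$horizon)
    ok <- ft$fate == "apoptotic" & !ft$censored
    data.frame(mito = ft$mito[ok], t_death_h = ft$t_death_h[ok])
  })
  out
}

#' Null ensemble for the division / death-time association
#'
#' Builds a virtual cell population in which death and division are
#' independent by construction: every cell draws a death time from the
#' supplied sample and, independently, a cell-cycle length; its position in
#' the cycle at the moment of stimulation is uniform, so the remaining time
#' to division is uniform on the cycle length. A cell divides (before
#' dying) exactly when that remaining time is shorter than its death time.
#' The selection alone -- with no causal coupling -- makes dividing
#' apoptotic cells die later on average and induces a positive death/
#' division-time correlation among dividers.
#'
#' @param death_times Sample of death times (hours) to resample from.
#' @param division_sampler Either a list `list(meanlog, sdlog)` describing a
#'   log-normal cell-cycle length -- the remaining time to division is then
#'   uniform on the drawn cycle length (uniform cycle position at stimulus)
#'   -- or a function `n -> n` drawing the division times directly.
#' @param n Number of virtual cells.
#' @param seed Integer seed.
#' @param horizon Observation horizon in hours (default 24).
#' @return List with `mean_death_dividing`, `mean_death_nondividing`,
#'   `cor_death_division` (Spearman, among dividers), `n_dividing`, and the
#'   per-cell table `cells`.
#' @export
run_null_division_ensemble <- function(death_times, division_sampler, n,
                                       seed = 1L, horizon = 24) {
  if (length(death_times) == 0) stop("death_times must be non-empty")
  cells <- with_seed(seed, {
    td <- sample(death_times, n, replace = TRUE)
    if (is.list(division_sampler) && !is.function(division_sampler)) {
      cycle <- rlnorm(n, division_sampler$meanlog, division_sampler$sdlog)
      tdiv <- runif(n) * cycle   # uniform cycle position at stimulus
    } else {
      cycle <- rep(NA_real_, n)
      tdiv <- division_sampler(n)
    }
    data.frame(t_death = td, cycle = cycle, t_division = tdiv)
  })
  cells$divides <- cells$t_division < pmin(cells$t_death, horizon)
  div <- cells$divides
  if (sum(div) < 3 || sum(!div) < 1) {
    cor_dd <- NA_real_
  } else {
    cor_dd <- spearman_rho(cells$t_death[div], cells$t_division[div])
  }
  list(
    mean_death_dividing = mean(cells$t_death[div]),
    mean_death_nondividing = mean(cells$t_death[!div]),
    cor_death_division = cor_dd,
    n_dividing = sum(div),
    cells = cells
  )
}
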