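#' Default generator parameters for the synthetic live-imaging fixture
#'
#' The fixture emulates a tracked single-cell imaging experiment at the
#' sensitive dose: per-cell mitochondrial level, binary fate, time to death
#' for apoptotic cells, and (optionally) a division time. Fate follows a
#' logistic model in log mitochondrial level; time to death follows a
#' decreasing power law in mitochondrial level with log-normal noise,
#' `t = a * m^(-b) * exp(eps)`, echoing the exponential-like decay of death
#' times with mitochondrial content. The numeric values were calibrated once
#' against the summary statistics of the reference imaging experiment at
#' 32 ng/ml (rank correlation about -0.47 between mitochondrial level and
#' death time; mean death times about 3 h and 6 h in the top and bottom
#' mitochondrial quartiles) and then frozen; they are generator constants,
#' not measured quantities.
#'
#' @return Named list of generator constants.
#' @export
default_imaging_params <- function() {
  list(
    mito_cv = 0.45,         # log-normal mitochondrial spread
    fate_slope = 3.0,       # logistic slope per unit log-mito
    apoptotic_fraction = 0.43,  # emulates enrichment to ~130 apoptotic/300
    t_scale = 4.1464,       # hours at the mean mitochondrial level
    t_power = 0.6957,       # decay exponent of death time vs mito
    t_sigma = 0.4994,       # log-normal noise on death times
    division_meanlog = log(20), # cycle length ~20 h
    division_sdlog = 0.2
  )
}

#' Generate a synthetic live-imaging fate table
#'
#' Produces the per-cell records a 24-hour tracking experiment yields:
#' mitochondrial level (population-mean normalised), fate, time to death
#' for apoptotic cells (always within the horizon), an observed division
#' time when the cell divides before dying, and the dose label.
#'
#' The default parameters reproduce, at the sensitive dose, the reference
#' statistics used to validate the generator (see
#' [default_imaging_params()]); the apoptotic fraction is the enriched one
#' of a tracking experiment designed to capture 100-150 apoptotic cells
#' out of ~300.
#'
#' @param n Number of cells (>= 50).
#' @param dose_profile List with `dose` (label, ng/ml), and optionally
#'   `apoptotic_fraction`, `t_scale`, `mito_effect` (multiplier on both the
#'   fate slope and the death-time power; 0 decouples fate and death time
#'   from mitochondria entirely).
#' @param seed Integer seed.
#' @param params Generator constants, see [default_imaging_params()].
#' @return An `imaging_fixture` data frame: `cell_id`, `dose_ng_ml`, `mito`,
#'   `fate`, `t_death_h`, `division_time_h`.
#' @examples
#' fx <- make_imaging_fixture(300, seed = 1)
#' table(fx$fate)
#' @export
make_imaging_fixture <- function(n = 300, dose_profile = list(dose = 32),
                                 seed = 1L,
                                 params = default_imaging_params()) {
  if (n < 50) stop("n must be at least 50")
  p <- params
  frac <- dose_profile$apoptotic_fraction %||% p$apoptotic_fraction
  tsc <- dose_profile$t_scale %||% p$t_scale
  eff <- dose_profile$mito_effect %||% 1
  dose <- dose_profile$dose %||% 32

  mito <- sample_mito_levels(n, mito_params(1, p$mito_cv),
                             seed = child_seed(seed, "mito"))
  lm_ <- log(as.numeric(mito))
  slope <- p$fate_slope * eff
  # intercept solved so the expected apoptotic fraction hits the target
  a <- stats::uniroot(function(a) mean(plogis(a + slope * lm_)) - frac,
                      c(-50, 50))$root
  prob <- plogis(a + slope * lm_)
  fate_draw <- with_seed(child_seed(seed, "fate"), runif(n))
  apop <- fate_draw < prob

  t_death <- rep(NA_real_, n)
  if (any(apop)) {
    m_a <- as.numeric(mito)[apop]
    base <- tsc * m_a^(-p$t_power * eff)
    eps <- with_seed(child_seed(seed, "tdeath"), rnorm(sum(apop)))
    td <- base * exp(p$t_sigma * eps)
    # death inside the observation window: resample the rare overshoots
    redraw_seed <- 1L
    while (any(td > 24)) {
      i <- td > 24
      eps_i <- with_seed(child_seed(seed, paste0("tdeath_r", redraw_seed)),
                         rnorm(sum(i)))
      td[i] <- base[i] * exp(p$t_sigma * eps_i)
      redraw_seed <- redraw_seed + 1L
    }
    t_death[apop] <- td
  }

  cycle <- with_seed(child_seed(seed, "cycle"),
                     rlnorm(n, p$division_meanlog, p$division_sdlog))
  u <- with_seed(child_seed(seed, "cyclepos"), runif(n))
  t_div <- u * cycle
  observed_div <- t_div < pmin(ifelse(apop, t_death, Inf), 24)
  division <- ifelse(observed_div, t_div, NA_real_)

  structure(data.frame(
    cell_id = seq_len(n),
    dose_ng_ml = dose,
    mito = as.numeric(mito),
    fate = ifelse(apop, "apoptotic", "survivor"),
    t_death_h = t_death,
    division_time_h = division,
    stringsAsFactors = FALSE
  ), seed = seed, params = p, class = c("imaging_fixture", "data.frame"))
}

#' Generate a synthetic immunofluorescence-style intensity table
#'
#' Emulates a two-channel single-cell staining experiment: a mitochondrial
#' intensity and one protein intensity per cell, sampled so that the
#' realised mitochondrial contribution to variability (MCV) is close to the
#' requested target. The protein is sampled conditionally on mitochondria
#' via [sample_protein_given_mito()] with `rho = rho_from_mcv(target_mcv)`.
#'
#' @param n Number of cells.
#' @param target_mcv Target MCV in percent, in `[0, 100]`.
#' @param seed Integer seed.
#' @param protein Protein label stored in the table.
#' @param mean_intensity,cv Marginal mean and coefficient of variation of
#'   the protein intensity. The default cv equals the mitochondrial cv, so a
#'   target MCV of 100 corresponds to an exactly linear (not merely
#'   log-linear) dependence and is realised exactly.
#' @param mparams Mitochondrial distribution ([mito_params()]).
#' @return An `if_table` data frame: `cell_id`, `mito`, `protein_intensity`;
#'   attribute `protein`.
#' @export
make_if_table <- function(n, target_mcv, seed = 1L, protein = "protein",
                          mean_intensity = 1000, cv = 0.45,
                          mparams = mito_params()) {
  if (target_mcv < 0 || target_mcv > 100) stop("target_mcv must lie in [0, 100]")
  mito <- sample_mito_levels(n, mparams, seed = child_seed(seed, "mito"))
  spec <- protein_spec(protein, mean_copies = mean_intensity, cv = cv,
                       rho = rho_from_mcv(target_mcv), role = "pro")
  intensity <- sample_protein_given_mito(mito, spec,
                                         seed = child_seed(seed, protein),
                                         mparams = mparams)
  structure(data.frame(cell_id = seq_len(n), mito = as.numeric(mito),
                       protein_intensity = intensity),
            protein = protein, target_mcv = target_mcv, seed = seed,
            class = c("if_table", "data.frame"))
}

#' Generate a toy two-condition expression table
#'
#' Builds an FPKM-style gene-by-condition table with a planted structure for
#' exercising the detection-threshold pipeline: a set of genes with exactly
#' one zero and one non-zero value whose non-zero values have median exactly
#' `planted_tau`; a set of genes at zero in both conditions; and a majority
#' of genes expressed in both conditions well above the threshold.
#'
#' @param n_genes Total number of genes (>= 10).
#' @param planted_tau The detection threshold the planted genes encode.
#' @param seed Integer seed.
#' @param frac_planted,frac_bothzero Fractions of planted one-zero genes and
#'   both-zero genes (the remainder is fully expressed).
#' @return Data frame `gene_id`, `low`, `high` (units: FPKM-like).
#' @export
make_toy_expression_table <- function(n_genes, planted_tau, seed = 1L,
                                      frac_planted = 0.2,
                                      frac_bothzero = 0.1) {
  if (n_genes < 10) stop("n_genes must be at least 10")
  stopifnot(planted_tau > 0)
  n_pl <- max(3L, round(n_genes * frac_planted))
  if (n_pl %% 2L == 0L) n_pl <- n_pl - 1L  # odd count: median is a datum
  n_z <- round(n_genes * frac_bothzero)
  n_expr <- n_genes - n_pl - n_z
  # planted non-zero values: symmetric around the median in rank, with the
  # middle value exactly planted_tau
  k <- (n_pl - 1L) / 2L
  vals <- planted_tau * c(seq(0.2, 0.9, length.out = k), 1,
                          seq(1.5, 4, length.out = k))
  tab <- with_seed(seed, {
    side <- sample(c(TRUE, FALSE), n_pl, replace = TRUE)
    low_pl <- ifelse(side, vals, 0)
    high_pl <- ifelse(side, 0, vals)
    expr <- matrix(rlnorm(2 * n_expr, log(50 * planted_tau), 1), ncol = 2)
    data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      low = c(low_pl, rep(0, n_z), expr[, 1]),
      high = c(high_pl, rep(0, n_z), expr[, 2])
    )
  })
  attr(tab, "planted_tau") <- planted_tau
  attr(tab, "seed") <- seed
  tab
}

#' Summary statistics of an imaging fixture
#'
#' Computes, over the apoptotic cells of a fixture, the Spearman rank
#' correlation between mitochondrial level and time to death, and the mean
#' times to death in the top and bottom mitochondrial quartiles. Quartile
#' boundaries are taken over the apoptotic subset, matching a boxplot built
#' from the tracked dying cells.
#'
#' @param fixture An `imaging_fixture`.
#' @return Named list: `spearman`, `mean_t_death_high_mito`,
#'   `mean_t_death_low_mito`, `n_apoptotic`, `mito_auc`.
#' @export
imaging_fixture_stats <- function(fixture) {
  ap <- fixture$fate == "apoptotic"
  m <- fixture$mito[ap]
  td <- fixture$t_death_h[ap]
  q <- quantile(m, c(0.25, 0.75), type = 7, names = FALSE)
  list(
    spearman = spearman_rho(m, td),
    mean_t_death_high_mito = mean(td[m >= q[2]]),
    mean_t_death_low_mito = mean(td[m <= q[1]]),
    n_apoptotic = sum(ap),
    mito_auc = roc_auc(fixture$mito[ap], fixture$mito[!ap])$auc
  )
}

#' Write a fixture with its JSON parameter sidecar
#'
#' @param fixture A data frame produced by a generator in this package.
#' @param path CSV output path; parameters and seed go to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(fixture, path) {
  utils::write.csv(as.data.frame(fixture), path, row.names = FALSE)
  side <- list(seed = attr(fixture, "seed"),
               params = attr(fixture, "params"),
               protein = attr(fixture, "protein"),
               target_mcv = attr(fixture, "target_mcv"),
               planted_tau = attr(fixture, "planted_tau"))
  side <- side[!vapply(side, is.null, TRUE)]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
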