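#' Default model configuration for the extrinsic apoptosis network
#'
#' Returns the full configuration (species, monomer composition, mass-action
#' reactions with rate constants, mean initial copy numbers) of the default
#' kinetic model: an EARM1.0-style receptor-to-effector-caspase network.
#' TRAIL binds its death receptor and forms an active death-inducing
#' signalling complex (DISC) that activates Caspase-8 under Flip inhibition;
#' active Caspase-8 is buffered by Bar, cleaves Bid to tBid (sequestered by
#' Mcl-1), tBid activates Bax, which (against Bcl-2 sequestration) dimerises
#' and tetramerises to form mitochondrial pores; pores release Smac and
#' cytochrome C; cytochrome C nucleates the apoptosome which, with the
#' Caspase-8 route and under XIAP inhibition, activates Caspase-3; Caspase-3
#' cleaves PARP and feeds back through Caspase-6 to Caspase-8.
#'
#' Rate constants are stored in per-second units (`1/s` for unimolecular,
#' `1/(molecule*s)` for bimolecular steps); bimolecular steps confined to the
#' mitochondrial compartment are scaled by the compartment volume fraction
#' `mito_volume_fraction`. Every value can be overridden via the `...`
#' arguments or by editing the returned list, and a full configuration can be
#' round-tripped through JSON (see [read_model_config()]).
#'
#' @param initial_means Named numeric vector overriding mean initial copy
#'   numbers (molecules/cell) of any species.
#' @param rate_overrides Named numeric vector overriding rate constants by
#'   reaction name.
#' @param mito_volume_fraction Volume fraction of the mitochondrial
#'   compartment used to scale its bimolecular rate constants (default 0.07).
#' @param turnover If `TRUE`, add first-order synthesis/degradation of the
#'   unbound precursors (off by default so that moiety conservation is exact).
#' @param turnover_rate Degradation rate constant (1/s) used when
#'   `turnover = TRUE`; synthesis rates are set to balance the mean initial
#'   copy numbers.
#' @param deactivation Named numeric vector of rate constants (1/s) for
#'   inhibitor-mediated inactivation of the active pro-apoptotic
#'   intermediates, extending the parent model's XIAP-mediated Caspase-3
#'   degradation motif to the other three inhibitor pairs: `C8` (Bar-bound
#'   active Caspase-8 to an inactive form), `tBid` (Mcl-1-bound tBid to an
#'   inactive form), and `MBax` (Bcl-2-mediated retro-translocation of
#'   mitochondrial Bax back to the inactive cytosolic form). These catalytic
#'   sinks turn each anti-apoptotic protein into a flux capacity, so
#'   commitment to MOMP is a genuine rate balance -- without them every
#'   irreversibly activated species accumulates until any ligand input,
#'   however small, eventually trips the pore and fractional killing cannot
#'   arise. Inactive forms are dead-end species carrying the same monomer
#'   composition, so moiety conservation stays exact.
#' @return A list with elements `species` (data frame: `name`,
#'   `initial_mean`), `composition` (named list of named integer vectors:
#'   monomer content of every species), `reactions` (list of
#'   `list(name, reactants, products, k)`), and `observables` (named list of
#'   species sets: `casp8_active`, `cytosolic_smac`, `pore`).
#' @export
default_model_config <- function(initial_means = NULL, rate_overrides = NULL,
                                 mito_volume_fraction = 0.07,
                                 turnover = FALSE, turnover_rate = 2.9e-6,
                                 deactivation = c(C8 = 6e-4,
                                                  tBid = 6e-4,
                                                  MBax = 4.4e-4)) {
  v <- mito_volume_fraction
  stopifnot(v > 0)

  comp <- list(
    L = c(L = 1), R = c(R = 1), L_R = c(L = 1, R = 1), DISC = c(L = 1, R = 1),
    flip = c(flip = 1), flip_DISC = c(flip = 1, L = 1, R = 1),
    pC8 = c(C8 = 1), DISC_pC8 = c(L = 1, R = 1, C8 = 1), C8 = c(C8 = 1),
    C8_inact = c(C8 = 1), tBid_inact = c(Bid = 1),
    BAR = c(BAR = 1), BAR_C8 = c(BAR = 1, C8 = 1),
    pC3 = c(C3 = 1), pC3_C8 = c(C3 = 1, C8 = 1), C3 = c(C3 = 1),
    pC6 = c(C6 = 1), pC6_C3 = c(C6 = 1, C3 = 1), C6 = c(C6 = 1),
    pC8_C6 = c(C8 = 1, C6 = 1),
    XIAP = c(XIAP = 1), XIAP_C3 = c(XIAP = 1, C3 = 1), C3_U = c(C3 = 1),
    PARP = c(PARP = 1), PARP_C3 = c(PARP = 1, C3 = 1), cPARP = c(PARP = 1),
    Bid = c(Bid = 1), Bid_C8 = c(Bid = 1, C8 = 1), tBid = c(Bid = 1),
    Mcl1 = c(Mcl1 = 1), tBid_Mcl1 = c(Bid = 1, Mcl1 = 1),
    Bax = c(Bax = 1), Bax_tBid = c(Bax = 1, Bid = 1), aBax = c(Bax = 1),
    MBax = c(Bax = 1), Bcl2 = c(Bcl2 = 1), MBax_Bcl2 = c(Bax = 1, Bcl2 = 1),
    Bax2 = c(Bax = 2), Bax2_Bcl2 = c(Bax = 2, Bcl2 = 1),
    Bax4 = c(Bax = 4), Bax4_Bcl2 = c(Bax = 4, Bcl2 = 1),
    M = c(M = 1), Bax4_M = c(Bax = 4, M = 1), AMito = c(Bax = 4, M = 1),
    mCytoC = c(CytoC = 1), AMito_mCytoC = c(Bax = 4, M = 1, CytoC = 1),
    ACytoC = c(CytoC = 1), cCytoC = c(CytoC = 1),
    Apaf = c(Apaf = 1), Apaf_cCytoC = c(Apaf = 1, CytoC = 1),
    aApaf = c(Apaf = 1), pC9 = c(C9 = 1), Apop = c(Apaf = 1, C9 = 1),
    Apop_pC3 = c(Apaf = 1, C9 = 1, C3 = 1),
    Apop_XIAP = c(Apaf = 1, C9 = 1, XIAP = 1),
    mSmac = c(Smac = 1), AMito_mSmac = c(Bax = 4, M = 1, Smac = 1),
    ASmac = c(Smac = 1), cSmac = c(Smac = 1),
    cSmac_XIAP = c(Smac = 1, XIAP = 1)
  )

  init <- c(
    L = 3000, R = 200, flip = 100, pC8 = 20000, BAR = 1000,
    pC3 = 10000, pC6 = 10000, XIAP = 1e5, PARP = 1e6,
    Bid = 4e4, Mcl1 = 2e4, Bax = 1e5, Bcl2 = 2e4,
    M = 5e5, mCytoC = 5e5, mSmac = 1e5, Apaf = 1e5, pC9 = 1e5
  )
  species <- names(comp)
  init_full <- stats::setNames(numeric(length(species)), species)
  init_full[names(init)] <- init
  if (!is.null(initial_means)) {
    bad <- setdiff(names(initial_means), species)
    if (length(bad)) stop("unknown species in initial_means: ",
                          paste(bad, collapse = ", "))
    init_full[names(initial_means)] <- initial_means
  }

  rxns <- list()
  bind <- function(name, a, b, ab, kf, kr) {
    rxns[[length(rxns) + 1L]] <<- list(name = paste0(name, "_f"),
                                       reactants = c(a, b), products = ab,
                                       k = kf)
    rxns[[length(rxns) + 1L]] <<- list(name = paste0(name, "_r"),
                                       reactants = ab, products = c(a, b),
                                       k = kr)
  }
  cat1 <- function(name, complex, products, kc) {
    rxns[[length(rxns) + 1L]] <<- list(name = name, reactants = complex,
                                       products = products, k = kc)
  }
  uni <- function(name, a, b, kf, kr) {
    rxns[[length(rxns) + 1L]] <<- list(name = paste0(name, "_f"),
                                       reactants = a, products = b, k = kf)
    rxns[[length(rxns) + 1L]] <<- list(name = paste0(name, "_r"),
                                       reactants = b, products = a, k = kr)
  }

  # Ligand-binding forward rate is a calibrated value: with the parent
  # model's weaker affinity, receptor occupancy keeps rising well past
  # 63 ng/ml and the simulated kill fraction cannot plateau the way the
  # measured dose-response does (see the methods vignette).
  bind("L_bind_R", "L", "R", "L_R", 2e-6, 1e-3)
  cat1("DISC_formation", "L_R", "DISC", 2e-5)
  # Receptor turnover: ligand-bound signalling complexes are internalised
  # and recycled, so the active DISC level reaches a dose-dependent steady
  # state within the first hour instead of ramping for the whole experiment.
  cat1("DISC_turnover", "DISC", c("L", "R"), 7e-4)
  bind("flip_bind_DISC", "flip", "DISC", "flip_DISC", 1e-6, 1e-3)
  bind("pC8_bind_DISC", "pC8", "DISC", "DISC_pC8", 1e-6, 1e-3)
  cat1("C8_activation", "DISC_pC8", c("C8", "DISC"), 1)
  bind("BAR_bind_C8", "BAR", "C8", "BAR_C8", 1e-6, 1e-3)
  bind("pC3_bind_C8", "pC3", "C8", "pC3_C8", 1e-7, 1e-3)
  cat1("C3_activation_by_C8", "pC3_C8", c("C3", "C8"), 1)
  bind("pC6_bind_C3", "pC6", "C3", "pC6_C3", 1e-7, 1e-3)
  cat1("C6_activation", "pC6_C3", c("C6", "C3"), 1)
  bind("pC8_bind_C6", "pC8", "C6", "pC8_C6", 3e-7, 1e-3)
  cat1("C8_activation_by_C6", "pC8_C6", c("C8", "C6"), 1)
  bind("XIAP_bind_C3", "XIAP", "C3", "XIAP_C3", 2e-6, 1e-3)
  cat1("C3_degradation_by_XIAP", "XIAP_C3", c("XIAP", "C3_U"), 0.1)
  bind("PARP_bind_C3", "PARP", "C3", "PARP_C3", 1e-6, 1e-2)
  cat1("PARP_cleavage", "PARP_C3", c("cPARP", "C3"), 1)
  bind("Bid_bind_C8", "Bid", "C8", "Bid_C8", 1e-6, 1e-3)
  cat1("Bid_cleavage", "Bid_C8", c("tBid", "C8"), 1)
  bind("tBid_bind_Mcl1", "tBid", "Mcl1", "tBid_Mcl1", 1e-6, 1e-3)
  bind("Bax_bind_tBid", "Bax", "tBid", "Bax_tBid", 1e-7, 1e-3)
  cat1("Bax_activation", "Bax_tBid", c("aBax", "tBid"), 1)
  uni("Bax_translocation", "aBax", "MBax", 1e-2, 1e-2)
  bind("MBax_bind_Bcl2", "MBax", "Bcl2", "MBax_Bcl2", 1e-6 / v, 1e-3)
  bind("Bax_dimerisation", "MBax", "MBax", "Bax2", 1e-6 / v, 1e-3)
  bind("Bax2_bind_Bcl2", "Bax2", "Bcl2", "Bax2_Bcl2", 1e-6 / v, 1e-3)
  bind("Bax_tetramerisation", "Bax2", "Bax2", "Bax4", 1e-6 / v, 1e-3)
  bind("Bax4_bind_Bcl2", "Bax4", "Bcl2", "Bax4_Bcl2", 1e-6 / v, 1e-3)
  bind("Bax4_bind_M", "Bax4", "M", "Bax4_M", 1e-6 / v, 1e-3)
  cat1("pore_formation", "Bax4_M", "AMito", 1)
  # Per-pore transport is kept slow so that releasing the mitochondrial
  # pool on the hour scale requires pore numbers of the order of the site
  # pool itself (full MOMP); a handful of stray pores in uncommitted cells
  # then leaks only a negligible fraction in 24 h, which keeps
  # permeabilisation effectively all-or-none.
  bind("pore_bind_mCytoC", "AMito", "mCytoC", "AMito_mCytoC", 2e-9 / v, 1e-3)
  cat1("CytoC_release", "AMito_mCytoC", c("AMito", "ACytoC"), 10)
  bind("pore_bind_mSmac", "AMito", "mSmac", "AMito_mSmac", 2e-9 / v, 1e-3)
  cat1("Smac_release", "AMito_mSmac", c("AMito", "ASmac"), 10)
  uni("CytoC_translocation", "ACytoC", "cCytoC", 1e-2, 1e-2)
  bind("Apaf_bind_cCytoC", "Apaf", "cCytoC", "Apaf_cCytoC", 5e-7, 1e-3)
  cat1("Apaf_activation", "Apaf_cCytoC", c("aApaf", "cCytoC"), 1)
  bind("apoptosome_assembly", "aApaf", "pC9", "Apop", 5e-8, 1e-3)
  bind("Apop_bind_pC3", "Apop", "pC3", "Apop_pC3", 5e-9, 1e-3)
  cat1("C3_activation_by_Apop", "Apop_pC3", c("Apop", "C3"), 1)
  uni("Smac_translocation", "ASmac", "cSmac", 1e-2, 1e-2)
  bind("Apop_bind_XIAP", "Apop", "XIAP", "Apop_XIAP", 2e-6, 1e-3)
  bind("cSmac_bind_XIAP", "cSmac", "XIAP", "cSmac_XIAP", 7e-6, 1e-3)
  if (!is.na(deactivation["C8"]) && deactivation[["C8"]] > 0) {
    cat1("C8_inactivation_by_BAR", "BAR_C8", c("BAR", "C8_inact"),
         deactivation[["C8"]])
  }
  if (!is.na(deactivation["tBid"]) && deactivation[["tBid"]] > 0) {
    cat1("tBid_inactivation_by_Mcl1", "tBid_Mcl1", c("Mcl1", "tBid_inact"),
         deactivation[["tBid"]])
  }
  if (!is.na(deactivation["MBax"]) && deactivation[["MBax"]] > 0) {
    cat1("Bax_retrotranslocation_by_Bcl2", "MBax_Bcl2", c("Bax", "Bcl2"),
         deactivation[["MBax"]])
  }

  if (turnover) {
    for (s in names(init)[init > 0 & names(init) != "L"]) {
      rxns[[length(rxns) + 1L]] <- list(name = paste0("degradation_", s),
                                        reactants = s, products = character(),
                                        k = turnover_rate)
      rxns[[length(rxns) + 1L]] <- list(name = paste0("synthesis_", s),
                                        reactants = character(), products = s,
                                        k = turnover_rate * init_full[[s]])
    }
  }

  if (!is.null(rate_overrides)) {
    nm <- vapply(rxns, `[[`, "", "name")
    bad <- setdiff(names(rate_overrides), nm)
    if (length(bad)) stop("unknown reaction in rate_overrides: ",
                          paste(bad, collapse = ", "))
    for (rn in names(rate_overrides)) {
      rxns[[match(rn, nm)]]$k <- rate_overrides[[rn]]
    }
  }

  list(
    species = data.frame(name = species, initial_mean = unname(init_full),
                         stringsAsFactors = FALSE),
    composition = comp,
    reactions = rxns,
    observables = list(
      # cumulative activated Caspase-8: its time derivative is the
      # activation rate (production flux), insensitive to downstream
      # sequestration or inactivation of the already-activated enzyme
      casp8_active = c("C8", "BAR_C8", "pC3_C8", "Bid_C8", "C8_inact"),
      cytosolic_smac = c("cSmac", "cSmac_XIAP"),
      pore = "AMito"
    ),
    turnover = turnover
  )
}

#' Build a validated mass-action reaction network
#'
#' Compiles a model configuration (see [default_model_config()]) into a
#' `reaction_network` object: the stoichiometry matrix, reactant index pairs
#' for mass-action rate evaluation, and the conserved moieties.
#'
#' Conserved moieties are detected from the stoichiometry left null space:
#' candidate non-negative integer vectors are generated from the monomer
#' composition of the species, each candidate is verified exactly against the
#' stoichiometry matrix (`w %*% S == 0`), and the verified set is checked to
#' span the full left null space (its size must equal
#' `nrow(S) - rank(S)`). Coefficients larger than one arise from
#' oligomerisation (Bax dimers and tetramers carry two and four Bax units).
#'
#' @param config A model configuration list; default [default_model_config()].
#' @return An object of class `reaction_network`: list with `species`,
#'   `initial_means`, `reactions`, `k` (rate constants), `stoichiometry`
#'   (species x reactions), `reactant_idx` (2 x reactions, 0 = absent),
#'   `conserved_moieties` (named list of named integer coefficient vectors),
#'   `observables`.
#' @examples
#' net <- build_network()
#' net
#' @export
build_network <- function(config = default_model_config()) {
  sp <- config$species$name
  if (anyDuplicated(sp)) stop("duplicate species names in configuration")
  nsp <- length(sp)
  rxns <- config$reactions
  nrx <- length(rxns)

  k <- vapply(rxns, function(r) as.numeric(r$k), 0)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("rate constants must be finite and non-negative")
  }

  S <- matrix(0L, nsp, nrx, dimnames = list(sp, vapply(rxns, `[[`, "", "name")))
  ridx <- matrix(0L, 2L, nrx)
  for (j in seq_len(nrx)) {
    r <- rxns[[j]]
    if (length(r$reactants) > 2L) {
      stop("mass-action reactions are limited to two reactants: ", r$name)
    }
    for (x in c(r$reactants, r$products)) {
      if (!x %in% sp) stop("unknown species '", x, "' in reaction ", r$name)
    }
    for (x in r$reactants) S[x, j] <- S[x, j] - 1L
    for (x in r$products) S[x, j] <- S[x, j] + 1L
    ridx[seq_along(r$reactants), j] <- match(r$reactants, sp)
  }

  moieties <- find_conserved_moieties(S, config$composition,
                                      strict = !isTRUE(config$turnover))

  structure(list(
    species = sp,
    initial_means = stats::setNames(config$species$initial_mean, sp),
    reactions = rxns,
    k = stats::setNames(k, colnames(S)),
    stoichiometry = S,
    reactant_idx = ridx,
    conserved_moieties = moieties,
    observables = config$observables,
    config = config
  ), class = "reaction_network")
}

#' Detect conserved moieties from a stoichiometry matrix
#'
#' Generates candidate conservation vectors from the monomer composition of
#' each species and keeps those lying exactly in the left null space of the
#' stoichiometry matrix. If the verified set does not span the whole left
#' null space, a warning reports the missing dimensions.
#'
#' @param S Integer stoichiometry matrix (species x reactions).
#' @param composition Named list: per species, a named integer vector of
#'   monomer content.
#' @param strict If `TRUE` (default) error when a composition-derived
#'   candidate is not conserved; if `FALSE` (models with turnover) drop it.
#' @return Named list of conservation vectors (named integer coefficients over
#'   their support).
#' @export
find_conserved_moieties <- function(S, composition, strict = TRUE) {
  monomers <- unique(unlist(lapply(composition, names)))
  out <- list()
  for (m in monomers) {
    w <- vapply(rownames(S), function(s) {
      cc <- composition[[s]]
      if (!is.null(cc) && m %in% names(cc)) cc[[m]] else 0
    }, 0)
    resid <- drop(w %*% S)
    if (all(resid == 0)) {
      out[[m]] <- w[w != 0]
    } else if (strict) {
      stop("composition moiety '", m, "' is not conserved by reactions: ",
           paste(colnames(S)[resid != 0], collapse = ", "))
    }
  }
  nullity <- nrow(S) - qr(S)$rank
  if (length(out) < nullity) {
    warning(sprintf(
      "found %d conserved moieties but the left null space has dimension %d",
      length(out), nullity))
  }
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network\n")
  cat(sprintf("  species:            %d\n", length(x$species)))
  cat(sprintf("  reactions:          %d\n", length(x$reactions)))
  cat(sprintf("  conserved moieties: %d (%s)\n", length(x$conserved_moieties),
              paste(names(x$conserved_moieties), collapse = ", ")))
  invisible(x)
}

#' Convert a TRAIL dose to ligand molecules per cell
#'
#' Linear conversion through the origin with a configurable anchor: by default
#' 50 ng/ml corresponds to 3000 ligand molecules per cell, the convention of
#' the parent model family for this pathway.
#'
#' @param dose Dose in ng/ml (scalar or vector), must be non-negative.
#' @param anchor_dose,anchor_copies The anchor point of the linear map.
#' @return Ligand molecules per cell.
#' @examples
#' trail_copies_from_dose(c(0, 32, 50, 250))
#' @export
trail_copies_from_dose <- function(dose, anchor_dose = 50,
                                   anchor_copies = 3000) {
  if (any(dose < 0)) stop("dose must be non-negative")
  stopifnot(anchor_dose > 0, anchor_copies >= 0)
  dose * (anchor_copies / anchor_dose)
}

#' Read a model configuration from a JSON document
#'
#' The JSON layout mirrors [default_model_config()]:
#' `{"species": [{"name": ..., "initial_mean": ...}],
#'   "composition": {...}, "reactions": [{"name", "reactants", "products",
#'   "k"}], "observables": {...}}`.
#'
#' @param path Path to a JSON file.
#' @return A model configuration list suitable for [build_network()].
#' @seealso [write_model_config()]
#' @export
read_model_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- data.frame(
    name = vapply(j$species, `[[`, "", "name"),
    initial_mean = vapply(j$species, function(s) as.numeric(s$initial_mean), 0),
    stringsAsFactors = FALSE
  )
  comp <- lapply(j$composition, function(x) unlist(x))
  rxns <- lapply(j$reactions, function(r) {
    list(name = r$name,
         reactants = as.character(unlist(r$reactants)),
         products = as.character(unlist(r$products)),
         k = as.numeric(r$k))
  })
  obs <- lapply(j$observables, function(x) as.character(unlist(x)))
  list(species = species, composition = comp, reactions = rxns,
       observables = obs, turnover = isTRUE(j$turnover))
}

#' Write a model configuration to a JSON document
#'
#' @param config A model configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  j <- list(
    species = lapply(seq_len(nrow(config$species)), function(i) {
      list(name = config$species$name[i],
           initial_mean = config$species$initial_mean[i])
    }),
    composition = lapply(config$composition, as.list),
    reactions = config$reactions,
    observables = config$observables,
    turnover = isTRUE(config$turnover)
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
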