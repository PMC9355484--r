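# Forward simulation of a two-cultivar x two-treatment waterlogging
# experiment in a randomized complete block design: morphology traits,
# steady-state gas exchange paired with raw fluorescence traces, A/Ci
# curves and light-response curves, generated from a scenario preset that
# encodes per-cultivar fractional treatment effects and pooled-SEM
# calibrated noise.
#
# Noise model: Gaussian block effects (additive, shared by all plots of a
# block within a trait), Gaussian plot effects with SD equal to the pooled
# SEM x sqrt(blocks) (so the ANOVA error term reproduces the printed SEM in
# expectation), and Gaussian plant-level subsampling error at half the plot
# SD. Zero noise makes every cell mean equal its configured value exactly.

#' Default scenario configuration
#'
#' The preset encodes a 2-cultivar ("Marketmore" tolerant, "Straight 8"
#' sensitive) x 2-treatment (control, waterlogged) x 4-block design with 6
#' measured plants per plot, 10 days of waterlogging, and per-cultivar
#' fractional effects and pooled-SEM noise levels for every simulated trait
#' (morphology: LN, LA, FM, DM; steady-state gas exchange: gs, E, WUE, Ci;
#' fluorescence yields; FvCB and light-response curve presets). Effects are
#' decline-positive fractions; negative values encode increases.
#'
#' Control-cell absolute means are plausible fixed constants (not
#' authoritative — only the relative effects and noise calibrations matter
#' for recovery analyses). The control intercellular CO2 is solved so that
#' the configured Ci increase and stomatal-limitation (Ls) decline hold
#' simultaneously under Ls = 1 − Ci/Ca. The waterlogged ΦPSII targets are
#' scaled by the configured ETR declines (ETR ∝ ΦPSII at fixed actinic
#' light).
#'
#' @param blocks number of blocks (default 4).
#' @param plants_per_cell measured plants per plot (default 6; the design
#'   also supports the 12 grown plants per plot via this argument).
#' @param noise_scale global multiplier on all noise SDs (0 = deterministic
#'   means; 1 = SEM-calibrated noise).
#' @return list of class `scenario_config`.
#' @export
default_paper_config <- function(blocks = 4, plants_per_cell = 6,
                                 noise_scale = 1) {
  cultivars <- c("Marketmore", "Straight 8")
  treatments <- c("control", "waterlogged")
  # E's printed SEM (0.0007) is on a mol basis; 0.7 in the package's mmol
  # convention
  sem <- c(LN = 0.136, LA = 13.928, FM = 0.403, DM = 0.046,
           A = 1.23, E = 0.7, gs = 0.153, Ci = 4.91, WUE = 2.77,
           Ls = 0.0116,
           Vc = 1.46, Vo = 0.478, Vcmax = 8.24, Jmax = 11.30,
           FvFm = 0.008, Fo = 35.95, Fm = 85.43, Fs = 64.09, qP = 0.03,
           PhiPSII = 0.03, ETR = 7.14, NPQ = 0.09, PhiNO = 0.015,
           PhiNPQ = 0.029, one_minus_qL = 0.03)
  plot_sd <- sem * sqrt(blocks)

  morphology_means <- list(
    "Marketmore" = c(LN = 21, LA = 580, FM = 12.5, DM = 1.15),
    "Straight 8" = c(LN = 22, LA = 610, FM = 13.0, DM = 1.20))
  morphology_effects <- list(
    "Marketmore" = c(LN = 0.08, LA = 0.08, FM = 0.14, DM = 0.08),
    "Straight 8" = c(LN = 0.14, LA = 0.17, FM = 0.25, DM = 0.25))

  # gs / E / WUE declines and Ci increases per cultivar; control Ci chosen
  # so that the Ls decline is simultaneously consistent with Ls = 1 - Ci/Ca.
  physiology_effects <- list(
    "Marketmore" = c(gs = 0.22, E = 0.14, WUE = 0.52, Ci = -0.06,
                     Ls = 0.43, Vcmax = 0.14, Jmax = 0.15,
                     Vc = 0.23, Vo = 0.33, ETR = 0.23, PhiPSII = 0.22,
                     Fo = 0.05, Amax = 0.08),
    "Straight 8" = c(gs = 0.24, E = 0.13, WUE = 0.40, Ci = -0.04,
                     Ls = 0.34, Vcmax = 0.33, Jmax = 0.14,
                     Vc = 0.19, Vo = 0.28, ETR = 0.26, PhiPSII = 0.25,
                     Fo = 0.06, Amax = 0.20))
  ca <- 415
  ci_control <- vapply(cultivars, function(cv) {
    e_ci <- -physiology_effects[[cv]][["Ci"]]   # fractional increase
    e_ls <- physiology_effects[[cv]][["Ls"]]    # fractional decline
    # (1 - (1+e_ci) r) = (1 - e_ls)(1 - r), r = Ci_c/Ca
    r <- e_ls / (e_ci + e_ls)
    ca * r
  }, numeric(1))
  physiology_means <- list(
    "Marketmore" = c(gs = 0.85, E = 3.5, WUE = 21,
                     Ci = ci_control[["Marketmore"]]),
    "Straight 8" = c(gs = 0.80, E = 3.4, WUE = 20,
                     Ci = ci_control[["Straight 8"]]))

  fvcb_presets <- list(
    "Marketmore" = list(control = fvcb_params(vcmax = 110, j = 160,
                                              rd = 1.5),
                        waterlogged = fvcb_params(vcmax = 110 * (1 - 0.14),
                                                  j = 160 * (1 - 0.15),
                                                  rd = 1.5)),
    "Straight 8" = list(control = fvcb_params(vcmax = 100, j = 150,
                                              rd = 1.5),
                        waterlogged = fvcb_params(vcmax = 100 * (1 - 0.33),
                                                  j = 150 * (1 - 0.14),
                                                  rd = 1.5)))

  # Ye-model presets: the amplitude phi is calibrated so the control
  # forward value at I = 1500 equals the reported control Amax (23.62
  # Marketmore, 19.59 Straight 8); waterlogged presets scale phi by the
  # configured Amax decline (Amax is proportional to phi in this family).
  ye_shape <- c(beta = 5e-5, gamma = 2e-3, ic = 25)
  amax_at_unit_phi <- (1 - ye_shape[["beta"]] * 1500) /
    (1 + ye_shape[["gamma"]] * 1500) * (1500 - ye_shape[["ic"]])
  amax_control <- c("Marketmore" = 23.62, "Straight 8" = 19.59)
  light_presets <- lapply(cultivars, function(cv) {
    phi_c <- amax_control[[cv]] / amax_at_unit_phi
    eff <- physiology_effects[[cv]][["Amax"]]
    list(control = c(phi = phi_c, ye_shape),
         waterlogged = c(phi = phi_c * (1 - eff), ye_shape))
  })
  names(light_presets) <- cultivars

  # Fluorescence yield targets per cell; waterlogged PhiPSII scaled by the
  # ETR decline; PhiNO follows from the partition identity
  # PhiPSII = 1 - PhiNO (1 + NPQ).
  fl_control <- list(
    "Marketmore" = c(fv_fm = 0.78, phi_psii = 0.30, npq = 1.20),
    "Straight 8" = c(fv_fm = 0.77, phi_psii = 0.28, npq = 1.25))
  fl_water_npq <- c("Marketmore" = 1.35, "Straight 8" = 1.40)
  fl_water_fvfm <- c("Marketmore" = 0.76, "Straight 8" = 0.75)
  fluorescence_targets <- lapply(cultivars, function(cv) {
    ctl <- fl_control[[cv]]
    ctl["phi_no"] <- (1 - ctl[["phi_psii"]]) / (1 + ctl[["npq"]])
    eff <- physiology_effects[[cv]][["ETR"]]
    wl <- c(fv_fm = fl_water_fvfm[[cv]],
            phi_psii = ctl[["phi_psii"]] * (1 - eff),
            npq = fl_water_npq[[cv]])
    wl["phi_no"] <- (1 - wl[["phi_psii"]]) / (1 + wl[["npq"]])
    list(control = ctl, waterlogged = wl)
  })
  names(fluorescence_targets) <- cultivars

  cfg <- structure(list(
    cultivars = cultivars, treatments = treatments,
    blocks = blocks, plants_per_cell = plants_per_cell,
    ca = ca,
    morphology_means = morphology_means,
    morphology_effects = morphology_effects,
    physiology_means = physiology_means,
    physiology_effects = physiology_effects,
    fvcb_presets = fvcb_presets,
    light_presets = light_presets,
    fluorescence_targets = fluorescence_targets,
    fm_scale = 2000,
    sem = sem,
    plot_sd = plot_sd * noise_scale,
    plant_sd_frac = 0.5,    # plant-level SD as fraction of plot SD
    block_sd_frac = 0.5,    # block-effect SD as fraction of plot SD
    aci_noise_cv = 0.02 * (noise_scale > 0),
    light_point_sd = 0.4 * noise_scale,
    noise_scale = noise_scale,
    protocol = default_protocol()),
    class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the design is non-degenerate, all effect fractions lie in
#' (−1, 1), noise SDs are non-negative and the fluorescence yield targets
#' satisfy the energy-partition identity.
#'
#' @param config a `scenario_config`.
#' @return the config, invisibly; stops with an aggregated message on
#'   violation.
#' @export
validate_scenario_config <- function(config) {
  errs <- character()
  if (config$blocks < 2) errs <- c(errs, "blocks must be >= 2")
  if (config$plants_per_cell < 1) errs <- c(errs, "plants_per_cell >= 1")
  eff <- unlist(c(config$morphology_effects, config$physiology_effects))
  if (any(eff <= -1 | eff >= 1))
    errs <- c(errs, "effect fractions must lie in (-1, 1)")
  if (any(config$plot_sd < 0)) errs <- c(errs, "noise SDs must be >= 0")
  for (cv in config$cultivars) for (tr in config$treatments) {
    tg <- config$fluorescence_targets[[cv]][[tr]]
    resid <- 1 - tg[["phi_no"]] * (1 + tg[["npq"]]) - tg[["phi_psii"]]
    if (abs(resid) > 1e-9)
      errs <- c(errs, sprintf("fluorescence targets inconsistent for %s/%s",
                              cv, tr))
  }
  if (length(errs)) stop("invalid scenario config: ",
                         paste(errs, collapse = "; "))
  invisible(config)
}

#' Construct a raw fluorescence record realizing target yields
#'
#' Inverse of the quenching calculus: given mutually consistent targets
#' (Fv/Fm, ΦPSII, NPQ, ΦNO) the raw F-levels are
#' Fm = fm_scale, Fo = Fm(1 − Fv/Fm), Fm′ = Fm/(1 + NPQ), Fs = ΦNO·Fm, and
#' Fo′ from the Oxborough–Baker relation. Running
#' [light_adapted_indices()] on the result recovers the targets to
#' numerical precision. The targets must satisfy the partition identity
#' ΦPSII = 1 − ΦNO(1 + NPQ).
#'
#' @param fv_fm,phi_psii,npq,phi_no target yields; all in (0, 1) except
#'   npq ≥ 0.
#' @param fm_scale maximal dark-adapted fluorescence level, arbitrary
#'   units; pure scale (indices are invariant to it).
#' @param tol tolerance on the partition-identity residual.
#' @return list with fields `fo`, `fm`, `fs`, `fm_prime`, `fo_prime`.
#' @export
#' @examples
#' r <- fluorescence_from_targets(0.75, 0.4, 0.6, 0.375, fm_scale = 2000)
#' light_adapted_indices(r)$phi_psii  # 0.4
fluorescence_from_targets <- function(fv_fm, phi_psii, npq, phi_no,
                                      fm_scale = 2000, tol = 1e-6) {
  if (fv_fm <= 0 || fv_fm >= 1 || phi_psii <= 0 || phi_psii >= 1 ||
      phi_no <= 0 || phi_no >= 1 || npq < 0)
    stop("targets out of range")
  resid <- 1 - phi_no * (1 + npq) - phi_psii
  if (abs(resid) > tol)
    stop("inconsistent yield targets: partition identity residual = ",
         format(resid, digits = 6))
  fm <- fm_scale
  fo <- fm * (1 - fv_fm)
  fm_prime <- fm / (1 + npq)
  fs <- phi_no * fm
  fo_prime <- estimate_fo_prime(fo, fm, fm_prime)
  list(fo = fo, fm = fm, fs = fs, fm_prime = fm_prime,
       fo_prime = fo_prime)
}

# treatment mean for a trait: control mean x (1 - effect)
.cell_mean <- function(control_mean, effect, treatment) {
  if (treatment == "control") control_mean else control_mean * (1 - effect)
}

#' Simulate a full experiment from a scenario configuration
#'
#' Forward-simulates the experiment bundle: a long morphology trait table,
#' a steady-state gas-exchange table with paired raw fluorescence columns
#' (in the CSV dialect of [read_gas_table()]), per-plot A/Ci curves at the
#' protocol CO2 setpoints (via [fvcb_forward()]) and per-plot
#' light-response curves at the protocol PPFD levels (via
#' [light_forward()]). Identical seeds give identical bundles; with
#' `noise_scale = 0` in the config every simulated value equals its
#' configured cell mean exactly.
#'
#' @param config a [default_paper_config()]-style `scenario_config`.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param components subset of
#'   `c("morphology", "gas", "aci", "light")` to generate.
#' @return list of class `experiment_bundle` with elements `morphology`
#'   (long TraitTable), `gas` (steady-state table incl. fluorescence
#'   columns), `aci` (long curve table), `light` (long curve table),
#'   `config`, `seed`.
#' @export
simulate_experiment <- function(config = default_paper_config(), seed = 1,
                                components = c("morphology", "gas",
                                               "aci", "light")) {
  validate_scenario_config(config)
  with_seed(seed, {
    design <- expand.grid(cultivar = config$cultivars,
                          treatment = config$treatments,
                          block = seq_len(config$blocks),
                          stringsAsFactors = FALSE)
    out <- list(config = config, seed = seed)

    draw_trait <- function(trait, means_by_cv, effects_by_cv, clamp_min = -Inf) {
      sd_plot <- if (trait %in% names(config$plot_sd))
        config$plot_sd[[trait]] else 0
      sd_plant <- sd_plot * config$plant_sd_frac
      sd_block <- sd_plot * config$block_sd_frac
      blk_eff <- stats::rnorm(config$blocks, 0, sd_block)
      rows <- lapply(seq_len(nrow(design)), function(r) {
        cv <- design$cultivar[r]; tr <- design$treatment[r]
        bl <- design$block[r]
        mu <- .cell_mean(means_by_cv[[cv]][[trait]],
                         effects_by_cv[[cv]][[trait]], tr)
        plot_eff <- stats::rnorm(1, 0, sd_plot)
        vals <- mu + blk_eff[bl] + plot_eff +
          stats::rnorm(config$plants_per_cell, 0, sd_plant)
        vals <- pmax(vals, clamp_min)
        data.frame(cultivar = cv, treatment = tr, block = bl,
                   plant = seq_len(config$plants_per_cell),
                   trait = trait, value = vals)
      })
      do.call(rbind, rows)
    }

    if ("morphology" %in% components) {
      traits <- names(config$morphology_means[[1]])
      out$morphology <- do.call(rbind, lapply(traits, function(tt)
        draw_trait(tt, config$morphology_means, config$morphology_effects,
                   clamp_min = 1e-6)))
    }

    if ("gas" %in% components) {
      gs_t <- draw_trait("gs", config$physiology_means,
                         config$physiology_effects, clamp_min = 0.01)
      wue_t <- draw_trait("WUE", config$physiology_means,
                          config$physiology_effects, clamp_min = 0.5)
      e_t <- draw_trait("E", config$physiology_means,
                        config$physiology_effects, clamp_min = 0.01)
      ci_t <- draw_trait("Ci", config$physiology_means,
                         config$physiology_effects, clamp_min = 1)
      # fluorescence: jitter phi_psii and npq at plot/plant level, derive
      # phi_no from the partition identity so targets stay consistent
      key <- c("cultivar", "treatment", "block", "plant")
      gas <- gs_t[key]
      gas$gs <- gs_t$value
      gas$E <- e_t$value
      gas$Ci <- pmin(ci_t$value, config$ca - 1)
      gas$Ca <- config$ca
      gas$A <- wue_t$value * gas$gs   # WUE = A/gs holds by construction
      gas$Q <- config$protocol$actinic
      gas$Tleaf <- config$protocol$chamber_t
      gas$RH <- config$protocol$chamber_rh

      sd_phi <- config$plot_sd[["PhiPSII"]]
      sd_npq <- config$plot_sd[["NPQ"]]
      sd_fvfm <- config$plot_sd[["FvFm"]]
      sd_fm <- config$plot_sd[["Fm"]]
      n <- nrow(gas)
      fl <- matrix(NA_real_, n, 5,
                   dimnames = list(NULL, c("Fo", "Fm", "Fs", "Fmp", "Fop")))
      cellkey <- paste(gas$cultivar, gas$treatment, gas$block)
      plot_eff <- lapply(unique(cellkey), function(k)
        stats::rnorm(3, 0, c(sd_phi, sd_npq, sd_fvfm)))
      names(plot_eff) <- unique(cellkey)
      for (r in seq_len(n)) {
        tg <- config$fluorescence_targets[[gas$cultivar[r]]][[gas$treatment[r]]]
        pe <- plot_eff[[cellkey[r]]]
        pl <- stats::rnorm(3, 0, config$plant_sd_frac *
                             c(sd_phi, sd_npq, sd_fvfm))
        phi_psii <- min(max(tg[["phi_psii"]] + pe[1] + pl[1], 0.02), 0.9)
        npq <- max(tg[["npq"]] + pe[2] + pl[2], 0.01)
        fv_fm <- min(max(tg[["fv_fm"]] + pe[3] + pl[3], 0.5), 0.85)
        phi_no <- (1 - phi_psii) / (1 + npq)
        fmsc <- max(config$fm_scale + stats::rnorm(1, 0, sd_fm), 200)
        rec <- fluorescence_from_targets(fv_fm, phi_psii, npq, phi_no,
                                         fm_scale = fmsc)
        fl[r, ] <- c(rec$fo, rec$fm, rec$fs, rec$fm_prime, rec$fo_prime)
      }
      gas <- cbind(gas, as.data.frame(fl))
      out$gas <- gas
    }

    if ("aci" %in% components) {
      grid <- aci_grid(config$protocol)
      rows <- lapply(seq_len(nrow(design)), function(r) {
        cv <- design$cultivar[r]; tr <- design$treatment[r]
        p <- config$fvcb_presets[[cv]][[tr]]
        a_true <- fvcb_forward(p, grid)$a_min
        noise <- if (config$aci_noise_cv > 0)
          stats::rnorm(length(grid), 0, config$aci_noise_cv) else 0
        data.frame(cultivar = cv, treatment = tr, block = design$block[r],
                   ci = grid, a = a_true * (1 + noise))
      })
      out$aci <- do.call(rbind, rows)
    }

    if ("light" %in% components) {
      lev <- config$protocol$ppfd_levels
      sd_amp_abs <- config$plot_sd[["A"]]   # plot-level amplitude SD
      rows <- lapply(seq_len(nrow(design)), function(r) {
        cv <- design$cultivar[r]; tr <- design$treatment[r]
        p <- config$light_presets[[cv]][[tr]]
        amax_cell <- light_forward("ye", p, 1500)
        amp <- if (config$noise_scale > 0)
          1 + stats::rnorm(1, 0, sd_amp_abs / amax_cell) else 1
        a_true <- light_forward("ye", p, lev) * amp
        a_obs <- a_true + stats::rnorm(length(lev), 0,
                                       config$light_point_sd)
        data.frame(cultivar = cv, treatment = tr, block = design$block[r],
                   i = lev, a = a_obs)
      })
      out$light <- do.call(rbind, rows)
    }
    structure(out, class = "experiment_bundle")
  })
}
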