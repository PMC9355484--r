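# End-to-end orchestration: indices -> curve fits -> RCBD ANOVA -> LSD ->
# pooled SEM -> percent changes -> correlation matrix, emitting the
# means-with-letters report structure conventional for factorial crop
# physiology experiments.

#' Run the full analysis pipeline on an experiment bundle
#'
#' Takes a simulated (or ingested) experiment bundle and produces the
#' complete report: per-trait cell means with Fisher's protected LSD
#' letters, pooled SEMs, per-cultivar percent changes
#' (decline-positive), per-trait ANOVA tables, per-plot A/Ci (Vcmax, Jmax,
#' Rd) and light-response (model, Amax, Ic, Ik, Φi, Pmax) parameter tables,
#' and a Pearson correlation matrix across plot-level traits. Deterministic
#' given the bundle.
#'
#' @param bundle an `experiment_bundle` from [simulate_experiment()], or a
#'   list with any of `morphology`, `gas`, `aci`, `light` in the same
#'   layouts.
#' @param alpha significance level for ANOVA flags and LSD; default 0.05.
#' @param rd_default day respiration used for the Rubisco velocity
#'   partitioning when no A/Ci-fitted Rd is available for the plot.
#' @param fvcb_template [fvcb_params()] supplying kinetic constants for
#'   A/Ci fitting.
#' @return list of class `analysis_report`: `summary` (per trait x cell:
#'   mean, SEM, letters), `percent_change` (per trait x cultivar), `anova`
#'   (named list of `anova_rcbd`), `aci_fits`, `light_fits`, `correlation`,
#'   `traits`, `meta`.
#' @export
run_full_analysis <- function(bundle, alpha = 0.05, rd_default = 1.5,
                              fvcb_template = fvcb_params()) {
  traits_long <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(bundle$morphology))
    traits_long$morphology <- bundle$morphology

  if (!is.null(bundle$gas)) {
    g <- bundle$gas
    idx <- stage("indices", stomatal_indices(
      a = g$A, gs = g$gs, ci = g$Ci, ca = g$Ca))
    fl <- stage("fluorescence", {
      t(vapply(seq_len(nrow(g)), function(r) {
        li <- light_adapted_indices(list(
          fo = g$Fo[r], fm = g$Fm[r], fs = g$Fs[r], fm_prime = g$Fmp[r],
          fo_prime = if ("Fop" %in% names(g)) g$Fop[r] else NULL,
          q = g$Q[r]))
        c(FvFm = li$fv_fm, PhiPSII = li$phi_psii, PhiNPQ = li$phi_npq,
          PhiNO = li$phi_no, qP = li$qp, one_minus_qL = li$one_minus_ql,
          NPQ = li$npq, ETR = li$etr, FvpFmp = li$fvp_fmp)
      }, numeric(9)))
    })
    vel <- stage("velocities",
                 rubisco_velocities(a = g$A, etr = fl[, "ETR"],
                                    rd = rd_default))
    wide <- data.frame(g[c("cultivar", "treatment", "block", "plant")],
                       A = g$A, gs = g$gs, E = g$E, Ci = g$Ci,
                       WUE = idx$wue, Ci_Ca = idx$ci_ca, Ls = idx$ls,
                       fl, Fo = g$Fo, Fm = g$Fm, Fs = g$Fs,
                       Vc = vel$vc, Vo = vel$vo)
    meas <- setdiff(names(wide), c("cultivar", "treatment", "block", "plant"))
    traits_long$gas <- stats::reshape(
      wide, direction = "long", varying = meas, v.names = "value",
      times = meas, timevar = "trait",
      idvar = c("cultivar", "treatment", "block", "plant"))
    rownames(traits_long$gas) <- NULL
  }

  aci_fits <- NULL
  if (!is.null(bundle$aci)) {
    aci_fits <- stage("fit-aci", {
      keys <- unique(bundle$aci[c("cultivar", "treatment", "block")])
      do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
        sel <- bundle$aci$cultivar == keys$cultivar[r] &
          bundle$aci$treatment == keys$treatment[r] &
          bundle$aci$block == keys$block[r]
        ft <- fit_aci(bundle$aci$ci[sel], bundle$aci$a[sel],
                      params = fvcb_template)
        data.frame(keys[r, ], Vcmax = ft$params$vcmax,
                   Jmax = ft$params$j, Rd = ft$params$rd, sse = ft$sse,
                   admissible = ft$admissible, row.names = NULL)
      }))
    })
    al <- aci_fits
    al$plant <- 1L
    traits_long$aci <- stats::reshape(
      al[c("cultivar", "treatment", "block", "plant", "Vcmax", "Jmax")],
      direction = "long", varying = c("Vcmax", "Jmax"), v.names = "value",
      times = c("Vcmax", "Jmax"), timevar = "trait",
      idvar = c("cultivar", "treatment", "block", "plant"))
    rownames(traits_long$aci) <- NULL
  }

  light_fits <- NULL
  if (!is.null(bundle$light)) {
    light_fits <- stage("fit-light", {
      keys <- unique(bundle$light[c("cultivar", "treatment", "block")])
      do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
        sel <- bundle$light$cultivar == keys$cultivar[r] &
          bundle$light$treatment == keys$treatment[r] &
          bundle$light$block == keys$block[r]
        ft <- select_light_model(bundle$light$i[sel], bundle$light$a[sel])
        data.frame(keys[r, ], model = ft$model, Amax = ft$amax_1500,
                   Ic = ft$ic, Ik = ft$ik, phi_i = ft$phi_i,
                   Pmax = ft$pmax, sse = ft$sse, row.names = NULL)
      }))
    })
    ll <- light_fits
    ll$plant <- 1L
    ll$trait <- "Amax"
    ll$value <- ll$Amax
    traits_long$light <- ll[c("cultivar", "treatment", "block", "plant",
                              "trait", "value")]
  }

  cols <- c("cultivar", "treatment", "block", "plant", "trait", "value")
  traits_long <- lapply(traits_long, function(d) d[cols])
  long <- do.call(rbind, traits_long)
  rownames(long) <- NULL
  traits <- unique(long$trait)

  anovas <- list(); summaries <- list(); pchanges <- list()
  for (tt in traits) {
    an <- stage(paste0("anova:", tt),
                anova_factorial_rcbd(long, tt, alpha = alpha))
    lsd <- stage(paste0("lsd:", tt), fisher_protected_lsd(an, alpha = alpha))
    sem <- pooled_sem(an, attr(an, "n_blocks"))
    cm <- attr(an, "cell_means")
    g <- lsd$groups
    g <- g[match(paste(cm$cultivar, cm$treatment, sep = ":"), g$group), ]
    summaries[[tt]] <- data.frame(trait = tt, cm[c("cultivar", "treatment")],
                                  mean = cm$value, sem = sem,
                                  letters = g$letters, row.names = NULL)
    pc <- do.call(rbind, lapply(unique(cm$cultivar), function(cv) {
      ctl <- cm$value[cm$cultivar == cv & cm$treatment == "control"]
      wlg <- cm$value[cm$cultivar == cv & cm$treatment != "control"]
      data.frame(trait = tt, cultivar = cv,
                 percent_change = percent_change(ctl, wlg))
    }))
    pchanges[[tt]] <- pc
    anovas[[tt]] <- an
  }

  correlation <- tryCatch(pearson_matrix(long), error = function(e) NULL)

  structure(list(summary = do.call(rbind, c(summaries,
                                            make.row.names = FALSE)),
                 percent_change = do.call(rbind, c(pchanges,
                                                   make.row.names = FALSE)),
                 anova = anovas, aci_fits = aci_fits,
                 light_fits = light_fits, correlation = correlation,
                 traits = traits,
                 meta = list(alpha = alpha,
                             seed = bundle$seed %||% NA,
                             package_version =
                               as.character(utils::packageVersion("leafphys")))),
            class = "analysis_report")
}

#' Write an analysis report as a CSV set
#'
#' Serializes the report tables with [write_report_table()]: summary,
#' percent changes, one ANOVA CSV per trait, curve-fit tables and the
#' correlation matrix. Output is byte-stable across identical runs.
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  tabs <- list(summary = report$summary,
               percent_change = report$percent_change)
  for (tt in names(report$anova))
    tabs[[paste0("anova_", gsub("[^A-Za-z0-9]", "_", tt))]] <-
      as.data.frame(report$anova[[tt]])
  if (!is.null(report$aci_fits)) tabs$aci_fits <- report$aci_fits
  if (!is.null(report$light_fits)) tabs$light_fits <- report$light_fits
  if (!is.null(report$correlation)) {
    r <- as.data.frame(report$correlation$r)
    r <- cbind(trait = report$correlation$traits, r)
    tabs$correlation <- r
  }
  write_report_table(tabs, dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", length(x$traits), "traits\n")
  cat("Percent changes (decline-positive):\n")
  print(x$percent_change, digits = 3)
  invisible(x)
}
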