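# Farquhar-von Caemmerer-Berry biochemical photosynthesis model:
# forward rates, Ci -> Cc correction, temperature normalisation, and A/Ci
# curve fitting with limitation-state assignment.

#' FvCB parameter set
#'
#' Constructor with the Bernacchi 25 °C kinetic constants as defaults
#' (Kc = 404.9 µmol mol⁻¹, Ko = 278.4 mmol mol⁻¹, Γ* = 42.75 µmol mol⁻¹,
#' O = 210 mmol mol⁻¹) — the constants embedded in the widely used
#' spreadsheet A/Ci fitting tools.
#'
#' @param vcmax maximum Rubisco carboxylation rate, µmol m⁻² s⁻¹.
#' @param j electron transport rate at measurement light (conventionally
#'   reported as Jmax by curve-fitting tools), µmol m⁻² s⁻¹.
#' @param tpu triose-phosphate utilization rate, µmol m⁻² s⁻¹; `Inf`
#'   disables the TPU limitation.
#' @param rd day respiration, µmol m⁻² s⁻¹.
#' @param gm mesophyll conductance, mol m⁻² s⁻¹ bar⁻¹; `Inf` fits on a Ci
#'   basis (Cc = Ci).
#' @param gamma_star CO2 compensation point in the absence of Rd,
#'   µmol mol⁻¹.
#' @param kc,ko Michaelis constants of Rubisco for CO2 (µmol mol⁻¹) and O2
#'   (mmol mol⁻¹).
#' @param o oxygen mole fraction, mmol mol⁻¹.
#' @return list of class `fvcb_params`.
#' @export
fvcb_params <- function(vcmax = 100, j = 150, tpu = Inf, rd = 1.5,
                        gm = Inf, gamma_star = 42.75, kc = 404.9,
                        ko = 278.4, o = 210) {
  stopifnot(vcmax > 0, j > 0, tpu > 0, rd >= 0, gm > 0,
            gamma_star > 0, kc > 0, ko > 0, o > 0, gamma_star < kc,
            vcmax > rd)
  structure(list(vcmax = vcmax, j = j, tpu = tpu, rd = rd, gm = gm,
                 gamma_star = gamma_star, kc = kc, ko = ko, o = o),
            class = "fvcb_params")
}

#' Forward FvCB rates
#'
#' Computes the three potential limitation rates at chloroplastic CO2 `cc`:
#' \deqn{A_c = V_{cmax}(C_c - \Gamma^*)/(C_c + K_c(1 + O/K_o)) - R_d}
#' \deqn{A_j = J(C_c - \Gamma^*)/(4C_c + 8\Gamma^*) - R_d}
#' \deqn{A_p = 3\,TPU - R_d}
#' and the realised rate `a_min = min(ac, aj, ap)`. At cc = Γ* both
#' carboxylation-limited rates equal −Rd.
#'
#' @param params an [fvcb_params()] object.
#' @param cc chloroplastic CO2 mole fraction, µmol mol⁻¹ (vectorised, ≥ 0).
#' @return data.frame with columns `ac`, `aj`, `ap`, `a_min`, `limitation`
#'   (factor in Rubisco/RuBP/TPU).
#' @export
#' @examples
#' p <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
#' fvcb_forward(p, cc = c(50, 300, 1200))
fvcb_forward <- function(params, cc) {
  if (any(cc < 0)) stop("cc must be non-negative")
  p <- params
  ac <- p$vcmax * (cc - p$gamma_star) /
    (cc + p$kc * (1 + p$o / p$ko)) - p$rd
  aj <- p$j * (cc - p$gamma_star) / (4 * cc + 8 * p$gamma_star) - p$rd
  ap <- rep(if (is.finite(p$tpu)) 3 * p$tpu - p$rd else Inf, length(cc))
  a_min <- pmin(ac, aj, ap)
  lim <- c("Rubisco", "RuBP", "TPU")[apply(cbind(ac, aj, ap), 1,
                                           which.min)]
  data.frame(ac = ac, aj = aj, ap = ap, a_min = a_min,
             limitation = factor(lim, levels = c("Rubisco", "RuBP", "TPU")))
}

#' Chloroplastic CO2 from intercellular CO2
#'
#' Cc = Ci − A/gm. With infinite mesophyll conductance Cc = Ci (Ci-basis
#' analysis). A negative corrected Cc is returned as `NA` with a warning so
#' the point can be excluded from fitting.
#'
#' @param ci intercellular CO2, µmol mol⁻¹.
#' @param a net assimilation, µmol m⁻² s⁻¹.
#' @param gm mesophyll conductance, mol m⁻² s⁻¹ bar⁻¹; may be `Inf`.
#' @return cc, µmol mol⁻¹ (NA where the correction goes negative).
#' @export
cc_from_ci <- function(ci, a, gm = Inf) {
  if (any(gm <= 0)) stop("gm must be positive (possibly infinite)")
  if (all(is.infinite(gm))) return(ci)
  cc <- ci - a / gm
  if (any(cc < 0)) {
    warning("Cc < 0 after mesophyll correction; point(s) flagged NA")
    cc[cc < 0] <- NA_real_
  }
  cc
}

# Arrhenius temperature factor relative to 25 degC; ea in J mol^-1.
.arrhenius <- function(ea, tleaf) {
  tk <- tleaf + 273.15
  exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Default activation energies for temperature normalisation
#'
#' Bernacchi-type activation energies (J mol⁻¹) for the temperature scaling
#' of the FvCB parameters and kinetic constants.
#' @return named numeric vector.
#' @export
fvcb_activation_energies <- function() {
  c(vcmax = 65330, j = 43540, tpu = 53100, rd = 46390,
    kc = 79430, ko = 36380, gamma_star = 37830)
}

#' Normalise FvCB parameters measured at tleaf to 25 °C
#'
#' Arrhenius scaling p25 = p(T)/f(T) with f(T) = exp(Ea(T−298.15)/(298.15·R·T)).
#' The identity at 25 °C and exact invertibility follow from the functional
#' form.
#'
#' @param params an [fvcb_params()] object measured at `tleaf`.
#' @param tleaf leaf temperature, °C, in (0, 50).
#' @param ea named activation energies, J mol⁻¹ (see
#'   [fvcb_activation_energies()]).
#' @param inverse logical; if TRUE, scales 25 °C parameters *to* `tleaf`.
#' @return an `fvcb_params` object at 25 °C (or at `tleaf` when
#'   `inverse = TRUE`).
#' @export
temperature_adjust <- function(params, tleaf,
                               ea = fvcb_activation_energies(),
                               inverse = FALSE) {
  if (tleaf <= 0 || tleaf >= 50) stop("tleaf must lie in (0, 50) degC")
  out <- params
  for (nm in names(ea)) {
    f <- .arrhenius(ea[[nm]], tleaf)
    if (!is.null(out[[nm]]) && is.finite(out[[nm]]))
      out[[nm]] <- if (inverse) out[[nm]] * f else out[[nm]] / f
  }
  out
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Re-implementation of the spreadsheet-tool limitation-assignment fit: the
#' Ci-sorted points are partitioned into contiguous Rubisco → RuBP → TPU
#' segments (labels monotone non-decreasing in Ci); every admissible
#' partition is enumerated, and for each one the model is *exactly linear*
#' in (Vcmax, J, 3·TPU, Rd), so the segment fit is solved in closed form by
#' linear least squares. The partition with minimal SSE among admissible
#' fits is returned (admissible = the assigned rate agrees with the min
#' rule at the fitted parameters at every point, within `admissible_tol`).
#' Ties in SSE (within `tie_tol` relative) are broken towards more
#' Rubisco-limited points, yielding a conservative Vcmax.
#'
#' @param ci intercellular CO2 per point, µmol mol⁻¹.
#' @param a net assimilation per point, µmol m⁻² s⁻¹.
#' @param params template [fvcb_params()] providing the kinetic constants
#'   (gamma_star, kc, ko, o) and gm.
#' @param rd_fixed optional fixed Rd; when NULL (default) Rd is fitted and
#'   clamped to be non-negative.
#' @param admissible_tol absolute tolerance (µmol m⁻² s⁻¹) for the min-rule
#'   agreement check; default 0.5, commensurate with typical IRGA
#'   measurement noise near the limitation crossover.
#' @param tie_tol relative SSE tolerance for the tie-break rule.
#' @return list of class `aci_fit`: `params` (fitted `fvcb_params`),
#'   `labels`, `fitted`, `residuals`, `sse`, `admissible`,
#'   `j_identifiable`, `tpu_identifiable`, `n`.
#' @export
#' @examples
#' p <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
#' ci <- c(50, 100, 200, 300, 400, 600, 800, 1000, 1200, 1500)
#' a <- fvcb_forward(p, ci)$a_min
#' fit <- fit_aci(ci, a, params = p)
#' fit$params$vcmax
fit_aci <- function(ci, a, params = fvcb_params(), rd_fixed = NULL,
                    admissible_tol = 0.5, tie_tol = 1e-6) {
  if (length(ci) != length(a)) stop("ci and a must have equal length")
  keep <- is.finite(ci) & is.finite(a)
  ci <- ci[keep]; a <- a[keep]
  if (length(ci) < 5) stop("fit_aci needs at least 5 points")
  if (min(ci) >= 200 || max(ci) <= 800)
    warning("curve should span at least one point below Ci=200 and one ",
            "above Ci=800 for reliable identification")
  ord <- order(ci)
  ci <- ci[ord]; a <- a[ord]
  cc <- cc_from_ci(ci, a, params$gm)
  ok <- !is.na(cc)
  ci <- ci[ok]; a <- a[ok]; cc <- cc[ok]
  n <- length(cc)
  if (n < 5) stop("fewer than 5 usable points after Cc correction")

  gs <- params$gamma_star
  x_vc <- (cc - gs) / (cc + params$kc * (1 + params$o / params$ko))
  x_j <- (cc - gs) / (4 * cc + 8 * gs)

  fit_one <- function(k1, k2) {
    # points 1..k1 Rubisco, (k1+1)..k2 RuBP, (k2+1)..n TPU
    seg <- rep(3L, n)
    if (k1 >= 1) seg[1:k1] <- 1L
    if (k2 > k1) seg[(k1 + 1):k2] <- 2L
    X <- cbind(vc = ifelse(seg == 1L, x_vc, 0),
               j = ifelse(seg == 2L, x_j, 0),
               tpu3 = ifelse(seg == 3L, 1, 0))
    use <- colSums(X != 0) > 0
    y <- a
    if (is.null(rd_fixed)) {
      Xf <- cbind(X[, use, drop = FALSE], rd = -1)
      cf <- tryCatch(qr.coef(qr(Xf), y), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) return(NULL)
      rd <- cf[["rd"]]
      if (rd < 0) {  # refit with rd pinned at zero
        rd <- 0
        cf2 <- tryCatch(qr.coef(qr(X[, use, drop = FALSE]), y),
                        error = function(e) NULL)
        if (is.null(cf2) || anyNA(cf2)) return(NULL)
        cf <- c(cf2, rd = 0)
      }
    } else {
      rd <- rd_fixed
      cf <- tryCatch(qr.coef(qr(X[, use, drop = FALSE]), y + rd),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) return(NULL)
      cf <- c(cf, rd = rd)
    }
    vcmax <- if ("vc" %in% names(cf)) cf[["vc"]] else NA_real_
    jfit <- if ("j" %in% names(cf)) cf[["j"]] else NA_real_
    tpu <- if ("tpu3" %in% names(cf)) cf[["tpu3"]] / 3 else Inf
    if ((!is.na(vcmax) && vcmax <= 0) || (!is.na(jfit) && jfit <= 0) ||
        (is.finite(tpu) && tpu <= 0)) return(NULL)
    pred <- ifelse(seg == 1L, vcmax * x_vc,
                   ifelse(seg == 2L, jfit * x_j, 3 * tpu)) - rd
    sse <- sum((a - pred)^2)
    # min-rule agreement at the fitted parameters
    ac <- if (is.na(vcmax)) rep(Inf, n) else vcmax * x_vc - rd
    aj <- if (is.na(jfit)) rep(Inf, n) else jfit * x_j - rd
    ap <- if (is.finite(tpu)) rep(3 * tpu - rd, n) else rep(Inf, n)
    amin <- pmin(ac, aj, ap)
    admissible <- all(pred - amin <= admissible_tol)
    list(k1 = k1, k2 = k2, seg = seg, vcmax = vcmax, j = jfit, tpu = tpu,
         rd = rd, pred = pred, sse = sse, admissible = admissible)
  }

  fits <- list()
  for (k1 in 0:n) for (k2 in k1:n) {
    f <- fit_one(k1, k2)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) stop("no feasible limitation assignment found")

  adm <- Filter(function(f) f$admissible, fits)
  pool <- if (length(adm)) adm else fits
  sses <- vapply(pool, `[[`, numeric(1), "sse")
  best_sse <- min(sses)
  tied <- pool[sses <= best_sse * (1 + tie_tol) + 1e-15]
  # prefer more Rubisco-limited points (conservative Vcmax), then fewer
  # TPU-limited points (a one-point TPU segment always fits exactly)
  nrub <- vapply(tied, `[[`, numeric(1), "k1")
  k2s <- vapply(tied, `[[`, numeric(1), "k2")
  best <- tied[[order(-nrub, -k2s)[1]]]
  if (!length(adm))
    warning("no admissible limitation assignment within tolerance; ",
            "returning best fit with admissible = FALSE")

  labels <- factor(c("Rubisco", "RuBP", "TPU")[best$seg],
                   levels = c("Rubisco", "RuBP", "TPU"))
  out_params <- params
  out_params$vcmax <- best$vcmax
  out_params$j <- best$j
  out_params$tpu <- best$tpu
  out_params$rd <- best$rd
  structure(list(params = out_params, labels = labels,
                 ci = ci, a = a, fitted = best$pred,
                 residuals = a - best$pred, sse = best$sse,
                 admissible = best$admissible && length(adm) > 0,
                 j_identifiable = !is.na(best$j),
                 tpu_identifiable = is.finite(best$tpu),
                 n = n),
            class = "aci_fit")
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("FvCB A/Ci fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  Vcmax = %.3f  J = %s  TPU = %s  Rd = %.3f  SSE = %.4g\n",
              x$params$vcmax,
              if (x$j_identifiable) sprintf("%.3f", x$params$j) else "n/i",
              if (x$tpu_identifiable) sprintf("%.3f", x$params$tpu) else "Inf",
              x$params$rd, x$sse))
  cat("  labels:", paste(table(x$labels), collapse = "/"),
      "(Rubisco/RuBP/TPU), admissible:", x$admissible, "\n")
  invisible(x)
}
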