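# Photosynthetic light-response curve fitting.
#
# Four candidate model families:
#   rh  : rectangular hyperbola            A = phi*I*Pm/(phi*I + Pm) - Rd
#   nrh : non-rectangular hyperbola        theta*A'^2 - (phi*I+Pm)*A' + phi*I*Pm = 0
#         (lower root), A = A' - Rd
#   exp : exponential saturation           A = Pm*(1 - exp(-phi*I/Pm)) - Rd
#   ye  : modified rectangular hyperbola   A = phi*(1-beta*I)/(1+gamma*I)*(I-Ic)
# The ye family is the only candidate with a photoinhibition (supra-optimal
# decline) term; by construction it passes through zero at I = Ic.

.light_models <- function() {
  list(
    rh = list(
      pars = c("phi", "pmax", "rd"), npar = 3,
      fn = function(i, p) p[["phi"]] * i * p[["pmax"]] /
        (p[["phi"]] * i + p[["pmax"]]) - p[["rd"]],
      deriv = function(i, p) p[["phi"]] * p[["pmax"]]^2 /
        (p[["phi"]] * i + p[["pmax"]])^2,
      lower = c(phi = 1e-4, pmax = 0.5, rd = 0),
      upper = c(phi = 0.5, pmax = 200, rd = 15)),
    nrh = list(
      pars = c("phi", "pmax", "theta", "rd"), npar = 4,
      fn = function(i, p) {
        b <- p[["phi"]] * i + p[["pmax"]]
        disc <- pmax(b^2 - 4 * p[["theta"]] * p[["phi"]] * i * p[["pmax"]], 0)
        (b - sqrt(disc)) / (2 * p[["theta"]]) - p[["rd"]]
      },
      deriv = function(i, p) {
        b <- p[["phi"]] * i + p[["pmax"]]
        disc <- pmax(b^2 - 4 * p[["theta"]] * p[["phi"]] * i * p[["pmax"]],
                     1e-12)
        (p[["phi"]] / (2 * p[["theta"]])) *
          (1 - (b - 2 * p[["theta"]] * p[["pmax"]]) / sqrt(disc))
      },
      lower = c(phi = 1e-4, pmax = 0.5, theta = 1e-3, rd = 0),
      upper = c(phi = 0.5, pmax = 200, theta = 0.999, rd = 15)),
    exp = list(
      pars = c("phi", "pmax", "rd"), npar = 3,
      fn = function(i, p) p[["pmax"]] *
        (1 - exp(-p[["phi"]] * i / p[["pmax"]])) - p[["rd"]],
      deriv = function(i, p) p[["phi"]] * exp(-p[["phi"]] * i / p[["pmax"]]),
      lower = c(phi = 1e-4, pmax = 0.5, rd = 0),
      upper = c(phi = 0.5, pmax = 200, rd = 15)),
    ye = list(
      pars = c("phi", "beta", "gamma", "ic"), npar = 4,
      fn = function(i, p) p[["phi"]] * (1 - p[["beta"]] * i) /
        (1 + p[["gamma"]] * i) * (i - p[["ic"]]),
      deriv = function(i, p) {
        u <- p[["phi"]] * (1 - p[["beta"]] * i) * (i - p[["ic"]])
        up <- p[["phi"]] * ((1 - p[["beta"]] * i) -
                            p[["beta"]] * (i - p[["ic"]]))
        v <- 1 + p[["gamma"]] * i
        (up * v - u * p[["gamma"]]) / v^2
      },
      lower = c(phi = 1e-4, beta = 0, gamma = 0, ic = 0),
      upper = c(phi = 0.5, beta = 5e-4, gamma = 0.05, ic = 200))
  )
}

#' Forward evaluation of a light-response model
#'
#' @param model one of `"rh"`, `"nrh"`, `"exp"`, `"ye"` (see the file-level
#'   notes in the source for the functional forms).
#' @param params named list/vector of coefficients for the model: `phi`,
#'   `pmax`, `rd` (rh, exp), plus `theta` in (0, 1] for nrh; `phi`, `beta`,
#'   `gamma`, `ic` for ye.
#' @param i incident PPFD, µmol m⁻² s⁻¹ (vectorised, ≥ 0).
#' @return net assimilation A, µmol m⁻² s⁻¹.
#' @export
#' @examples
#' light_forward("ye", list(phi = 0.07, beta = 5e-5, gamma = 2e-3, ic = 25),
#'               i = c(25, 1500))
light_forward <- function(model, params, i) {
  reg <- .light_models()
  if (!model %in% names(reg)) stop("unknown light-response model: ", model)
  if (any(i < 0)) stop("i must be non-negative")
  p <- as.list(params)
  missing <- setdiff(reg[[model]]$pars, names(p))
  if (length(missing))
    stop("missing coefficient(s) for model '", model, "': ",
         paste(missing, collapse = ", "))
  if (model == "nrh" && (p$theta <= 0 || p$theta > 1))
    stop("theta must lie in (0, 1]")
  reg[[model]]$fn(i, p)
}

# analytic dA/dI
.light_deriv <- function(model, params, i) {
  .light_models()[[model]]$deriv(i, as.list(params))
}

.cardinal_points <- function(model, p) {
  fn <- function(i) light_forward(model, p, i)
  # light compensation point: A(ic) = 0
  ic <- if (model == "ye") unname(p[["ic"]]) else {
    a0 <- fn(0)
    if (a0 >= 0) 0 else {
      hi <- 10
      while (fn(hi) < 0 && hi < 4000) hi <- hi * 2
      if (fn(hi) < 0) NA_real_ else
        stats::uniroot(fn, c(0, hi), tol = 1e-9)$root
    }
  }
  # light-saturated (maximum) net rate over the working range
  opt <- stats::optimize(fn, c(0, 5000), maximum = TRUE, tol = 1e-6)
  pmax_net <- opt$objective
  phi_ic <- if (is.na(ic)) NA_real_ else .light_deriv(model, p, ic)
  phi_0 <- .light_deriv(model, p, 0)
  ik <- if (!is.na(ic) && is.finite(phi_ic) && phi_ic > 0)
    pmax_net / phi_ic + ic else NA_real_
  rd_eq <- -fn(0)
  list(ic = ic, ik = ik, phi_i = phi_ic, phi_0 = phi_0,
       pmax = pmax_net, i_opt = opt$maximum, rd = max(rd_eq, 0),
       amax_1500 = fn(1500))
}

# deterministic start grid per model (no RNG inside fitters)
.light_starts <- function(model, i, a) {
  amax <- max(a)
  rd0 <- max(0, -min(a[i == min(i)]))
  pos <- i > 0
  phi0 <- if (any(pos)) max((a[pos][1] - a[i == min(i)][1]) /
                              i[pos][1], 0.01) else 0.05
  phi0 <- min(max(phi0, 0.005), 0.3)
  pm0 <- max(amax + rd0, 1)
  switch(model,
    rh = list(c(phi = phi0, pmax = pm0, rd = rd0 + 0.01),
              c(phi = phi0 * 2, pmax = pm0 * 1.5, rd = rd0 + 0.5)),
    exp = list(c(phi = phi0, pmax = pm0, rd = rd0 + 0.01),
               c(phi = phi0 * 2, pmax = pm0 * 1.2, rd = rd0 + 0.5)),
    nrh = list(c(phi = phi0, pmax = pm0, theta = 0.7, rd = rd0 + 0.01),
               c(phi = phi0, pmax = pm0, theta = 0.95, rd = rd0 + 0.5),
               c(phi = phi0 * 2, pmax = pm0 * 1.2, theta = 0.4,
                 rd = rd0 + 0.1)),
    ye = {
      ic0 <- max(if (phi0 > 0) rd0 / phi0 else 10, 1)
      list(c(phi = phi0, beta = 1e-5, gamma = 1e-3, ic = ic0),
           c(phi = phi0 * 1.5, beta = 5e-5, gamma = 3e-3, ic = ic0 * 2),
           c(phi = phi0, beta = 1e-6, gamma = 2e-4, ic = ic0))
    })
}

#' Fit one light-response model to a curve
#'
#' Nonlinear least squares (Levenberg–Marquardt via
#' \code{minpack.lm::nlsLM}) from a small deterministic grid of starting
#' values; the start with the lowest converged SSE wins. Cardinal points
#' are extracted from the fitted model: Ic (A = 0, closed form for the ye
#' family, bracketed root otherwise), apparent quantum yield Φi as the
#' analytic derivative dA/dI at Ic (the slope at I = 0 is also reported),
#' Pmax as the maximum net rate over 0–5000 µmol m⁻² s⁻¹, Ik as the
#' intersection of the initial-slope line with the Pmax plateau
#' (Ik = Pmax/Φi + Ic), and Amax as the fitted value at I = 1500.
#'
#' @param i PPFD per point, µmol m⁻² s⁻¹ (should include 0 and ≥ 1000).
#' @param a net assimilation per point, µmol m⁻² s⁻¹.
#' @param model one of `"rh"`, `"nrh"`, `"exp"`, `"ye"`.
#' @return list of class `light_fit`: `model`, `params`, `ic`, `ik`,
#'   `phi_i`, `phi_0`, `pmax`, `rd`, `amax_1500`, `sse`, `fitted`, `npar`,
#'   `physiological` (TRUE when Φi ≤ 0.125, the theoretical quantum-yield
#'   ceiling).
#' @export
fit_light_curve <- function(i, a, model = "ye") {
  reg <- .light_models()
  if (!model %in% names(reg)) stop("unknown light-response model: ", model)
  if (length(i) != length(a)) stop("i and a must have equal length")
  if (length(i) < 6) stop("need at least 6 points")
  if (min(i) > 0 || max(i) < 1000)
    warning("curve should include I = 0 and I >= 1000 for identification")
  if (all(abs(a) < 1e-12)) stop("degenerate curve: all A values are zero")
  ord <- order(i)
  i <- i[ord]; a <- a[ord]

  fam <- reg[[model]]
  dat <- data.frame(i = i, a = a)
  best <- NULL
  for (st in .light_starts(model, i, a)) {
    fit <- tryCatch({
      form <- switch(model,
        rh = a ~ phi * i * pmax / (phi * i + pmax) - rd,
        exp = a ~ pmax * (1 - exp(-phi * i / pmax)) - rd,
        nrh = a ~ (phi * i + pmax -
                     sqrt((phi * i + pmax)^2 -
                            4 * theta * phi * i * pmax)) / (2 * theta) - rd,
        ye = a ~ phi * (1 - beta * i) / (1 + gamma * i) * (i - ic))
      minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                        lower = fam$lower, upper = fam$upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("light-response fit failed to converge for model '", model, "'")
  cf <- stats::coef(best$fit)
  card <- .cardinal_points(model, cf)
  structure(c(list(model = model, params = as.list(cf)),
              card[c("ic", "ik", "phi_i", "phi_0", "pmax", "i_opt", "rd",
                     "amax_1500")],
              list(sse = best$sse,
                   fitted = light_forward(model, cf, i),
                   i = i, a = a, npar = fam$npar,
                   physiological = is.finite(card$phi_i) &&
                     card$phi_i <= 0.125)),
            class = "light_fit")
}

#' Fit all candidate light-response models and select by SSE
#'
#' Fits every candidate family to the same curve and returns the fit with
#' the lowest residual sum of squares; ties (SSE within 1e−6 relative) go
#' to the model with fewer parameters.
#'
#' @inheritParams fit_light_curve
#' @param models candidate set; default all four.
#' @return the winning `light_fit`; attribute `"candidates"` carries the
#'   per-model SSE table.
#' @export
select_light_model <- function(i, a, models = c("rh", "nrh", "exp", "ye")) {
  fits <- list(); errs <- character()
  for (m in models) {
    f <- tryCatch(fit_light_curve(i, a, model = m),
                  error = function(e) e)
    if (inherits(f, "error")) errs <- c(errs, paste0(m, ": ", conditionMessage(f)))
    else fits[[m]] <- f
  }
  if (!length(fits))
    stop("all candidate light-response fits failed: ",
         paste(errs, collapse = " | "))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  npars <- vapply(fits, `[[`, numeric(1), "npar")
  best_sse <- min(sses)
  tied <- sses <= best_sse * (1 + 1e-6) + 1e-12
  pick <- names(fits)[tied][which.min(npars[tied])]
  out <- fits[[pick]]
  attr(out, "candidates") <- data.frame(model = names(fits), sse = sses,
                                        npar = npars, row.names = NULL)
  out
}

#' @export
print.light_fit <- function(x, ...) {
  cat("Light-response fit, model '", x$model, "'\n", sep = "")
  cat(sprintf("  Ic = %.2f  Ik = %.1f  phi_i = %.4f  Pmax = %.2f  Amax(1500) = %.2f  SSE = %.4g\n",
              x$ic, x$ik, x$phi_i, x$pmax, x$amax_1500, x$sse))
  invisible(x)
}
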