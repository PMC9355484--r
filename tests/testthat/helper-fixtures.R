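# Shared fixtures and independent oracles for the test suite.

# random admissible raw fluorescence records (vectorised)
random_fluor_records <- function(n, seed = 101) {
  withr::with_seed(seed, {
    fm <- runif(n, 1000, 4000)
    fo <- fm * runif(n, 0.18, 0.3)          # Fv/Fm in 0.70-0.82
    fmp <- fo + (fm - fo) * runif(n, 0.2, 0.95)
    fs <- fo + (fmp - fo) * runif(n, 0.05, 0.95)
    fop <- fo * runif(n, 0.7, 1.0)
    fop <- pmin(fop, fs * 0.999)
    data.frame(fo = fo, fm = fm, fs = fs, fm_prime = fmp, fo_prime = fop)
  })
}

# noiseless A/Ci curve from known parameters
make_aci_curve <- function(params = fvcb_params(vcmax = 100, j = 150,
                                                rd = 1.5),
                           ci = c(50, 100, 200, 300, 400, 600, 800,
                                  1000, 1200, 1500)) {
  list(ci = ci, a = fvcb_forward(params, ci)$a_min, params = params)
}

# brute-force balanced RCBD sum-of-squares decomposition (projection form),
# independent of stats::aov
rcbd_ss_oracle <- function(d) {
  g <- mean(d$value)
  n <- nrow(d)
  ss_tot <- sum((d$value - g)^2)
  mean_by <- function(f) tapply(d$value, d[[f]], mean)
  cnt_by <- function(f) tapply(d$value, d[[f]], length)
  ss_main <- function(f) sum(cnt_by(f) * (mean_by(f) - g)^2)
  cell <- tapply(d$value, list(d$cultivar, d$treatment), mean)
  ncell <- tapply(d$value, list(d$cultivar, d$treatment), length)
  mc <- mean_by("cultivar"); mt <- mean_by("treatment")
  dev <- cell - outer(mc, rep(1, length(mt))) -
    outer(rep(1, length(mc)), mt) + g
  ss_int <- sum(ncell * dev^2)
  ss_c <- ss_main("cultivar"); ss_t <- ss_main("treatment")
  ss_b <- ss_main("block")
  list(cultivar = ss_c, treatment = ss_t, interaction = ss_int,
       block = ss_b, error = ss_tot - ss_c - ss_t - ss_int - ss_b,
       total = ss_tot)
}

# random balanced RCBD trait table (plot-level)
random_rcbd_table <- function(blocks = 4, seed = 1, sd = 1,
                              eff_c = 0, eff_t = 0, eff_i = 0) {
  withr::with_seed(seed, {
    d <- expand.grid(cultivar = c("cv1", "cv2"),
                     treatment = c("control", "waterlogged"),
                     block = seq_len(blocks), stringsAsFactors = FALSE)
    d$plant <- 1L
    d$trait <- "y"
    d$value <- 10 +
      eff_c * (d$cultivar == "cv2") +
      eff_t * (d$treatment == "waterlogged") +
      eff_i * (d$cultivar == "cv2") * (d$treatment == "waterlogged") +
      rnorm(nrow(d), 0, sd)
    d
  })
}

# independent exhaustive-enumeration oracle for the A/Ci limitation
# assignment, built on lm() rather than the package's QR path
fit_aci_oracle <- function(ci, a, params = fvcb_params(), tol = 0.5) {
  ord <- order(ci); ci <- ci[ord]; a <- a[ord]
  n <- length(ci)
  gs <- params$gamma_star
  x_vc <- (ci - gs) / (ci + params$kc * (1 + params$o / params$ko))
  x_j <- (ci - gs) / (4 * ci + 8 * gs)
  best <- NULL
  for (k1 in 0:n) for (k2 in k1:n) {
    seg <- rep(3L, n)
    if (k1 >= 1) seg[1:k1] <- 1L
    if (k2 > k1) seg[(k1 + 1):k2] <- 2L
    df <- data.frame(y = a,
                     xv = ifelse(seg == 1, x_vc, 0),
                     xj = ifelse(seg == 2, x_j, 0),
                     xp = as.numeric(seg == 3))
    terms <- c(if (k1 >= 1) "xv", if (k2 > k1) "xj", if (k2 < n) "xp")
    fml <- stats::as.formula(paste("y ~", paste(terms, collapse = "+")))
    fit <- stats::lm(fml, data = df)
    cf <- stats::coef(fit)
    rd <- -unname(cf["(Intercept)"])
    if (is.na(rd)) next
    if (rd < 0) {
      fit <- stats::lm(stats::as.formula(
        paste("y ~ 0 +", paste(terms, collapse = "+"))), data = df)
      cf <- c(`(Intercept)` = 0, stats::coef(fit))
      rd <- 0
    }
    vcmax <- if ("xv" %in% names(cf)) unname(cf["xv"]) else NA
    j <- if ("xj" %in% names(cf)) unname(cf["xj"]) else NA
    tpu <- if ("xp" %in% names(cf)) unname(cf["xp"]) / 3 else Inf
    if ((!is.na(vcmax) && vcmax <= 0) || (!is.na(j) && j <= 0) ||
        (is.finite(tpu) && tpu <= 0)) next
    pred <- ifelse(seg == 1, vcmax * x_vc,
                   ifelse(seg == 2, j * x_j, 3 * tpu)) - rd
    sse <- sum((a - pred)^2)
    ac <- if (is.na(vcmax)) Inf else vcmax * x_vc - rd
    aj <- if (is.na(j)) Inf else j * x_j - rd
    ap <- if (is.finite(tpu)) 3 * tpu - rd else Inf
    adm <- all(pred - pmin(ac, aj, ap) <= tol)
    if (!adm) next
    cand <- list(k1 = k1, k2 = k2, sse = sse, vcmax = vcmax, j = j)
    if (is.null(best) || sse < best$sse * (1 - 1e-9) ||
        (sse <= best$sse * (1 + 1e-6) &&
           (k1 > best$k1 || (k1 == best$k1 && k2 > best$k2))))
      best <- cand
  }
  best
}
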