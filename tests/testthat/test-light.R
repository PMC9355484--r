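ye_pars <- list(phi = 0.07, beta = 5e-5, gamma = 2e-3, ic = 25)
ppfd <- c(0, 10, 50, 75, 100, 200, 400, 600, 800, 1000, 1200, 1500)

test_that("forward models honour their construction", {
  expect_equal(light_forward("ye", ye_pars, ye_pars$ic), 0)
  # rectangular hyperbola asymptote
  rh <- list(phi = 0.06, pmax = 25, rd = 1.2)
  expect_equal(light_forward("rh", rh, 1e9), 25 - 1.2, tolerance = 1e-4)
  expect_error(light_forward("blackman", rh, 100), "unknown")
  expect_error(light_forward("nrh", list(phi = 0.06, pmax = 25,
                                         theta = 1.5, rd = 1), 100),
               "theta")
  expect_error(light_forward("ye", ye_pars, -10), "non-negative")
})

test_that("non-rectangular hyperbola degenerates to its two limits", {
  p_rh <- list(phi = 0.06, pmax = 25, rd = 0)
  i <- seq(0, 1500, by = 100)
  # theta -> 0: rectangular hyperbola
  nrh0 <- light_forward("nrh", c(p_rh, theta = 1e-7), i)
  rh <- light_forward("rh", p_rh, i)
  expect_equal(nrh0, rh, tolerance = 1e-4)
  # theta -> 1: Blackman two-line limit min(phi I, pmax)
  nrh1 <- light_forward("nrh", c(p_rh, theta = 1 - 1e-9), i)
  expect_equal(nrh1, pmin(0.06 * i, 25), tolerance = 1e-3)
})

test_that("noiseless ye-generated curves are recovered to 0.1 percent", {
  a <- light_forward("ye", ye_pars, ppfd)
  ft <- fit_light_curve(ppfd, a, model = "ye")
  for (nm in names(ye_pars))
    expect_lt(abs(ft$params[[nm]] / ye_pars[[nm]] - 1), 1e-3)
  expect_lt(abs(light_forward("ye", ft$params, ft$ic)), 1e-6)
})

test_that("the compensation point satisfies A(Ic) = 0 for every family", {
  withr::with_seed(23, {
    for (k in 1:5) {
      a <- light_forward("ye", ye_pars, ppfd) + rnorm(length(ppfd), 0, 0.3)
      for (m in c("rh", "nrh", "exp", "ye")) {
        ft <- suppressWarnings(fit_light_curve(ppfd, a, model = m))
        expect_lt(abs(light_forward(m, ft$params, ft$ic)), 1e-6)
        expect_gt(ft$pmax, 0)
      }
    }
  })
})

test_that("degenerate all-zero curves are rejected", {
  expect_error(fit_light_curve(ppfd, rep(0, length(ppfd))), "degenerate")
})

test_that("model selection returns the generating family", {
  # NRH-generated data -> NRH wins (no other family nests theta = 0.9)
  nrh_p <- list(phi = 0.06, pmax = 24, theta = 0.9, rd = 1.1)
  a_nrh <- light_forward("nrh", nrh_p, ppfd)
  sel <- select_light_model(ppfd, a_nrh)
  expect_equal(sel$model, "nrh")
  # photoinhibited ye data -> ye is the only candidate that can decline
  ye_ph <- list(phi = 0.08, beta = 4e-4, gamma = 1e-3, ic = 20)
  a_ye <- light_forward("ye", ye_ph, c(ppfd, 2000))
  sel2 <- select_light_model(c(ppfd, 2000), a_ye)
  expect_equal(sel2$model, "ye")
  expect_lte(sel2$sse, min(attr(sel2, "candidates")$sse) + 1e-12)
})

test_that("SSE ties go to the model with fewer parameters", {
  # rh-generated data: nrh can match rh exactly (theta -> 0 nests it), so
  # the tie rule must pick the 3-parameter family
  rh_p <- list(phi = 0.055, pmax = 26, rd = 1)
  a_rh <- light_forward("rh", rh_p, ppfd)
  sel <- select_light_model(ppfd, a_rh, models = c("rh", "nrh"))
  expect_equal(sel$model, "rh")
})

test_that("reported quantum yield equals the model slope at Ic", {
  a <- light_forward("ye", ye_pars, ppfd)
  ft <- fit_light_curve(ppfd, a, model = "ye")
  h <- 1e-3
  num <- (light_forward("ye", ft$params, ft$ic + h) -
            light_forward("ye", ft$params, ft$ic - h)) / (2 * h)
  expect_lt(abs(ft$phi_i / num - 1), 1e-4)
  expect_true(ft$physiological)  # below the 0.125 theoretical ceiling
})

test_that("cardinal points are internally consistent", {
  a <- light_forward("ye", ye_pars, ppfd)
  ft <- fit_light_curve(ppfd, a, model = "ye")
  expect_equal(ft$ik, ft$pmax / ft$phi_i + ft$ic, tolerance = 1e-9)
  expect_equal(ft$amax_1500, light_forward("ye", ft$params, 1500),
               tolerance = 1e-9)
})
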