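test_that("forward rates match hand-evaluated FvCB equations", {
  p <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
  f <- fvcb_forward(p, 300)
  expect_equal(f$ac, 100 * (300 - 42.75) / (300 + 404.9 * (1 + 210 / 278.4))
               - 1.5, tolerance = 1e-12)
  expect_equal(f$aj, 150 * (300 - 42.75) / (4 * 300 + 8 * 42.75) - 1.5,
               tolerance = 1e-12)
  expect_equal(as.character(f$limitation), "RuBP")  # aj < ac at this Cc
  # compensation point: both carboxylation-limited rates equal -Rd
  fc <- fvcb_forward(p, p$gamma_star)
  expect_equal(fc$ac, -1.5, tolerance = 1e-12)
  expect_equal(fc$aj, -1.5, tolerance = 1e-12)
  # Rubisco-limited asymptote
  expect_equal(fvcb_forward(p, 1e9)$ac, p$vcmax - p$rd, tolerance = 1e-4)
  expect_error(fvcb_forward(p, -5), "non-negative")
})

test_that("mesophyll correction Cc = Ci - A/gm", {
  expect_equal(cc_from_ci(300, 20, Inf), 300)
  expect_equal(cc_from_ci(300, 20, 0.5), 260)
  expect_equal(cc_from_ci(300, 0, 0.5), 300)
  expect_warning(cc <- cc_from_ci(10, 20, 0.5), "flagged")
  expect_true(is.na(cc))
})

test_that("temperature normalisation is identity at 25 C, invertible and
           modest over one degree", {
  p <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
  expect_equal(temperature_adjust(p, 25)$vcmax, 100, tolerance = 1e-12)
  p25 <- temperature_adjust(p, 24)
  # closed-form Arrhenius factor over one degree (~9.3% for Ea = 65.33 kJ)
  f24 <- exp(65330 * (297.15 - 298.15) / (298.15 * 8.314 * 297.15))
  expect_equal(p25$vcmax, 100 / f24, tolerance = 1e-12)
  expect_lt(abs(p25$vcmax / 100 - 1), 0.10)
  back <- temperature_adjust(p25, 24, inverse = TRUE)
  expect_equal(back$vcmax, p$vcmax, tolerance = 1e-12)
  expect_equal(back$kc, p$kc, tolerance = 1e-12)
  # monotone: warmer leaf means larger 25C-normalised divisor
  v <- vapply(c(20, 22, 24, 26, 28),
              function(tl) temperature_adjust(p, tl)$vcmax, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(temperature_adjust(p, 55), "tleaf")
})

test_that("noiseless curves are recovered to 0.1 percent", {
  true <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
  cur <- make_aci_curve(true, ci = aci_grid(default_protocol()))
  ft <- fit_aci(cur$ci, cur$a, params = true)
  expect_lt(abs(ft$params$vcmax / true$vcmax - 1), 1e-3)
  expect_lt(abs(ft$params$j / true$j - 1), 1e-3)
  expect_lt(abs(ft$params$rd / true$rd - 1), 1e-3)
  expect_false(ft$tpu_identifiable)  # no TPU limitation in the truth
  expect_true(ft$admissible)
  # finite-TPU truth is also recovered
  true2 <- fvcb_params(vcmax = 100, j = 150, tpu = 9, rd = 1.5)
  cur2 <- make_aci_curve(true2)
  ft2 <- fit_aci(cur2$ci, cur2$a, params = true2)
  expect_lt(abs(ft2$params$tpu / 9 - 1), 1e-3)
})

test_that("labels are monotone and the fitted SSE never exceeds the truth's", {
  true <- fvcb_params(vcmax = 90, j = 120, rd = 1)
  cur <- make_aci_curve(true)
  ft <- fit_aci(cur$ci, cur$a, params = true)
  expect_true(all(diff(as.integer(ft$labels)) >= 0))
  expect_lte(ft$sse, sum((cur$a - fvcb_forward(true, cur$ci)$a_min)^2) + 1e-12)
})

test_that("a Rubisco-only curve flags J as unidentifiable", {
  true <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
  ci <- c(50, 75, 100, 125, 150)
  a <- fvcb_forward(true, ci)$ac
  expect_warning(ft <- fit_aci(ci, a, params = true), "span")
  expect_false(ft$j_identifiable)
  expect_lt(abs(ft$params$vcmax / 100 - 1), 1e-3)
})

test_that("too-few points raise an error", {
  expect_error(fit_aci(c(100, 300, 600, 1000), c(5, 15, 20, 22)),
               "at least 5")
})

test_that("mean Vcmax from noisy replicate curves lands within 5 percent", {
  true <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
  grid <- aci_grid(default_protocol())
  withr::with_seed(31, {
    v <- replicate(4, {
      a <- fvcb_forward(true, grid)$a_min * (1 + rnorm(length(grid), 0, 0.02))
      fit_aci(grid, a, params = true)$params$vcmax
    })
  })
  expect_lt(abs(mean(v) / 100 - 1), 0.05)
})

test_that("selected assignment matches the exhaustive lm-based oracle on
           short curves", {
  withr::with_seed(17, {
    for (k in 1:8) {
      true <- fvcb_params(vcmax = runif(1, 60, 120), j = runif(1, 100, 180),
                          rd = runif(1, 0.5, 2.5))
      ci <- sort(runif(8, 40, 1500))
      a <- fvcb_forward(true, ci)$a_min * (1 + rnorm(8, 0, 0.02))
      ft <- suppressWarnings(fit_aci(ci, a, params = true))
      orc <- fit_aci_oracle(ci, a, params = true)
      expect_equal(ft$sse, orc$sse, tolerance = 1e-8)
      expect_equal(sum(ft$labels == "Rubisco"), orc$k1)
    }
  })
})
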