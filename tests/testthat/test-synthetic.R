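test_that("the default scenario encodes the preset effects and validates", {
  cfg <- default_paper_config()
  expect_silent(validate_scenario_config(cfg))
  expect_equal(cfg$morphology_effects[["Straight 8"]][["FM"]], 0.25)
  expect_equal(cfg$morphology_effects[["Marketmore"]][["FM"]], 0.14)
  # control Marketmore light preset evaluates to the configured Amax
  expect_equal(light_forward("ye", cfg$light_presets[["Marketmore"]]$control,
                             1500), 23.62, tolerance = 1e-9)
  expect_equal(light_forward("ye", cfg$light_presets[["Straight 8"]]$control,
                             1500), 19.59, tolerance = 1e-9)
  # Straight 8 waterlogged Vcmax preset encodes the 33 percent decline
  expect_equal(cfg$fvcb_presets[["Straight 8"]]$waterlogged$vcmax,
               100 * 0.67, tolerance = 1e-12)
})

test_that("invalid configurations are rejected with aggregated messages", {
  cfg <- default_paper_config()
  cfg$morphology_effects[["Marketmore"]][["FM"]] <- 1.5
  expect_error(validate_scenario_config(cfg), "effect fractions")
  cfg2 <- default_paper_config()
  cfg2$fluorescence_targets[["Marketmore"]]$control[["phi_no"]] <- 0.9
  expect_error(validate_scenario_config(cfg2), "inconsistent")
})

test_that("zero noise reproduces configured cell means exactly", {
  cfg <- default_paper_config(noise_scale = 0)
  b <- simulate_experiment(cfg, seed = 1)
  fm <- b$morphology[b$morphology$trait == "FM", ]
  cm <- tapply(fm$value, list(fm$cultivar, fm$treatment), mean)
  expect_equal(unname(cm["Marketmore", "waterlogged"] /
                        cm["Marketmore", "control"]), 0.86,
               tolerance = 1e-12)
  # WUE through the stomatal-index path is exact as well
  s <- stomatal_indices(b$gas)
  expect_equal(unname(tapply(s$wue, list(b$gas$cultivar, b$gas$treatment),
                             mean)["Marketmore", "waterlogged"]),
               21 * (1 - 0.52), tolerance = 1e-9)
})

test_that("identical seeds give identical bundles; different seeds differ", {
  cfg <- default_paper_config()
  b1 <- simulate_experiment(cfg, seed = 42)
  b2 <- simulate_experiment(cfg, seed = 42)
  b3 <- simulate_experiment(cfg, seed = 43)
  expect_identical(b1$morphology, b2$morphology)
  expect_identical(b1$gas, b2$gas)
  expect_identical(b1$aci, b2$aci)
  expect_false(identical(b1$gas$A, b3$gas$A))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(1234)
  x1 <- rnorm(1)
  set.seed(1234)
  invisible(simulate_experiment(default_paper_config(), seed = 9,
                                components = "morphology"))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("inverse fluorescence construction realizes its targets", {
  r <- fluorescence_from_targets(0.75, 0.4, 0.6, 0.375, fm_scale = 2000)
  expect_equal(r$fm, 2000)
  expect_equal(r$fo, 500)
  expect_equal(r$fm_prime, 1250)
  expect_equal(r$fs, 750)
  li <- light_adapted_indices(r)
  expect_equal(li$phi_psii, 0.4, tolerance = 1e-9)
  expect_equal(li$npq, 0.6, tolerance = 1e-9)
  expect_equal(li$phi_no, 0.375, tolerance = 1e-9)
  expect_equal(li$fv_fm, 0.75, tolerance = 1e-9)
})

test_that("inconsistent yield targets are refused with the residual", {
  expect_error(fluorescence_from_targets(0.75, 0.5, 0.6, 0.375),
               "partition identity")
})

test_that("fluorescence indices are invariant to the Fm scale", {
  r1 <- fluorescence_from_targets(0.78, 0.3, 1.2, 0.7 / 2.2,
                                  fm_scale = 2000)
  r2 <- fluorescence_from_targets(0.78, 0.3, 1.2, 0.7 / 2.2,
                                  fm_scale = 4000)
  expect_equal(r2$fo, 2 * r1$fo)
  expect_equal(r2$fs, 2 * r1$fs)
  li1 <- light_adapted_indices(r1)
  li2 <- light_adapted_indices(r2)
  expect_equal(li1$phi_psii, li2$phi_psii, tolerance = 1e-12)
  expect_equal(li1$ql, li2$ql, tolerance = 1e-12)
})

test_that("simulated declines converge to the configured effects", {
  cfg <- default_paper_config()
  dec <- vapply(1:200, function(k) {
    b <- simulate_experiment(cfg, seed = 5000 + k,
                             components = "morphology")
    fm <- b$morphology[b$morphology$trait == "FM" &
                         b$morphology$cultivar == "Straight 8", ]
    cm <- tapply(fm$value, fm$treatment, mean)
    percent_change(cm[["control"]], cm[["waterlogged"]])
  }, numeric(1))
  mc_se <- sd(dec) / sqrt(length(dec))
  expect_lt(abs(mean(dec) - 25), 3 * mc_se + 0.05)
})
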