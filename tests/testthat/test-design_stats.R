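test_that("constant data give zero F for every effect", {
  d <- random_rcbd_table(sd = 0)
  an <- anova_factorial_rcbd(d, "y")
  eff <- an[an$source != "error", ]
  expect_true(all(eff$f == 0))
  expect_equal(sum(an$df), nrow(d) - 1)
})

test_that("purely additive effects produce zero interaction SS", {
  d <- random_rcbd_table(sd = 0, eff_c = 2, eff_t = -3)
  an <- anova_factorial_rcbd(d, "y")
  expect_lt(an$ss[an$source == "cultivar:treatment"], 1e-10)
  expect_gt(an$ss[an$source == "cultivar"], 0)
})

test_that("SS decomposition matches the brute-force projection oracle", {
  for (k in 1:20) {
    d <- random_rcbd_table(seed = 100 + k, sd = runif(1, 0.5, 3),
                           eff_c = rnorm(1), eff_t = rnorm(1),
                           eff_i = rnorm(1))
    an <- anova_factorial_rcbd(d, "y")
    orc <- rcbd_ss_oracle(d)
    get_ss <- function(src) an$ss[an$source == src]
    expect_equal(get_ss("cultivar"), orc$cultivar, tolerance = 1e-8)
    expect_equal(get_ss("treatment"), orc$treatment, tolerance = 1e-8)
    expect_equal(get_ss("cultivar:treatment"), orc$interaction,
                 tolerance = 1e-8)
    expect_equal(get_ss("block"), orc$block, tolerance = 1e-8)
    expect_equal(get_ss("error"), orc$error, tolerance = 1e-8)
    expect_equal(sum(an$ss), orc$total, tolerance = 1e-8)
  }
})

test_that("plant subsamples are averaged to plot means before ANOVA", {
  d <- random_rcbd_table(sd = 1, eff_t = 2)
  d6 <- do.call(rbind, lapply(1:6, function(p) {
    x <- d; x$plant <- p; x$value <- x$value + rnorm(nrow(x), 0, 0.5); x
  }))
  an <- anova_factorial_rcbd(d6, "y")
  expect_equal(attr(an, "df_error"), 9)  # 2x2x4 on plot means
})

test_that("incomplete designs are rejected", {
  d <- random_rcbd_table()
  expect_error(anova_factorial_rcbd(d[-1, ], "y"), "complete")
  expect_error(anova_factorial_rcbd(d, "nope"), "not found")
})

test_that("protected LSD separates means beyond the threshold and only
           then", {
  d <- random_rcbd_table(seed = 3, sd = 0.5, eff_t = 10)
  an <- anova_factorial_rcbd(d, "y")
  lsd <- fisher_protected_lsd(an)
  g <- lsd$groups
  expect_equal(lsd$lsd_value,
               qt(0.975, attr(an, "df_error")) *
                 sqrt(2 * attr(an, "mse") / attr(an, "n_blocks")),
               tolerance = 1e-12)
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    share <- any(strsplit(g$letters[i], "")[[1]] %in%
                   strsplit(g$letters[j], "")[[1]])
    if (abs(g$mean[i] - g$mean[j]) > lsd$lsd_value)
      expect_false(share)
    if (g$mean[i] == g$mean[j])
      expect_true(share)
  }
})

test_that("a non-significant omnibus F collapses all groups to one letter", {
  d <- random_rcbd_table(seed = 8, sd = 5)  # pure noise
  an <- anova_factorial_rcbd(d, "y")
  lsd <- fisher_protected_lsd(an, gate_p = 0.6)
  expect_true(all(lsd$groups$letters == "a"))
  expect_false(lsd$gate_significant)
})

test_that("LSD letters are invariant to group input order", {
  d <- random_rcbd_table(seed = 12, sd = 0.5, eff_t = 6, eff_c = 3)
  an <- anova_factorial_rcbd(d, "y")
  means <- setNames(attr(an, "cell_means")$value,
                    paste(attr(an, "cell_means")$cultivar,
                          attr(an, "cell_means")$treatment, sep = ":"))
  l1 <- fisher_protected_lsd(an, means = means)
  perm <- c(3, 1, 4, 2)
  l2 <- fisher_protected_lsd(an, means = means[perm])
  m <- match(l1$groups$group, l2$groups$group)
  expect_identical(l1$groups$letters, l2$groups$letters[m])
})

test_that("Shapiro-Wilk wrapper behaves at its boundaries", {
  w <- shapiro_wilk(qnorm(ppoints(50)))
  expect_gt(w$w, 0.99)
  bimodal <- c(rnorm(40, -6, 0.3), rnorm(40, 6, 0.3))
  expect_lt(shapiro_wilk(bimodal)$p, 0.01)
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
})

test_that("Pearson matrix recovers exact linear relations and their signs", {
  x <- 1:16
  m <- data.frame(a = x, b = 2 * x, c = -x + 3, d = rnorm(16))
  pm <- pearson_matrix(m)
  expect_equal(unname(pm$r["a", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(pm$r["a", "c"]), -1, tolerance = 1e-12)
  expect_equal(pm$r, t(pm$r))
  expect_true(all(diag(pm$r) == 1))
  expect_true(all(abs(pm$r) <= 1))
  # affine invariance (sign-aware)
  m2 <- transform(m, d = 5 - 3 * d)
  pm2 <- pearson_matrix(m2)
  expect_equal(unname(pm2$r["a", "d"]), -unname(pm$r["a", "d"]),
               tolerance = 1e-12)
  expect_error(pearson_matrix(data.frame(a = x, z = rep(1, 16))), "z")
})

test_that("independent traits show near-zero mean correlation", {
  withr::with_seed(44, {
    rs <- replicate(400, cor(rnorm(16), rnorm(16)))
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(400 * 15))
})

test_that("pooled SEM reproduces the sqrt(MSE/n) convention", {
  expect_equal(pooled_sem(0.0740, 4), 0.136, tolerance = 1e-2)
  expect_equal(pooled_sem(0, 4), 0)
  expect_equal(pooled_sem(2, 4) / pooled_sem(2, 16), 2, tolerance = 1e-12)
  expect_error(pooled_sem(1, 1), "at least 2")
})
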