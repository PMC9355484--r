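# Factorial RCBD statistics layer: two-way fixed-effects ANOVA in a
# randomized complete block design, Fisher's protected LSD mean separation,
# normality diagnostics, Pearson correlation matrix and pooled SEM.

#' Aggregate a long trait table to plot (cell-by-block) means
#'
#' Plants within a cultivar x treatment x block cell are subsamples of one
#' experimental unit (the plot); averaging them before ANOVA guards against
#' pseudo-replication.
#'
#' @param table long-format data.frame with columns `cultivar`, `treatment`,
#'   `block`, `plant`, `trait`, `value`.
#' @param trait trait name to extract.
#' @return data.frame with one row per cultivar x treatment x block and a
#'   `value` column holding the plot mean.
#' @export
plot_means <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not found: ", trait)
  out <- stats::aggregate(value ~ cultivar + treatment + block, data = d,
                          FUN = mean)
  out
}

#' Two-way factorial ANOVA in a randomized complete block design
#'
#' Balanced fixed-effects decomposition for a cultivar x treatment factorial
#' with blocks: sources cultivar, treatment, cultivar x treatment, block and
#' error, F-tested against the error mean square. Observations are plot
#' means (use [plot_means()] to aggregate plant subsamples first, or pass
#' `aggregate_plants = TRUE` with a plant-level table).
#'
#' @param table long-format trait table (see [plot_means()]).
#' @param trait trait name.
#' @param alpha significance level for the `significant` flag; default 0.05.
#' @param aggregate_plants average plants to plot means first (default TRUE).
#' @return data.frame of class `anova_rcbd` with columns `source`, `df`,
#'   `ss`, `ms`, `f`, `p`, `significant`; attributes `mse`, `df_error`,
#'   `n_blocks`, `cell_means`. When an effect SS is exactly 0 (e.g. all
#'   observations equal) its F is reported as 0.
#' @export
anova_factorial_rcbd <- function(table, trait, alpha = 0.05,
                                 aggregate_plants = TRUE) {
  d <- if (aggregate_plants) plot_means(table, trait) else {
    x <- table[table$trait == trait, , drop = FALSE]
    if (!nrow(x)) stop("trait not found: ", trait)
    x
  }
  if (!all(is.finite(d$value))) stop("trait values must be finite")
  tab <- table(d$cultivar, d$treatment, d$block)
  if (any(tab == 0))
    stop("missing cultivar x treatment x block cell(s); the design must ",
         "be complete")
  if (length(unique(as.vector(tab))) != 1)
    stop("unbalanced design: aggregate plants to plot means first")
  if (dim(tab)[3] < 2) stop("need at least 2 blocks")

  d$cultivar <- factor(d$cultivar)
  d$treatment <- factor(d$treatment)
  d$block <- factor(d$block)
  fit <- stats::aov(value ~ block + cultivar + treatment +
                      cultivar:treatment, data = d)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  row_of <- function(nm) which(rn == nm)
  pick <- c(cultivar = row_of("cultivar"), treatment = row_of("treatment"),
            `cultivar:treatment` = row_of("cultivar:treatment"),
            block = row_of("block"), error = row_of("Residuals"))
  out <- data.frame(source = names(pick),
                    df = s$Df[pick],
                    ss = s$`Sum Sq`[pick],
                    ms = s$`Mean Sq`[pick],
                    row.names = NULL)
  mse <- out$ms[out$source == "error"]
  out$f <- ifelse(out$source == "error", NA,
                  ifelse(out$ss == 0, 0, out$ms / mse))
  out$p <- ifelse(is.na(out$f), NA,
                  stats::pf(out$f, out$df, out$df[out$source == "error"],
                            lower.tail = FALSE))
  out$significant <- !is.na(out$p) & out$p <= alpha

  cm <- stats::aggregate(value ~ cultivar + treatment, data = d, FUN = mean)
  structure(out, class = c("anova_rcbd", "data.frame"),
            mse = mse, df_error = out$df[out$source == "error"],
            n_blocks = dim(tab)[3], alpha = alpha, cell_means = cm,
            trait = trait)
}

#' Pooled standard error of the mean from the ANOVA error term
#'
#' SEM = sqrt(MSE/n): the pooled SEM displayed as a single error bar per
#' trait when treatment variances are homogeneous.
#'
#' @param anova an `anova_rcbd` table (or any object with an `mse`
#'   attribute), or a single MSE value.
#' @param n number of replications contributing to each displayed mean
#'   (≥ 2).
#' @return pooled SEM.
#' @export
pooled_sem <- function(anova, n) {
  if (n < 2) stop("n must be at least 2")
  mse <- if (is.numeric(anova) && length(anova) == 1) anova
         else attr(anova, "mse")
  if (is.null(mse)) stop("cannot extract MSE")
  sqrt(mse / n)
}

#' Fisher's protected LSD mean separation
#'
#' LSD = t(1 − α/2, df_error) · sqrt(2·MSE/n). Letters are assigned to the
#' descending-sorted means by the standard sweep: means within one LSD of
#' each other may share a letter; means differing by more than the LSD never
#' do. Protection: when the gating omnibus F test is non-significant, all
#' groups share a single letter.
#'
#' @param anova an `anova_rcbd` object fitted on the same data.
#' @param means named numeric vector of group (cell) means; when NULL the
#'   cultivar x treatment cell means stored in `anova` are used.
#' @param n_per_group replications per mean; defaults to the block count.
#' @param alpha significance level; default 0.05.
#' @param gate_p p-value of the gating omnibus test; by default the
#'   smallest p among the cultivar, treatment and interaction effects.
#' @return list of class `lsd_result`: `lsd_value`, `groups` (data.frame
#'   mean/letters in input order), `protected`, `gate_significant`.
#' @export
fisher_protected_lsd <- function(anova, means = NULL, n_per_group = NULL,
                                 alpha = 0.05, gate_p = NULL) {
  if (is.null(means)) {
    cm <- attr(anova, "cell_means")
    means <- stats::setNames(cm$value,
                             paste(cm$cultivar, cm$treatment, sep = ":"))
  }
  if (is.null(n_per_group)) n_per_group <- attr(anova, "n_blocks")
  if (is.null(n_per_group) || n_per_group <= 1)
    stop("n_per_group must exceed 1")
  mse <- attr(anova, "mse")
  df_err <- attr(anova, "df_error")
  if (is.null(gate_p)) {
    eff <- anova$p[anova$source %in%
                     c("cultivar", "treatment", "cultivar:treatment")]
    gate_p <- min(eff, na.rm = TRUE)
  }
  lsd <- stats::qt(1 - alpha / 2, df_err) * sqrt(2 * mse / n_per_group)
  gate_sig <- is.finite(gate_p) && gate_p <= alpha

  k <- length(means)
  if (!gate_sig || lsd == 0 && all(means == means[1])) {
    letters_out <- rep("a", k)
  } else {
    ord <- order(means, decreasing = TRUE)
    m <- means[ord]
    # maximal runs of means whose range does not exceed the LSD
    segs <- list()
    for (s in seq_len(k)) {
      e <- s
      while (e < k && (m[s] - m[e + 1]) <= lsd + 1e-12) e <- e + 1
      segs[[s]] <- c(s, e)
    }
    # drop segments contained in another
    keep <- vapply(seq_along(segs), function(j) {
      !any(vapply(seq_along(segs), function(l) {
        l != j && segs[[l]][1] <= segs[[j]][1] && segs[[l]][2] >= segs[[j]][2]
      }, logical(1)))
    }, logical(1))
    segs <- unique(segs[keep])
    segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
    lab <- rep("", k)
    for (j in seq_along(segs))
      for (idx in segs[[j]][1]:segs[[j]][2])
        lab[idx] <- paste0(lab[idx], letters[j])
    letters_out <- character(k)
    letters_out[ord] <- lab
  }
  structure(list(lsd_value = lsd,
                 groups = data.frame(group = names(means), mean = unname(means),
                                     letters = letters_out,
                                     row.names = NULL),
                 protected = TRUE, gate_significant = gate_sig,
                 alpha = alpha),
            class = "lsd_result")
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation as implemented in base R's
#' \code{stats::shapiro.test}, wrapped to return the (W, p) pair used as a
#' pre-pooling variance diagnostic.
#'
#' @param values numeric sample, 3 ≤ n ≤ 5000, non-constant.
#' @return list with `w` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("sample size must lie in [3, 5000]")
  if (stats::sd(values) == 0) stop("sample is constant")
  ht <- stats::shapiro.test(values)
  list(w = unname(ht$statistic), p = ht$p.value)
}

#' Pearson correlation matrix across traits
#'
#' Product-moment correlations between trait columns with two-sided
#' p-values from the t transform with n − 2 degrees of freedom, plus
#' significance stars at α = 0.05.
#'
#' @param table either a wide data.frame of numeric trait columns, or a
#'   long trait table (columns cultivar/treatment/block/trait/value), which
#'   is reshaped to plot-level wide format first.
#' @param traits trait names to include (default: all).
#' @return list of class `correlation_matrix`: `traits`, `r`, `p`, `n`,
#'   `stars`.
#' @export
pearson_matrix <- function(table, traits = NULL) {
  if (all(c("trait", "value") %in% names(table))) {
    pm <- stats::aggregate(value ~ cultivar + treatment + block + trait,
                           data = table, FUN = mean)
    wide <- stats::reshape(pm, direction = "wide",
                           idvar = c("cultivar", "treatment", "block"),
                           timevar = "trait")
    names(wide) <- sub("^value\\.", "", names(wide))
    mat <- wide[, setdiff(names(wide), c("cultivar", "treatment", "block")),
                drop = FALSE]
  } else {
    mat <- table[, vapply(table, is.numeric, logical(1)), drop = FALSE]
  }
  if (!is.null(traits)) mat <- mat[, traits, drop = FALSE]
  traits <- names(mat)
  k <- length(traits)
  sds <- vapply(mat, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  if (any(sds == 0))
    stop("zero-variance trait(s): ",
         paste(traits[sds == 0], collapse = ", "))
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (ii in seq_len(k)) for (jj in seq_len(k)) {
    x <- mat[[ii]]; y <- mat[[jj]]
    ok <- is.finite(x) & is.finite(y)
    nn <- sum(ok)
    if (nn < 3) stop("need at least 3 complete observations per pair")
    rij <- stats::cor(x[ok], y[ok])
    nmat[ii, jj] <- nn
    r[ii, jj] <- rij
    if (ii == jj) p[ii, jj] <- 0 else {
      tt <- rij * sqrt((nn - 2) / max(1 - rij^2, .Machine$double.eps))
      p[ii, jj] <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
    }
  }
  diag(r) <- 1
  stars <- ifelse(p <= 0.05 & row(p) != col(p), "*", "")
  structure(list(traits = traits, r = r, p = p, n = nmat, stars = stars),
            class = "correlation_matrix")
}
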