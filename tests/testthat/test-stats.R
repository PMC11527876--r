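make_lmm_data <- function(seed, n_genes = 60, b_w = 0, b_nmt = 0, b_int = 0,
                          sd_g = 0.3, sd_e = 0.2, nmt_frac = 0.5) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  is_nmt <- rep(c(TRUE, FALSE), c(round(nmt_frac * n_genes),
                                  n_genes - round(nmt_frac * n_genes)))
  u <- rnorm(n_genes, 0, sd_g)
  rows <- lapply(seq_len(n_genes), function(i) {
    data.frame(gene_id = genes[i], is_nmt = is_nmt[i], linkage = c("Z", "W"),
               y = u[i] + c(0, b_w) + b_nmt * is_nmt[i] +
                 c(0, b_int) * is_nmt[i] + rnorm(2, 0, sd_e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("REML matches lme4 on an unbalanced two-factor design", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data(1, b_w = 0.4, b_nmt = 0.2, b_int = 0.3)
  d <- d[-c(3, 10, 25), ] # unbalance
  fit <- fit_random_intercept_lmm(d, "y", c("is_nmt", "linkage"),
                                  interaction = TRUE)
  ref <- lme4::lmer(y ~ is_nmt * linkage + (1 | gene_id),
                    data = transform(d, is_nmt = factor(ifelse(is_nmt, "N-mt", "non-N-mt"),
                                                        levels = c("non-N-mt", "N-mt")),
                                     linkage = factor(linkage, levels = c("Z", "W"))),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-5)
  expect_equal(fit$sigma2_g, vc$vcov[1], tolerance = 1e-6)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-6)
})

test_that("REML equals closed-form ANOVA components on balanced one-way data", {
  set.seed(3)
  m <- 5; k <- 30
  g <- rep(sprintf("g%02d", 1:k), each = m)
  y <- rep(rnorm(k, 10, 0.8), each = m) + rnorm(k * m, 0, 0.4)
  d <- data.frame(gene_id = g, y = y)
  fit <- fit_random_intercept_lmm(d, "y", character(0))
  gm <- tapply(y, g, mean)
  msb <- m * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - rep(gm, each = m))^2) / (k * (m - 1))
  expect_equal(fit$sigma2_e, msw, tolerance = 1e-10)
  expect_lt(abs(fit$sigma2_g - (msb - msw) / m), 1e-8)
})

test_that("zero gene variance degenerates to ordinary least squares", {
  # residuals centered within genes: the between-gene variance component is
  # below its null expectation, so REML sits at the lambda = 0 boundary and
  # GLS collapses to OLS
  d <- make_lmm_data(4, b_w = 0.3, sd_g = 0, sd_e = 0.5)
  X <- model.matrix(~ factor(linkage, levels = c("Z", "W")), d)
  resid <- d$y - X %*% qr.solve(X, d$y)
  d$y <- d$y - ave(as.vector(resid), d$gene_id)
  fit <- fit_random_intercept_lmm(d, "y", "linkage", interaction = FALSE)
  ols <- qr.solve(X, d$y)
  expect_equal(fit$sigma2_g, 0)
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-6)
})

test_that("degenerate designs fall back or fail informatively", {
  d <- make_lmm_data(5)
  d1 <- d[d$linkage == "W", ] # one obs per gene
  expect_warning(fit <- fit_random_intercept_lmm(d1, "y", "is_nmt",
                                                 interaction = FALSE),
                 "falling back to OLS")
  expect_equal(fit$method, "ols")
  expect_equal(fit$sigma2_g, 0)

  d2 <- d
  d2$dup <- d2$linkage # aliased with linkage
  expect_error(fit_random_intercept_lmm(d2, "y", c("linkage", "dup"),
                                        interaction = FALSE),
               "rank deficient")

  d3 <- d; d3$y <- 1
  expect_warning(fit3 <- fit_random_intercept_lmm(d3, "y", "linkage",
                                                  interaction = FALSE),
                 "constant response")
  expect_equal(fit3$coefficients$estimate[2], 0)
})

test_that("estimates are invariant to row order and gene relabelling", {
  d <- make_lmm_data(6, b_w = 0.25, b_int = 0.2)
  f1 <- fit_random_intercept_lmm(d, "y", c("is_nmt", "linkage"))
  set.seed(7)
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_random_intercept_lmm(d2, "y", c("is_nmt", "linkage"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-9)
  d3 <- d
  d3$gene_id <- chartr("g", "x", d3$gene_id)
  f3 <- fit_random_intercept_lmm(d3, "y", c("is_nmt", "linkage"))
  expect_equal(f1$coefficients$estimate, f3$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("interaction Wald test is approximately calibrated under the null", {
  rejected <- vapply(1:300, function(s) {
    d <- make_lmm_data(1000 + s, n_genes = 40)
    fit <- fit_random_intercept_lmm(d, "y", c("is_nmt", "linkage"),
                                    interaction = TRUE)
    fit$coefficients$p[grepl(":", fit$coefficients$term)] < 0.05
  }, TRUE)
  expect_gt(mean(rejected), 0.02)
  expect_lt(mean(rejected), 0.09)
})

test_that("contrast report isolates the W effect within function classes", {
  d <- make_lmm_data(8, n_genes = 200, b_w = 0.05, b_int = 0.4)
  rep <- interaction_and_contrasts(d, "y")
  expect_lt(rep$interaction_p, 0.05)
  expect_gt(rep$w_effect_ratio, 1) # W effect stronger for N-mt genes
  expect_true(all(c("N-mt", "non-N-mt") %in% names(rep$by_function)))
  # single-class data: only the estimable contrast is reported
  d1 <- d[d$is_nmt, ]
  rep1 <- suppressWarnings(
    fit_random_intercept_lmm(d1, "y", "linkage", interaction = FALSE))
  expect_s3_class(rep1, "neosex_lmm")
})
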