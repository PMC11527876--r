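# Random-intercept linear mixed models for divergence responses, fitted by
# REML with the variance ratio lambda = sigma2_gene / sigma2_resid profiled
# out by 1-D bounded optimization (GLS for the fixed effects at each lambda).
# Wald tests use the GLS covariance with a normal reference.

# Profiled REML criterion at lambda (up to an additive constant):
#   (n - p) log(RSS_gls) + sum_i log(1 + n_i lambda) + log det(X' V*^-1 X)
# where V* = I + lambda Z Z' and RSS_gls is the generalized residual sum of
# squares at the GLS fixed-effect solution.
.reml_pieces <- function(lambda, X, y, g) {
  n <- length(y)
  p <- ncol(X)
  ni <- tabulate(g)
  shrink <- lambda / (1 + ni * lambda) # per group
  Xg <- rowsum(X, g) # group sums of columns
  yg <- rowsum(y, g)[, 1]
  A <- crossprod(X) - crossprod(Xg * sqrt(shrink))
  b <- crossprod(X, y) - crossprod(Xg, shrink * yg)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  r <- y - X %*% beta
  rg <- rowsum(as.vector(r), g)[, 1]
  rss <- sum(r^2) - sum(shrink * rg^2)
  logdetA <- 2 * sum(log(diag(ch)))
  crit <- (n - p) * log(rss) + sum(log(1 + ni * lambda)) + logdetA
  list(crit = crit, beta = beta, rss = rss, A = A, ni = ni, n = n, p = p)
}

# Analytic derivative of the profiled REML criterion with respect to lambda;
# used to polish the Brent minimum to near machine precision:
#   crit'(lambda) = -(n-p) sum_i s_i' rg_i^2 / RSS
#                   + sum_i n_i/(1+n_i lambda) - sum_i s_i' Xg_i' A^-1 Xg_i
# with s_i' = d/dlambda [lambda/(1+n_i lambda)] = (1+n_i lambda)^-2.
.reml_grad <- function(lambda, X, y, g) {
  pieces <- .reml_pieces(lambda, X, y, g)
  if (is.null(pieces)) return(NA_real_)
  ni <- pieces$ni
  dshrink <- 1 / (1 + ni * lambda)^2
  Xg <- rowsum(X, g)
  yg <- rowsum(y, g)[, 1]
  rg <- yg - as.vector(Xg %*% pieces$beta)
  q <- rowSums((Xg %*% solve(pieces$A)) * Xg)
  -(pieces$n - pieces$p) * sum(dshrink * rg^2) / pieces$rss +
    sum(ni / (1 + ni * lambda)) - sum(dshrink * q)
}

#' Fit a random-intercept linear mixed model by profiled REML
#'
#' Fits `response ~ fixed effects + (1 | group)` where the single random
#' effect is a per-gene intercept. REML estimation profiles the fixed effects
#' and residual variance out analytically and optimizes the variance ratio
#' `lambda = sigma2_g / sigma2_e` by 1-D bounded search (no randomness).
#' Fixed-effect reference levels are non-N-mt function and Z linkage, so the
#' linkage coefficient measures the W effect. When every group contributes a
#' single observation the gene variance is inestimable and the fit falls back
#' to ordinary least squares with a warning.
#'
#' @param data Data frame containing the response, the grouping column, and
#'   the fixed-effect columns.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect column names (e.g.
#'   `c("is_nmt", "linkage")`); `is_nmt` may be logical (recoded to
#'   non-N-mt/N-mt) and `linkage` is releveled to reference `Z`.
#' @param interaction Include the two-way interaction of the first two fixed
#'   effects (requires both main effects).
#' @param group Name of the grouping (gene id) column.
#' @return An object of class `neosex_lmm`: list with `coefficients` (estimate,
#'   se, z, p per term), `sigma2_g`, `sigma2_e`, `lambda`, `reml_criterion`,
#'   `n_obs`, `n_groups`, `method` ("reml" or "ols"), `reference_levels`.
#' @export
fit_random_intercept_lmm <- function(data, response, fixed,
                                     interaction = length(fixed) >= 2,
                                     group = "gene_id") {
  stopifnot(response %in% names(data), group %in% names(data),
            all(fixed %in% names(data)))
  if (interaction && length(fixed) < 2)
    stop("interaction requires both main effects")
  df <- data
  if ("is_nmt" %in% fixed && !is.factor(df$is_nmt))
    df$is_nmt <- factor(ifelse(as.logical(df$is_nmt), "N-mt", "non-N-mt"),
                        levels = c("non-N-mt", "N-mt"))
  if ("linkage" %in% fixed)
    df$linkage <- factor(df$linkage, levels = c("Z", setdiff(unique(df$linkage), "Z")))
  rhs <- if (length(fixed) == 0) {
    "1"
  } else if (interaction) {
    paste(paste(fixed, collapse = " + "), "+",
          paste(fixed[1], fixed[2], sep = ":"))
  } else {
    paste(fixed, collapse = " + ")
  }
  fml <- stats::as.formula(paste("~", rhs))
  keep <- stats::complete.cases(df[, c(response, group, fixed)])
  df <- df[keep, , drop = FALSE]
  X <- stats::model.matrix(fml, df)
  y <- df[[response]]
  g <- factor(df[[group]])
  n <- length(y)
  p <- qr(X)$rank
  if (p < ncol(X)) {
    aliased <- colnames(X)[-seq_len(p)]
    stop("design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  if (nlevels(g) < 2) stop("need at least 2 groups")

  wald <- function(beta, covb) {
    se <- sqrt(diag(covb))
    z <- beta / se
    data.frame(term = colnames(X), estimate = as.vector(beta), se = se,
               z = as.vector(z), p = 2 * stats::pnorm(-abs(z)),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  ols_fit <- function(reason) {
    warning("sigma2_g inestimable (", reason, "); falling back to OLS")
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - ncol(X))
    covb <- s2 * chol2inv(chol(crossprod(X)))
    structure(list(coefficients = wald(fit$coefficients, covb),
                   sigma2_g = 0, sigma2_e = s2, lambda = 0,
                   reml_criterion = NA_real_, n_obs = n,
                   n_groups = nlevels(g), method = "ols",
                   reference_levels = c(is_nmt = "non-N-mt", linkage = "Z")),
              class = "neosex_lmm")
  }

  if (stats::var(y) == 0) return(ols_fit("constant response"))
  if (max(tabulate(g)) == 1L) return(ols_fit("one observation per group"))

  gi <- as.integer(g) # rowsum() and tabulate() then agree on group order
  obj <- function(theta) {
    pieces <- .reml_pieces(exp(theta), X, y, gi)
    if (is.null(pieces)) return(.Machine$double.xmax)
    pieces$crit
  }
  opt <- stats::optimize(obj, interval = c(-30, 15), tol = 1e-10)
  lam <- exp(opt$minimum)
  # polish with the analytic gradient: root of crit'(lambda) near the Brent
  # minimum (Brent alone resolves lambda only to ~sqrt(eps) relative)
  lo <- lam / 4; hi <- lam * 4
  glo <- .reml_grad(lo, X, y, gi)
  ghi <- .reml_grad(hi, X, y, gi)
  if (is.finite(glo) && is.finite(ghi) && glo < 0 && ghi > 0) {
    lam <- stats::uniroot(function(l) .reml_grad(l, X, y, gi),
                          lower = lo, upper = hi,
                          tol = .Machine$double.eps * max(1, lam))$root
  }
  # compare against the lambda = 0 boundary (pure OLS covariance structure)
  p0 <- .reml_pieces(0, X, y, gi)
  best <- .reml_pieces(lam, X, y, gi)
  if (!is.null(p0) && p0$crit <= best$crit) {
    lam <- 0
    best <- p0
  }
  s2e <- best$rss / (n - ncol(X))
  s2g <- lam * s2e
  covb <- s2e * solve(best$A)
  structure(list(coefficients = wald(best$beta, covb),
                 sigma2_g = s2g, sigma2_e = s2e, lambda = lam,
                 reml_criterion = best$crit, n_obs = n,
                 n_groups = nlevels(g), method = "reml",
                 reference_levels = c(is_nmt = "non-N-mt", linkage = "Z")),
            class = "neosex_lmm")
}

#' @export
print.neosex_lmm <- function(x, ...) {
  cat("Random-intercept LMM (", x$method, "), ", x$n_obs, " obs in ",
      x$n_groups, " groups\n", sep = "")
  cat("reference levels: function = non-N-mt, linkage = Z\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("sigma2_gene = %.6g  sigma2_resid = %.6g\n",
              x$sigma2_g, x$sigma2_e))
  invisible(x)
}

.term_row <- function(fit, pattern) {
  i <- grep(pattern, fit$coefficients$term)
  if (length(i) != 1) return(NULL)
  fit$coefficients[i, ]
}

#' Interaction test and per-class contrasts
#'
#' Given per-gene divergence observations with function and linkage labels,
#' fits the full interaction model, then refits within each linkage class
#' (testing the function effect) and within each function class (testing the
#' linkage effect). Reports the Wald p-value of the interaction and the ratio
#' of the W-linkage coefficients between function classes (how much stronger
#' the W effect is for N-mt genes).
#'
#' @param data Data frame with columns `gene_id`, `is_nmt`, `linkage`, and
#'   the response.
#' @param response Name of the response column.
#' @return List with `full` (the interaction fit), `interaction_p`,
#'   `by_linkage` (function-effect rows per linkage class), `by_function`
#'   (linkage-effect rows per function class), and `w_effect_ratio`
#'   (`b_linkage[N-mt] / b_linkage[non-N-mt]`, `NA` when not estimable).
#' @export
interaction_and_contrasts <- function(data, response) {
  full <- fit_random_intercept_lmm(data, response, c("is_nmt", "linkage"),
                                   interaction = TRUE)
  inter <- .term_row(full, ":")
  refit <- function(sub, term) {
    tryCatch(
      .term_row(suppressWarnings(
        fit_random_intercept_lmm(sub, response, term, interaction = FALSE)),
        term),
      error = function(e) {
        message("contrast skipped: ", conditionMessage(e))
        NULL
      })
  }
  by_linkage <- list()
  for (lk in intersect(c("W", "Z"), unique(data$linkage))) {
    sub <- data[data$linkage == lk, , drop = FALSE]
    if (length(unique(sub$is_nmt)) < 2) next
    by_linkage[[lk]] <- refit(sub, "is_nmt")
  }
  by_function <- list()
  for (fn in c(TRUE, FALSE)) {
    sub <- data[as.logical(data$is_nmt) == fn, , drop = FALSE]
    if (length(unique(sub$linkage)) < 2) next
    by_function[[if (fn) "N-mt" else "non-N-mt"]] <- refit(sub, "linkage")
  }
  by_function <- Filter(Negate(is.null), by_function)
  by_linkage <- Filter(Negate(is.null), by_linkage)
  ratio <- NA_real_
  if (!is.null(by_function[["N-mt"]]) && !is.null(by_function[["non-N-mt"]]) &&
      by_function[["non-N-mt"]]$estimate != 0) {
    ratio <- by_function[["N-mt"]]$estimate / by_function[["non-N-mt"]]$estimate
  }
  list(full = full,
       interaction_p = if (is.null(inter)) NA_real_ else inter$p,
       by_linkage = by_linkage, by_function = by_function,
       w_effect_ratio = ratio)
}
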