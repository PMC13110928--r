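#' Build the oscillation-emergence GEE design
#'
#' Encodes a plate-level occurrence table as the marginal-model design:
#' response `y = n_oscillating / n_wells`, observation weights `n_wells`,
#' cluster = plate, and fixed effects (in this deterministic column order)
#' intercept, centered week `t`, condition indicators `C_80` and `C_50`
#' (reference = the iGluta-alone condition) and the `t x condition`
#' interactions.
#'
#' @param table occurrence data.frame (`plate_id, condition, week, n_wells,
#'   n_oscillating`).
#' @param reference_condition label of the reference condition. Labels
#'   `"iGluta"` and `"iGluta-alone"` are treated as synonyms.
#' @param center_weeks center the week covariate at its observed mean
#'   (default `TRUE`).
#' @return list of class `gee_design`: `X` (model matrix), `y`, `weights`,
#'   `cluster`, `terms`.
#' @export
build_design <- function(table, reference_condition = "iGluta",
                         center_weeks = TRUE) {
  tab <- as.data.frame(table)
  cond <- as.character(tab$condition)
  cond[cond == "iGluta-alone"] <- "iGluta"
  if (reference_condition == "iGluta-alone") reference_condition <- "iGluta"
  known <- c("iGluta", "80:20", "50:50")
  if (!all(cond %in% known))
    stop("unknown condition label(s): ",
         paste(setdiff(cond, known), collapse = ", "))
  if (!reference_condition %in% known)
    stop("unknown reference condition: ", reference_condition)
  non_ref <- setdiff(known, reference_condition)
  # keep the canonical order 80:20 before 50:50 for the indicator columns
  non_ref <- known[known %in% non_ref]
  t <- tab$week
  if (center_weeks) t <- t - mean(t)
  c80 <- as.numeric(cond == non_ref[1])
  c50 <- as.numeric(cond == non_ref[2])
  X <- cbind(`(Intercept)` = 1, t = t, C_80 = c80, C_50 = c50,
             `t:C_80` = t * c80, `t:C_50` = t * c50)
  if (any(tab$n_wells < 1)) stop("weights (n_wells) must be >= 1")
  y <- tab$n_oscillating / tab$n_wells
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  structure(list(X = X, y = y, weights = tab$n_wells,
                 cluster = as.character(tab$plate_id),
                 terms = colnames(X)),
            class = "gee_design")
}

#' Fit the weighted binomial-logit GEE
#'
#' Marginal model for correlated binomial fractions: logit link, exchangeable
#' within-cluster working correlation, observation-level weights (wells per
#' plate), scale fixed at 1. Estimation alternates Fisher scoring for the
#' regression coefficients with a moment estimate of the exchangeable
#' correlation from within-cluster products of Pearson residuals
#' (degrees-of-freedom corrected and normalized by the estimated Pearson
#' scale, so the estimate is a correlation; the working variance keeps the
#' binomial scale fixed at 1). Standard errors come from the robust
#' sandwich covariance; Wald chi-square statistics are `(beta / se)^2` on 1
#' degree of freedom, and odds ratios are `exp(beta)` with
#' `exp(beta +/- 1.96 se)` confidence limits.
#'
#' @param table occurrence data.frame, or a prebuilt `gee_design`.
#' @param reference_condition passed to [build_design()].
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return object of class `gee_fit`: `beta`, `robust_se`, `alpha_hat`,
#'   `wald_chi2`, `p_value`, `odds_ratio`, `or_ci` (2-column matrix),
#'   `vcov`, `n_clusters`, `n_obs`, `converged`, `n_iterations`.
#' @export
fit_gee <- function(table, reference_condition = "iGluta", tol = 1e-8,
                    max_iter = 100) {
  design <- if (inherits(table, "gee_design")) table
            else build_design(table, reference_condition)
  X <- design$X
  y <- design$y
  w <- design$weights
  cl <- design$cluster
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X)
  idx <- split(seq_along(y), cl)
  # initialize from the independence-model weighted logistic fit
  init <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::binomial())
  )
  beta <- init$coefficients
  if (anyNA(beta)) stop("initial weighted logistic fit failed (separation?)")
  alpha <- 0
  converged <- FALSE
  iter <- 0
  clamp <- function(p) pmin(pmax(p, 1e-8), 1 - 1e-8)
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- clamp(stats::plogis(eta))
    v <- mu * (1 - mu) / w                 # working variance, scale phi = 1
    r <- (y - mu) / sqrt(v)                # Pearson residuals
    # moment estimator of the exchangeable correlation
    num <- 0
    npairs <- 0
    for (ii in idx) {
      ni <- length(ii)
      if (ni < 2) next
      ri <- r[ii]
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      npairs <- npairs + ni * (ni - 1) / 2
    }
    # normalize by the estimated Pearson scale so alpha is a correlation
    # (the working variance itself keeps phi fixed at 1, as is standard for
    # binomial GEEs); without this, cluster-level overdispersion inflates the
    # products and alpha escapes [-1, 1]
    phi_hat <- sum(r^2) / (length(y) - p)
    alpha <- if (npairs > p && phi_hat > 0) num / ((npairs - p) * phi_hat)
             else 0
    nmax <- max(lengths(idx))
    alpha <- max(min(alpha, 0.999),
                 if (nmax > 1) -0.999 / (nmax - 1) else 0)
    # Fisher scoring update with working covariance A^1/2 R(alpha) A^1/2
    lhs <- matrix(0, p, p)
    rhs <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Xi <- X[ii, , drop = FALSE]
      mui <- mu[ii]
      Ai <- v[ii]
      Di <- Xi * (mui * (1 - mui))         # d mu / d beta
      R <- matrix(alpha, ni, ni)
      diag(R) <- 1
      Vi <- sqrt(Ai) * R * rep(sqrt(Ai), each = ni)
      Vinv <- solve(Vi)
      DtVinv <- crossprod(Di, Vinv)
      lhs <- lhs + DtVinv %*% Di
      rhs <- rhs + DtVinv %*% (y[ii] - mui)
    }
    delta <- solve(lhs, rhs)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  # robust sandwich covariance at the final beta
  eta <- drop(X %*% beta)
  mu <- clamp(stats::plogis(eta))
  v <- mu * (1 - mu) / w
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Xi <- X[ii, , drop = FALSE]
    mui <- mu[ii]
    Ai <- v[ii]
    Di <- Xi * (mui * (1 - mui))
    R <- matrix(alpha, ni, ni)
    diag(R) <- 1
    Vi <- sqrt(Ai) * R * rep(sqrt(Ai), each = ni)
    Vinv <- solve(Vi)
    DtVinv <- crossprod(Di, Vinv)
    ei <- y[ii] - mui
    B <- B + DtVinv %*% Di
    u <- DtVinv %*% ei
    M <- M + u %*% t(u)
  }
  Binv <- solve(B)
  vc <- Binv %*% M %*% Binv
  se <- sqrt(diag(vc))
  chi2 <- (beta / se)^2
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- design$terms
  if (!converged)
    warning("GEE did not converge in ", max_iter, " iterations")
  structure(list(beta = stats::setNames(beta, design$terms),
                 robust_se = stats::setNames(se, design$terms),
                 alpha_hat = alpha,
                 wald_chi2 = stats::setNames(chi2, design$terms),
                 p_value = stats::setNames(pval, design$terms),
                 odds_ratio = stats::setNames(exp(beta), design$terms),
                 or_ci = ci, vcov = vc,
                 n_clusters = length(idx), n_obs = length(y),
                 converged = converged, n_iterations = iter),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial-logit GEE (exchangeable, alpha = %.4f, %d clusters, %d obs)\n",
    x$alpha_hat, x$n_clusters, x$n_obs))
  tab <- data.frame(beta = x$beta, robust_se = x$robust_se,
                    wald_chi2 = x$wald_chi2, p = x$p_value,
                    OR = x$odds_ratio, OR_lo = x$or_ci[, 1],
                    OR_hi = x$or_ci[, 2])
  print(round(tab, 4))
  if (!x$converged) cat("warning: not converged\n")
  invisible(x)
}

#' Wald test of one GEE coefficient
#'
#' @param fit a [fit_gee()] result.
#' @param coefficient coefficient name or index.
#' @return list with `chi2` and `p` (upper tail of chi-square on 1 df).
#' @export
wald_test <- function(fit, coefficient) {
  stopifnot(inherits(fit, "gee_fit"))
  b <- fit$beta[coefficient]
  se <- fit$robust_se[coefficient]
  if (anyNA(b)) stop("unknown coefficient: ", coefficient)
  if (se == 0) stop("robust SE is zero")
  chi2 <- unname((b / se)^2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
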