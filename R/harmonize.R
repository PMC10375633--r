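# Multi-site (batch) harmonization of regional morphometry.
#
# ComBat fits, per region, a location/scale model with additive and
# multiplicative batch effects on residuals standardized by a pooled
# covariate-adjusted fit, shrinks the per-batch estimates toward parametric
# empirical-Bayes priors (normal on locations, inverse-gamma on variances),
# and back-transforms with the covariate effects restored. CovBat additionally
# harmonizes the covariance structure by running a location/scale correction
# on principal-component scores of the ComBat residuals.

#' Describe the batch structure and biological covariates of a sample
#'
#' @param batch Site/scanner label per subject (coerced to factor). Every
#'   batch must contain at least 2 subjects.
#' @param covariates Optional numeric matrix or data.frame of biological
#'   covariates to preserve (e.g. age, sex, TIV columns); may be NULL.
#' @return Object of class `batch_design`.
#' @export
batch_design <- function(batch, covariates = NULL) {
  batch <- factor(batch)
  counts <- table(batch)
  if (any(counts < 2L)) {
    stop("batch(es) with a single subject: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  X <- covariate_matrix(covariates, length(batch))  # errors on rank deficiency
  structure(list(batch = batch, covariates = X[, -1L, drop = FALSE]),
            class = "batch_design")
}

# Full design: batch one-hot (no intercept) + covariates; used for the pooled
# standardizing fit.
combat_design_matrix <- function(design) {
  B <- outer(design$batch, levels(design$batch), `==`) * 1
  colnames(B) <- levels(design$batch)
  X <- cbind(B, design$covariates)
  if (qr(X)$rank < ncol(X)) stop("batch + covariate design is rank deficient")
  X
}

#' ComBat empirical-Bayes batch harmonization
#'
#' Removes additive and multiplicative batch effects from a subject x region
#' matrix while preserving the covariate effects declared in the design.
#' Parametric empirical Bayes: batch locations get a normal prior, batch
#' variances an inverse-gamma prior, with hyperparameters estimated from the
#' spread across regions and the conditional posterior iterated to convergence
#' (max absolute change < 1e-4, at most 100 sweeps).
#'
#' @param data Subject x region numeric matrix, no missing values.
#' @param design A [batch_design()] aligned with `data` rows.
#' @return List of class `harmonization_result`: `adjusted` (same shape and
#'   dimnames as `data`), `gamma_star` and `delta2_star` (EB-shrunk batch x
#'   region location/scale effects), `model` (pooled fit pieces).
#' @export
combat <- function(data, design) {
  data <- as.matrix(data)
  check_no_missing(data, "data")
  stopifnot(inherits(design, "batch_design"))
  if (nrow(data) != length(design$batch)) stop("data rows do not match design")
  batch <- design$batch
  nb <- nlevels(batch)
  n <- nrow(data)
  R <- ncol(data)
  X <- combat_design_matrix(design)
  n_i <- as.vector(table(batch))

  # pooled fit: per-batch intercepts + covariate slopes, per region
  fit <- stats::lm.fit(X, data)
  beta <- fit$coefficients                      # (nb + p) x R
  grand <- crossprod(n_i / n, beta[seq_len(nb), , drop = FALSE])  # 1 x R
  cov_part <- if (ncol(design$covariates) > 0L) {
    design$covariates %*% beta[-seq_len(nb), , drop = FALSE]
  } else matrix(0, n, R)
  stand_mean <- matrix(grand, n, R, byrow = TRUE) + cov_part
  resid <- data - X %*% beta
  pooled_var <- colSums(resid^2) / n
  if (any(pooled_var <= 0)) stop("region(s) with zero pooled residual variance")
  # zero within-batch variance breaks the scale model
  for (b in levels(batch)) {
    v <- apply(data[batch == b, , drop = FALSE], 2L, stats::var)
    if (any(v <= .Machine$double.eps)) {
      stop("zero within-batch variance in batch ", b, " for region(s) ",
           paste(utils::head(colnames(data)[v <= .Machine$double.eps], 3L), collapse = ", "))
    }
  }
  Z <- (data - stand_mean) / matrix(sqrt(pooled_var), n, R, byrow = TRUE)

  if (nb == 1L) {
    # nothing to remove: a single batch is its own reference
    return(structure(list(
      adjusted = data,
      gamma_star = matrix(0, 1L, R, dimnames = list(levels(batch), colnames(data))),
      delta2_star = matrix(1, 1L, R, dimnames = list(levels(batch), colnames(data))),
      model = list(beta = beta, pooled_var = pooled_var,
                   stand_mean = stand_mean, batch = batch)),
      class = "harmonization_result"))
  }

  gamma_hat <- rowsum(Z, batch) / n_i                       # nb x R
  delta2_hat <- (rowsum(Z^2, batch) - n_i * gamma_hat^2) / (n_i - 1)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (b in seq_len(nb)) {
    g_bar <- mean(gamma_hat[b, ])
    t2 <- stats::var(gamma_hat[b, ])
    # inverse-gamma hyperparameters by method of moments on delta2_hat;
    # degenerate spreads (e.g. a single batch) fall back to no shrinkage
    m <- mean(delta2_hat[b, ]); v <- stats::var(delta2_hat[b, ])
    shrink_loc <- is.finite(t2) && t2 > 1e-12
    shrink_scale <- is.finite(v) && v > 1e-12
    lambda <- if (shrink_scale) (2 * v + m^2) / v else NA_real_
    theta <- if (shrink_scale) (m * v + m^3) / v else NA_real_
    idx <- batch == levels(batch)[b]
    Zb <- Z[idx, , drop = FALSE]
    g_old <- gamma_hat[b, ]; d_old <- delta2_hat[b, ]
    for (it in seq_len(100L)) {
      g_new <- if (shrink_loc) {
        (n_i[b] * t2 * gamma_hat[b, ] + d_old * g_bar) / (n_i[b] * t2 + d_old)
      } else rep(g_bar, R)
      d_new <- if (shrink_scale) {
        ss <- colSums((Zb - matrix(g_new, n_i[b], R, byrow = TRUE))^2)
        (theta + 0.5 * ss) / (n_i[b] / 2 + lambda - 1)
      } else d_old
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(d_old, 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < 1e-4) break
    }
    gamma_star[b, ] <- g_old
    delta2_star[b, ] <- d_old
  }
  if (any(delta2_star <= 0)) stop("non-positive EB variance estimate")

  adj <- (Z - gamma_star[batch, , drop = FALSE]) / sqrt(delta2_star[batch, , drop = FALSE])
  adjusted <- adj * matrix(sqrt(pooled_var), n, R, byrow = TRUE) + stand_mean
  dimnames(adjusted) <- dimnames(data)
  dimnames(gamma_star) <- dimnames(delta2_star) <- list(levels(batch), colnames(data))
  structure(list(adjusted = adjusted, gamma_star = gamma_star,
                 delta2_star = delta2_star,
                 model = list(beta = beta, pooled_var = pooled_var,
                              stand_mean = stand_mean, batch = batch)),
            class = "harmonization_result")
}

#' CovBat covariance-aware batch harmonization
#'
#' Runs [combat()], then projects the harmonized residuals onto principal
#' axes capturing `var_explained` of their variance, applies a per-batch
#' location/scale correction to each retained component score, and
#' reconstructs. This shrinks between-batch differences in regional
#' covariance that location/scale harmonization alone leaves behind.
#'
#' @inheritParams combat
#' @param var_explained Fraction of residual variance whose principal
#'   components are score-harmonized, in (0, 1]; default 0.95.
#' @return A `harmonization_result` (same contract as [combat()]).
#' @export
covbat <- function(data, design, var_explained = 0.95) {
  if (var_explained <= 0 || var_explained > 1) stop("var_explained must be in (0, 1]")
  cb <- combat(data, design)
  batch <- design$batch
  E <- cb$adjusted - cb$model$stand_mean
  n <- nrow(E)
  ctr <- colMeans(E)
  Ec <- sweep(E, 2L, ctr)
  sv <- svd(Ec)
  varfrac <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(varfrac >= var_explained - 1e-12)[1L]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # per-batch location/scale standardization of each score to the pooled scale
  n_i <- as.vector(table(batch))
  mu_b <- rowsum(scores, batch) / n_i
  var_b <- (rowsum(scores^2, batch) - n_i * mu_b^2) / (n_i - 1)
  pooled_sd <- apply(scores, 2L, stats::sd)
  adj_scores <- (scores - mu_b[batch, , drop = FALSE]) /
    sqrt(var_b[batch, , drop = FALSE]) * matrix(pooled_sd, n, k, byrow = TRUE)
  Ec_new <- Ec - scores %*% t(sv$v[, seq_len(k), drop = FALSE]) +
    adj_scores %*% t(sv$v[, seq_len(k), drop = FALSE])
  adjusted <- sweep(Ec_new, 2L, ctr, `+`) + cb$model$stand_mean
  dimnames(adjusted) <- dimnames(cb$adjusted)
  out <- cb
  out$adjusted <- adjusted
  out$model$covbat <- list(k = k, var_explained = var_explained)
  out
}

#' Bland-Altman agreement between two per-subject measurements
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List: `bias` (mean of x - y), `lower`/`upper` limits of agreement
#'   (bias -/+ 1.96 SD of differences), `sd_diff`, `fraction_inside`.
#' @export
agreement_bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  lower <- bias - 1.96 * s
  upper <- bias + 1.96 * s
  list(bias = bias, sd_diff = s, lower = lower, upper = upper,
       fraction_inside = mean(d >= lower & d <= upper))
}
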