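# Brain-age modeling on regional-contribution features.
#
# Three linear-kernel regressors — epsilon-insensitive support vector
# regression (C selected by nested grid search), relevance vector regression
# (sparse Bayesian learning by expectation-maximization over a precomputed
# linear kernel), and Gaussian process regression (signal/noise variances by
# marginal-likelihood maximization) — are trained on typically-developing
# controls under age-stratified tenfold cross-validation with repeated
# shuffles, then applied to the patient group. The brain age gap (BrainAGE)
# is predicted minus chronological age; patients are split into delayed
# (DED), premature (PRD) and intermediate development groups by a 0.5-SD rule.

#' Configuration for brain-age model fitting and validation
#'
#' @param model One of `"svr"`, `"rvr"`, `"gpr"`.
#' @param C_grid Strictly positive SVR regularization grid; the default is the
#'   nine-point grid 2^-7, 2^-5, 2^-3, 2^-1, 1, 2, 2^3, 2^5, 2^7.
#' @param n_folds Outer cross-validation folds (default 10).
#' @param n_shuffles Independent re-randomizations of the fold assignment
#'   (default 10).
#' @param n_strata Number of quantile age bins used to stratify folds.
#' @param split_sd_factor Multiplier of the brain-age SD in the DED/PRD rule.
#' @param seed Integer; drives all fold randomization.
#' @return Object of class `brainage_config`.
#' @export
brainage_config <- function(model = c("rvr", "svr", "gpr"),
                            C_grid = 2^c(-7, -5, -3, -1, 0, 1, 3, 5, 7),
                            n_folds = 10L, n_shuffles = 10L, n_strata = 10L,
                            split_sd_factor = 0.5, seed = 1L) {
  model <- match.arg(model)
  if (any(C_grid <= 0)) stop("C_grid must be strictly positive")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (split_sd_factor <= 0) stop("split_sd_factor must be positive")
  structure(list(model = model, C_grid = C_grid, n_folds = as.integer(n_folds),
                 n_shuffles = as.integer(n_shuffles),
                 n_strata = as.integer(n_strata),
                 split_sd_factor = split_sd_factor, seed = as.integer(seed)),
            class = "brainage_config")
}

# ---- feature standardization shared by the three regressors ----------------

standardize_fit <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  list(ctr = ctr, scl = scl,
       Xs = sweep(sweep(X, 2L, ctr), 2L, scl, `/`))
}
standardize_apply <- function(std, X) {
  sweep(sweep(as.matrix(X), 2L, std$ctr), 2L, std$scl, `/`)
}

#' Linear epsilon-insensitive support vector regression
#'
#' Solves the primal problem `0.5 ||w||^2 + C * sum L_eps(y - Xw - b)` with the
#' squared epsilon-insensitive loss (smooth, so L-BFGS-B applies), on
#' standardized features and centered targets. `C` is selected over `C_grid`
#' by inner cross-validated mean absolute error.
#'
#' @param X Feature matrix, no missing values.
#' @param y Numeric target (years).
#' @param C_grid Candidate regularization constants.
#' @param epsilon Insensitivity half-width, target units (default 0.01, small
#'   relative to year-scale targets so the tube does not bias the fit).
#' @param n_inner_folds Inner CV folds for the C search (default 5).
#' @return Object of class `svr_model` with a [predict()] method; element
#'   `C` is the selected constant.
#' @export
fit_svr_linear <- function(X, y, C_grid = 2^c(-7, -5, -3, -1, 0, 1, 3, 5, 7),
                           epsilon = 0.01, n_inner_folds = 5L) {
  X <- as.matrix(X)
  check_no_missing(X, "X"); check_no_missing(y, "y")
  if (nrow(X) < n_inner_folds) stop("n (", nrow(X), ") < folds (", n_inner_folds, ")")
  if (length(C_grid) > 1L) {
    folds <- rep_len(seq_len(n_inner_folds), nrow(X))  # deterministic inner split
    cv_mae <- vapply(C_grid, function(C) {
      errs <- vapply(seq_len(n_inner_folds), function(f) {
        tr <- folds != f
        m <- svr_core(X[tr, , drop = FALSE], y[tr], C, epsilon)
        mean(abs(y[!tr] - predict_svr(m, X[!tr, , drop = FALSE])))
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    C <- C_grid[which.min(cv_mae)]
  } else {
    C <- C_grid
  }
  m <- svr_core(X, y, C, epsilon)
  m$C <- C
  m
}

svr_core <- function(X, y, C, epsilon) {
  std <- standardize_fit(X)
  Xs <- std$Xs
  y_ctr <- mean(y)
  yc <- y - y_ctr
  p <- ncol(Xs); n <- nrow(Xs)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    r <- yc - Xs %*% w - b
    m <- pmax(0, abs(r) - epsilon)
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    r <- as.vector(yc - Xs %*% w - b)
    m <- pmax(0, abs(r) - epsilon)
    g_r <- 2 * m * sign(r)
    c(w - C * as.vector(crossprod(Xs, g_r)), -C * sum(g_r))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500L))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1L], std = std,
                 y_ctr = y_ctr, epsilon = epsilon),
            class = "svr_model")
}

predict_svr <- function(object, newdata) {
  Xs <- standardize_apply(object$std, newdata)
  as.vector(Xs %*% object$w + object$b + object$y_ctr)
}

#' @export
predict.svr_model <- function(object, newdata, ...) predict_svr(object, newdata)

#' Relevance vector regression over a precomputed linear kernel
#'
#' Sparse Bayesian regression (automatic relevance determination): the design
#' is `[1, K]` with `K` the linear Gram matrix of standardized features, each
#' basis function carries its own Gaussian precision hyperparameter, and
#' hyperparameters plus the noise variance are updated by
#' expectation-maximization until the maximum relative change falls below
#' 1e-4 or 500 iterations. Basis functions whose precision exceeds 1e9 are
#' pruned; the surviving training samples are the relevance vectors.
#'
#' @param X Feature matrix.
#' @param y Numeric target.
#' @param max_iter,tol EM iteration cap and relative-change tolerance.
#' @param prune_threshold Precision above which a basis function is removed.
#' @return Object of class `rvr_model` with a [predict()] method; elements
#'   include `relevance` (indices of retained kernel bases) and `weights`.
#' @export
fit_rvr <- function(X, y, max_iter = 500L, tol = 1e-4, prune_threshold = 1e9) {
  X <- as.matrix(X)
  check_no_missing(X, "X"); check_no_missing(y, "y")
  std <- standardize_fit(X)
  Xs <- std$Xs
  n <- nrow(Xs)
  K <- tcrossprod(Xs) / ncol(Xs)
  if (any(!is.finite(K))) stop("non-finite kernel entries")
  y_ctr <- mean(y)
  yc <- y - y_ctr
  Phi <- cbind(1, K)                   # intercept + one basis per training sample
  M <- ncol(Phi)
  alpha <- rep(1, M)
  sigma2 <- max(stats::var(yc) * 0.1, 1e-6)
  keep <- rep(TRUE, M)
  mu_full <- numeric(M)
  solve_spd <- function(M) {
    # near-noiseless fits make M ill-conditioned; escalate jitter until stable
    scale <- mean(diag(M))
    for (e in c(0, 1e-12, 1e-9, 1e-6) * scale) {
      out <- tryCatch(chol2inv(chol(M + diag(e, nrow(M)))), error = function(.) NULL)
      if (!is.null(out)) return(out)
    }
    stop("kernel system could not be factorized")
  }
  for (it in seq_len(max_iter)) {
    Pk <- Phi[, keep, drop = FALSE]
    A <- diag(alpha[keep], sum(keep))
    Sigma <- solve_spd(A + crossprod(Pk) / sigma2)
    mu <- as.vector(Sigma %*% crossprod(Pk, yc)) / sigma2
    gamma <- 1 - alpha[keep] * diag(Sigma)
    alpha_new <- gamma / pmax(mu^2, 1e-300)
    resid <- yc - Pk %*% mu
    sigma2_new <- max(sum(resid^2) / max(n - sum(gamma), 1e-6),
                      1e-9 * stats::var(yc) + 1e-12)
    rel <- max(abs(log(pmax(alpha_new, 1e-300)) - log(pmax(alpha[keep], 1e-300))),
               abs(log(sigma2_new) - log(sigma2)))
    alpha[keep] <- alpha_new
    sigma2 <- sigma2_new
    mu_full[] <- 0; mu_full[keep] <- mu
    keep <- keep & (alpha < prune_threshold)
    if (!any(keep)) { keep[1L] <- TRUE; break }  # degenerate: keep intercept
    if (rel < tol) break
  }
  structure(list(std = std, X_train = Xs, weights = mu_full[keep],
                 relevance = which(keep), sigma2 = sigma2, y_ctr = y_ctr,
                 n_basis_total = M, iterations = it),
            class = "rvr_model")
}

#' @export
predict.rvr_model <- function(object, newdata, ...) {
  Xs <- standardize_apply(object$std, newdata)
  Kstar <- tcrossprod(Xs, object$X_train) / ncol(Xs)
  Phi <- cbind(1, Kstar)[, object$relevance, drop = FALSE]
  as.vector(Phi %*% object$weights + object$y_ctr)
}

#' Gaussian process regression with a linear kernel
#'
#' `K = s2 * X X' / p + n2 * I` on standardized features; the signal and noise
#' variances `(s2, n2)` maximize the log marginal likelihood (optimized on the
#' log scale by L-BFGS-B with Cholesky factorizations, jitter added for
#' duplicate rows). The predictive mean is returned by [predict()].
#'
#' @param X Feature matrix.
#' @param y Numeric target.
#' @return Object of class `gpr_model`; elements `signal_var`, `noise_var`.
#' @export
fit_gpr_linear <- function(X, y) {
  X <- as.matrix(X)
  check_no_missing(X, "X"); check_no_missing(y, "y")
  std <- standardize_fit(X)
  Xs <- std$Xs
  n <- nrow(Xs)
  y_ctr <- mean(y)
  yc <- y - y_ctr
  K0 <- tcrossprod(Xs) / ncol(Xs)
  nlml <- function(par) {
    s2 <- exp(par[1]); n2 <- exp(par[2])
    Kf <- s2 * K0 + diag(n2 + 1e-10, n)
    L <- tryCatch(chol(Kf), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  v <- stats::var(yc) + 1e-12
  fit <- stats::optim(c(log(v), log(v / 2)), nlml, method = "L-BFGS-B",
                      lower = c(log(1e-12), log(1e-10)),
                      upper = c(log(1e8 * v + 1), log(1e4 * v + 1)))
  s2 <- exp(fit$par[1]); n2 <- exp(fit$par[2])
  Kf <- s2 * K0 + diag(n2 + 1e-10, n)
  L <- tryCatch(chol(Kf), error = function(e) chol(Kf + diag(1e-6, n)))
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(std = std, X_train = Xs, alpha = alpha, signal_var = s2,
                 noise_var = n2, y_ctr = y_ctr),
            class = "gpr_model")
}

#' @export
predict.gpr_model <- function(object, newdata, ...) {
  Xs <- standardize_apply(object$std, newdata)
  Kstar <- object$signal_var * tcrossprod(Xs, object$X_train) / ncol(Xs)
  as.vector(Kstar %*% object$alpha + object$y_ctr)
}

fit_brainage_model <- function(X, y, config) {
  switch(config$model,
         svr = fit_svr_linear(X, y, C_grid = config$C_grid),
         rvr = fit_rvr(X, y),
         gpr = fit_gpr_linear(X, y))
}

#' Age-stratified fold assignment
#'
#' Subjects are binned into `n_strata` age quantile bins and assigned to folds
#' round-robin within a random permutation of each bin, so each fold's age
#' distribution tracks the sample's.
#'
#' @param age Numeric vector.
#' @param n_folds Folds.
#' @param n_strata Quantile bins (merged automatically if sparsely populated).
#' @param seed Integer seed for the within-bin permutation.
#' @return Integer fold id per subject (1..n_folds); each fold non-empty.
#' @export
stratified_folds <- function(age, n_folds = 10L, n_strata = 10L, seed = 1L) {
  n <- length(age)
  if (n < n_folds) stop("fewer subjects (", n, ") than folds (", n_folds, ")")
  n_strata <- max(1L, min(n_strata, floor(n / n_folds)))
  br <- unique(stats::quantile(age, probs = seq(0, 1, length.out = n_strata + 1L)))
  bins <- cut(age, breaks = br, include.lowest = TRUE, labels = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (b in sort(unique(bins))) {
      idx <- sample(which(bins == b))
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Cross-validated brain-age estimation
#'
#' For each of `n_shuffles` re-randomizations: NCs (typically developing
#' controls) are split into `n_folds` age-stratified folds; per fold, the
#' model is trained on the remaining folds (SVR's C selected by nested inner
#' CV on the training folds only), the held-out NCs are predicted once, and
#' all patients are predicted by every fold model. Per-shuffle validation
#' metrics (Spearman rho of predicted vs chronological age, MAE, RMSE) pool
#' the folds of that shuffle. Final brain age is the mean prediction over
#' shuffles (NC: over the shuffles' held-out predictions; patients: over all
#' fold models and shuffles), and BrainAGE is brain age minus chronological
#' age.
#'
#' @param nc_X,nc_age Control features and ages (aligned).
#' @param asd_X,asd_age Patient features and ages; may be NULL.
#' @param config A [brainage_config()].
#' @return List of class `brainage_result`: `performance` (per-shuffle rho /
#'   mae / rmse data.frame plus mean/sd summary rows in `summary`), `nc` and
#'   `asd` data.frames (age, brain_age, gap), `folds` (subject x shuffle fold
#'   assignment for leakage audits), `config`.
#' @export
cross_validated_brainage <- function(nc_X, nc_age, asd_X = NULL, asd_age = NULL,
                                     config = brainage_config()) {
  nc_X <- as.matrix(nc_X)
  stopifnot(nrow(nc_X) == length(nc_age))
  has_asd <- !is.null(asd_X)
  if (has_asd) {
    asd_X <- as.matrix(asd_X)
    stopifnot(nrow(asd_X) == length(asd_age))
  }
  n_nc <- nrow(nc_X)
  pred_nc <- matrix(NA_real_, n_nc, config$n_shuffles)
  pred_asd <- if (has_asd) matrix(0, nrow(asd_X), config$n_shuffles)
  fold_matrix <- matrix(NA_integer_, n_nc, config$n_shuffles)
  perf <- data.frame(shuffle = seq_len(config$n_shuffles), rho = NA_real_,
                     mae = NA_real_, rmse = NA_real_)
  for (s in seq_len(config$n_shuffles)) {
    folds <- stratified_folds(nc_age, config$n_folds, config$n_strata,
                              seed = derive_seed(config$seed, paste0("shuffle", s)))
    fold_matrix[, s] <- folds
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      model <- fit_brainage_model(nc_X[tr, , drop = FALSE], nc_age[tr], config)
      pred_nc[!tr, s] <- predict(model, nc_X[!tr, , drop = FALSE])
      if (has_asd) {
        pred_asd[, s] <- pred_asd[, s] +
          predict(model, asd_X) / config$n_folds
      }
    }
    perf$rho[s] <- stats::cor(pred_nc[, s], nc_age, method = "spearman")
    perf$mae[s] <- mean(abs(pred_nc[, s] - nc_age))
    perf$rmse[s] <- sqrt(mean((pred_nc[, s] - nc_age)^2))
  }
  nc_brain_age <- rowMeans(pred_nc)
  nc <- data.frame(age = nc_age, brain_age = nc_brain_age,
                   gap = nc_brain_age - nc_age)
  asd <- NULL
  if (has_asd) {
    asd_brain_age <- rowMeans(pred_asd)
    asd <- data.frame(age = asd_age, brain_age = asd_brain_age,
                      gap = asd_brain_age - asd_age)
  }
  structure(list(
    performance = perf,
    summary = data.frame(metric = c("rho", "mae", "rmse"),
                         mean = c(mean(perf$rho), mean(perf$mae), mean(perf$rmse)),
                         sd = c(stats::sd(perf$rho), stats::sd(perf$mae),
                                stats::sd(perf$rmse))),
    nc = nc, asd = asd, folds = fold_matrix, predictions_nc = pred_nc,
    config = config), class = "brainage_result")
}

#' Pairwise paired t-tests on per-shuffle MAE of competing models
#'
#' @param ... Two or more named per-shuffle MAE vectors (equal length, matched
#'   by shuffle), or `brainage_result` objects.
#' @param alpha Family-wise level; the Bonferroni-adjusted threshold is
#'   `alpha / n_pairs`.
#' @return data.frame: model_a, model_b, mean_diff, statistic, p, significant;
#'   attribute `threshold`.
#' @export
compare_models_mae <- function(..., alpha = 0.05) {
  args <- list(...)
  maes <- lapply(args, function(a) {
    if (inherits(a, "brainage_result")) a$performance$mae else as.numeric(a)
  })
  nm <- names(maes)
  if (is.null(nm) || any(nm == "")) nm <- paste0("model_", seq_along(maes))
  lens <- lengths(maes)
  if (length(unique(lens)) != 1L) stop("per-shuffle MAE vectors must be matched in length")
  pairs <- utils::combn(seq_along(maes), 2L)
  thr <- alpha / ncol(pairs)
  rows <- apply(pairs, 2L, function(pr) {
    d <- maes[[pr[1]]] - maes[[pr[2]]]
    if (stats::sd(d) < 1e-12) {
      if (abs(mean(d)) < 1e-12) {
        st <- 0; p <- 1
      } else {                      # constant nonzero offset: exact difference
        st <- Inf * sign(mean(d)); p <- 0
      }
    } else {
      tt <- stats::t.test(d)
      st <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(model_a = nm[pr[1]], model_b = nm[pr[2]], mean_diff = mean(d),
               statistic = st, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  out
}

#' Split patients into delayed / premature development groups
#'
#' With `SD` the standard deviation of `brain_age` over the supplied (patient)
#' sample: DED (delayed) iff `brain_age + sd_factor * SD < age`; PRD
#' (premature) iff `brain_age - sd_factor * SD > age`; otherwise `neither`
#' (the band where predicted and chronological age agree to within the rule's
#' margin).
#'
#' @param brain_age,age Numeric vectors (years), equal length >= 2.
#' @param sd_factor Multiplier of SD, default 0.5.
#' @return data.frame: age, brain_age, gap, dev_label (factor DED/PRD/neither);
#'   attribute `sd_brain_age`.
#' @export
split_ded_prd <- function(brain_age, age, sd_factor = 0.5) {
  if (length(brain_age) != length(age)) stop("length mismatch")
  if (length(age) < 2L) stop("need >= 2 subjects to compute SD")
  s <- stats::sd(brain_age)
  if (s < 1e-12) {
    warning("zero SD of brain age: all subjects labeled 'neither'")
    lab <- rep("neither", length(age))
  } else {
    lab <- ifelse(brain_age + sd_factor * s < age, "DED",
                  ifelse(brain_age - sd_factor * s > age, "PRD", "neither"))
  }
  out <- data.frame(age = age, brain_age = brain_age, gap = brain_age - age,
                    dev_label = factor(lab, levels = c("DED", "PRD", "neither")))
  attr(out, "sd_brain_age") <- s
  out
}

#' Cognition comparisons between the DED and PRD groups
#'
#' Runs [compare_groups()] (age and sex covariates) for each cognition score
#' between the delayed- and premature-development subgroups.
#'
#' @param split A [split_ded_prd()] data.frame.
#' @param phenotypes data.frame aligned with `split` rows, carrying `age`,
#'   `sex` and the score columns.
#' @param scores Score column names (default FIQ plus the three ADI-R
#'   subscores).
#' @return data.frame: score, n_ded, n_prd, statistic, p, test.
#' @export
compare_ded_prd_cognition <- function(split, phenotypes,
                                      scores = c("fiq", "adi_rrb", "adi_soc", "adi_ver")) {
  stopifnot(nrow(split) == nrow(phenotypes))
  sel <- split$dev_label %in% c("DED", "PRD")
  if (!any(split$dev_label == "DED") || !any(split$dev_label == "PRD")) {
    stop("both DED and PRD groups must be non-empty")
  }
  lab <- droplevels(split$dev_label[sel])
  covs <- cbind(age = phenotypes$age[sel], sex = as.numeric(phenotypes$sex[sel]))
  rows <- lapply(scores, function(sc) {
    cmp <- compare_groups(phenotypes[[sc]][sel], lab, covs)
    data.frame(score = sc, n_ded = sum(lab == "DED"), n_prd = sum(lab == "PRD"),
               statistic = cmp$statistic, p = cmp$p.value, test = cmp$test,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove site means from chronological age
#'
#' Residualizes age on site indicators and adds the grand mean back; used as
#' an alternative training target in the site-sensitivity rerun.
#'
#' @param age Numeric vector (years).
#' @param site Site label per subject.
#' @return Adjusted age vector, same length.
#' @export
site_residualized_age <- function(age, site) {
  site <- factor(site)
  if (nlevels(site) < 2L) {
    warning("single site: age returned unchanged")
    return(age)
  }
  stats::lm.fit(stats::model.matrix(~ site), age)$residuals + mean(age)
}
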