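# Person-based similarity index (PBSI) and leave-one-region-out regional
# contributions.
#
# The PBSI of a subject is the mean Spearman correlation between that
# subject's regional volume profile and every other same-group subject's
# profile: high values mean the subject's morphometric profile is typical of
# the group, low values mean it is atypical. Removing one region at a time
# and recomputing (with full re-ranking of the reduced profiles) measures how
# much each region carries the inter-individual similarity.

#' Pairwise Spearman correlations between subjects' regional profiles
#'
#' Each subject's profile is rank-transformed across regions (average ranks on
#' ties) and subjects are correlated pairwise (Pearson on ranks, which equals
#' Spearman's rho).
#'
#' @param profiles Subject x region numeric matrix (>= 2 subjects, >= 2
#'   regions), no missing values.
#' @return Symmetric subject x subject correlation matrix with unit diagonal.
#' @export
pairwise_spearman <- function(profiles) {
  profiles <- as.matrix(profiles)
  check_no_missing(profiles, "profiles")
  if (nrow(profiles) < 2L || ncol(profiles) < 2L) {
    stop("need at least 2 subjects and 2 regions")
  }
  ranks <- t(apply(profiles, 1L, rank, ties.method = "average"))
  rv <- apply(ranks, 1L, stats::var)
  if (any(rv == 0)) {
    stop("constant profile (rank correlation undefined) for subject(s): ",
         paste(utils::head(rownames(profiles)[rv == 0], 5L), collapse = ", "))
  }
  rc <- ranks - rowMeans(ranks)
  rc <- rc / sqrt(rowSums(rc^2))
  m <- tcrossprod(rc)
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  dimnames(m) <- list(rownames(profiles), rownames(profiles))
  m
}

#' PBSI scores from a pairwise correlation matrix
#'
#' The score of subject s is the mean of row s excluding the diagonal — the
#' average similarity of s to every other member of the same group.
#'
#' @param corr Symmetric subject x subject correlation matrix with unit
#'   diagonal, n >= 2.
#' @return Named numeric vector of per-subject scores in `[-1, 1]`.
#' @export
compute_pbsi <- function(corr) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 2L || ncol(corr) != n) stop("corr must be square with n >= 2")
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("corr must have unit diagonal")
  if (n == 2L) warning("PBSI over a group of 2: each score is a single correlation")
  scores <- (rowSums(corr) - 1) / (n - 1)
  names(scores) <- rownames(corr)
  scores
}

#' PBSI scores straight from a profile matrix
#'
#' Convenience wrapper: [pairwise_spearman()] then [compute_pbsi()]. Should be
#' applied strictly within one diagnostic group.
#'
#' @inheritParams pairwise_spearman
#' @return Named numeric vector of PBSI scores.
#' @export
pbsi_scores <- function(profiles) compute_pbsi(pairwise_spearman(profiles))

#' Leave-one-region-out contributions to the PBSI
#'
#' For each region i the PBSI of every subject is recomputed on the profile
#' with region i removed (ranks fully recomputed on the reduced profile), and
#' the contribution is `|PBSI(all) - PBSI(without i)|`.
#'
#' @inheritParams pairwise_spearman
#' @return Subject x region matrix of non-negative contributions.
#' @export
regional_contributions <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3L) stop("need at least 3 regions for leave-one-out")
  full <- pbsi_scores(profiles)
  out <- matrix(NA_real_, nrow(profiles), ncol(profiles),
                dimnames = dimnames(profiles))
  for (i in seq_len(ncol(profiles))) {
    out[, i] <- abs(full - suppressWarnings(pbsi_scores(profiles[, -i, drop = FALSE])))
  }
  out
}

#' Group-mean contributions and the patient-minus-control delta map
#'
#' @param contrib Subject x region contribution matrix.
#' @param group Two-level group label per subject.
#' @param case_level Level treated as the case group for `delta = mean(case) -
#'   mean(control)`; defaults to `"ASD"` if present, else the first level.
#' @return List: `group_means` (group x region), `delta` (named vector over
#'   regions), `case_level`.
#' @export
contribution_delta <- function(contrib, group, case_level = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (is.null(case_level)) {
    case_level <- if ("ASD" %in% levels(group)) "ASD" else levels(group)[1L]
  }
  ctrl_level <- setdiff(levels(group), case_level)
  gm <- rowsum(as.matrix(contrib), group) / as.vector(table(group))
  delta <- gm[case_level, ] - gm[ctrl_level, ]
  names(delta) <- colnames(contrib)
  list(group_means = gm, delta = delta, case_level = case_level)
}

#' Ordinary-least-squares residualization on covariates
#'
#' @param values Numeric vector.
#' @param covariates Covariates (vector/matrix/data.frame) or NULL for
#'   intercept-only centering.
#' @return Residual vector (mean ~ 0).
#' @export
residualize <- function(values, covariates = NULL) {
  X <- covariate_matrix(covariates, length(values))
  stats::lm.fit(X, values)$residuals
}

#' Covariate-adjusted two-group comparison with distribution-based test choice
#'
#' Values are residualized on the covariates (pooled fit), then a Shapiro-Wilk
#' normality check at alpha = 0.05 per group selects the test: two-sample
#' Student's t if both groups pass, Wilcoxon rank-sum otherwise. Degenerate
#' inputs (zero residual variance) are reported with p = 1.
#'
#' @param values Numeric vector.
#' @param group Two-level label per value.
#' @param covariates Covariates to adjust for, or NULL.
#' @return List of class `group_comparison`: `statistic`, `p.value`, `test`
#'   (`"t"`, `"wilcoxon"` or `"degenerate"`), `covariates_applied`, group
#'   means of residuals.
#' @export
compare_groups <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required, got ", nlevels(group))
  if (any(table(group) < 3L)) stop("each group needs n >= 3")
  keep <- !is.na(values)
  values <- values[keep]; group <- droplevels(group[keep])
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  res <- residualize(values, covariates)
  a <- res[group == levels(group)[1L]]
  b <- res[group == levels(group)[2L]]
  if (stats::sd(res) < 1e-12) {
    out <- list(statistic = 0, p.value = 1, test = "degenerate")
  } else {
    normal <- function(x) {
      if (length(unique(x)) < 3L) return(FALSE)
      n <- length(x)
      if (n > 5000L) x <- sample(x, 5000L)
      stats::shapiro.test(x)$p.value > 0.05
    }
    if (normal(a) && normal(b)) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      out <- list(statistic = unname(tt$statistic), p.value = tt$p.value, test = "t")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      out <- list(statistic = unname(wt$statistic), p.value = wt$p.value,
                  test = "wilcoxon")
    }
  }
  out$group_means <- tapply(res, group, mean)
  out$covariates_applied <- !is.null(covariates) && ncol(covariates) > 0L
  class(out) <- "group_comparison"
  out
}

#' Region-wise group differences in contributions with Bonferroni control
#'
#' Runs [compare_groups()] per region (age and sex as covariates, per the
#' standard design) and flags regions with raw p below `alpha / n_regions`.
#'
#' @param contrib Subject x region contribution matrix.
#' @param group Two-level label per subject.
#' @param covariates Covariates to adjust for (typically age, sex), or NULL.
#' @param alpha Family-wise level, default 0.05.
#' @return data.frame: region, statistic, p, p_bonferroni, test, significant;
#'   attribute `threshold` = alpha / n_regions.
#' @export
regionwise_group_difference <- function(contrib, group, covariates = NULL,
                                        alpha = 0.05) {
  contrib <- as.matrix(contrib)
  R <- ncol(contrib)
  thr <- alpha / R
  rows <- lapply(seq_len(R), function(i) {
    cmp <- compare_groups(contrib[, i], group, covariates)
    data.frame(region = colnames(contrib)[i], statistic = cmp$statistic,
               p = cmp$p.value, test = cmp$test, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * R, 1)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  out
}

#' Spearman correlation between two vectors after covariate residualization
#'
#' Both vectors are residualized on the covariates (empty covariates allowed,
#' e.g. for the PBSI-age analysis), then Spearman's rho with a two-sided p is
#' computed (exact null distribution for small tie-free samples, t
#' approximation otherwise, as in [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, equal length >= 5.
#' @param covariates Covariates or NULL.
#' @return List: `rho`, `p.value`, `n`.
#' @export
correlate_with_covariates <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  if (length(x) < 5L) stop("need at least 5 paired observations")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop("constant residuals: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(rx, ry, method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
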