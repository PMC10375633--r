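# Synthetic cohorts and expression matrices with known ground truth.
#
# The generator emulates the statistical structure a multi-site pediatric
# morphometry study presents to the analysis code: regional gray-matter
# volumes with linear age/sex/TIV effects, additive + multiplicative site
# (batch) effects, and group-dependent subject-level heterogeneity in which
# the patient group deviates more from the common profile than controls, with
# a deviation scale that grows with age.

#' Specify a synthetic two-group, multi-site morphometry cohort
#'
#' Volumes follow the generative model
#' `v[s, r] = mu[r] + beta_age[r] * age[s] + beta_sex[r] * sex[s] +
#'  beta_tiv[r] * tiv[s] + shift[site(s), r] + scale[site(s), r] * eps[s, r]`
#' with `eps[s, r] ~ N(0, (het_sd_group(s) + het_age_slope * (age[s] - age_min))^2)`.
#' Subject-level deviations `eps` carry the inter-individual heterogeneity the
#' person-based similarity index is sensitive to; `het_sd_asd > het_sd_nc`
#' plants greater heterogeneity in the patient group.
#'
#' @param n_per_group Subjects per diagnostic group (ASD and NC).
#' @param n_regions Even number of cortical parcels (default 360, 180 per
#'   hemisphere).
#' @param n_sites Number of acquisition sites.
#' @param age_range Two-element numeric, years; ages drawn uniformly.
#' @param site_shift_sd SD of additive per-(site, region) offsets, volume units.
#' @param site_scale_sd Log-scale SD of multiplicative per-(site, region)
#'   effects, `scale = exp(N(0, site_scale_sd))` so scales are positive.
#' @param beta_age Age slope per region, volume/year; scalar or length
#'   `n_regions` (gray matter volume shrinks with age in this age range, so the
#'   default is negative).
#' @param beta_sex,beta_tiv Effect sizes for sex (0/1 coded) and total
#'   intracranial volume (mm^3).
#' @param het_sd_nc,het_sd_asd Subject-deviation SDs per group, volume units.
#' @param het_age_slope Increase of the deviation SD per year of age.
#' @param seed Integer; the same spec + seed reproduces the cohort exactly.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100L,
                        n_regions = 360L,
                        n_sites = 4L,
                        age_range = c(5, 20),
                        site_shift_sd = 5,
                        site_scale_sd = 0.1,
                        beta_age = -1.5,
                        beta_sex = 5,
                        beta_tiv = 2e-4,
                        het_sd_nc = 15,
                        het_sd_asd = 25,
                        het_age_slope = 0.5,
                        seed = 1L) {
  if (n_per_group < 1L) stop("invalid spec: n_per_group must be positive")
  if (n_regions < 2L) stop("invalid spec: n_regions must be positive and even")
  if (n_regions %% 2L != 0L) stop("invalid spec: n_regions must be even")
  if (n_sites < 1L) stop("invalid spec: n_sites must be positive")
  if (length(age_range) != 2L || age_range[2] <= age_range[1]) {
    stop("invalid spec: age_range must be (min, max) with min < max")
  }
  if (!length(beta_age) %in% c(1L, n_regions)) {
    stop("beta_age must be scalar or length n_regions")
  }
  if (het_sd_asd < het_sd_nc) {
    warning("het_sd_asd < het_sd_nc: patient group planted as LESS heterogeneous than controls")
  }
  structure(list(
    n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
    n_sites = as.integer(n_sites), age_range = as.numeric(age_range),
    site_shift_sd = site_shift_sd, site_scale_sd = site_scale_sd,
    beta_age = beta_age, beta_sex = beta_sex, beta_tiv = beta_tiv,
    het_sd_nc = het_sd_nc, het_sd_asd = het_sd_asd,
    het_age_slope = het_age_slope, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort from a specification
#'
#' Draws phenotypes (age uniform over `age_range`, sex Bernoulli(0.8) male to
#' mirror the male-skewed composition typical of autism cohorts, TIV
#' log-normal around 1.5e6 mm^3, site uniform, FIQ and ADI-R subscores) and
#' regional volumes from the generative model documented in [cohort_spec()].
#' ADI-R scores are produced only for the ASD group (NA for controls), as in
#' the instruments they emulate.
#'
#' All planted quantities (regional baselines, slopes, site effects, and the
#' full subject-by-region deviation matrix `eps`) are returned in `$truth`, so
#' `profiles` can be reconstructed exactly and recovery tests have ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `profiles`
#'   (subject x region numeric matrix with region-label columns), `phenotypes`
#'   (data.frame: subject_id, age, sex, site, tiv, dx, fiq, adi_rrb, adi_soc,
#'   adi_ver) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_group
  R <- spec$n_regions
  labels <- make_region_labels(R)
  beta_age <- rep_len(spec$beta_age, R)

  with_seed(spec$seed, {
    mu <- rnorm(R, mean = 600, sd = 60)
    beta_sex <- rep_len(spec$beta_sex, R)
    beta_tiv <- rep_len(spec$beta_tiv, R)
    shift <- matrix(rnorm(spec$n_sites * R, 0, spec$site_shift_sd), spec$n_sites, R)
    scale <- matrix(exp(rnorm(spec$n_sites * R, 0, spec$site_scale_sd)), spec$n_sites, R)

    dx <- rep(c("ASD", "NC"), each = spec$n_per_group)
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- rbinom(n, 1L, 0.8)
    tiv <- exp(rnorm(n, log(1.5e6), 0.08))
    site <- sample.int(spec$n_sites, n, replace = TRUE)
    fiq <- ifelse(dx == "ASD", rnorm(n, 105.6, 17.1), rnorm(n, 113.0, 12.7))
    adi_rrb <- ifelse(dx == "ASD", pmax(0, rnorm(n, 6, 2.5)), NA_real_)
    adi_soc <- ifelse(dx == "ASD", pmax(0, rnorm(n, 20, 5.5)), NA_real_)
    adi_ver <- ifelse(dx == "ASD", pmax(0, rnorm(n, 16, 4.4)), NA_real_)

    het_sd <- ifelse(dx == "ASD", spec$het_sd_asd, spec$het_sd_nc) +
      spec$het_age_slope * (age - spec$age_range[1])
    eps <- matrix(rnorm(n * R), n, R) * het_sd

    signal <- matrix(mu, n, R, byrow = TRUE) +
      outer(age, beta_age) + outer(as.numeric(sex), beta_sex) + outer(tiv, beta_tiv) +
      shift[site, , drop = FALSE]
    profiles <- signal + scale[site, , drop = FALSE] * eps
    dimnames(profiles) <- list(sprintf("sub_%04d", seq_len(n)), labels)

    phenotypes <- data.frame(
      subject_id = rownames(profiles), age = age, sex = sex, site = site,
      tiv = tiv, dx = dx, fiq = fiq, adi_rrb = adi_rrb, adi_soc = adi_soc,
      adi_ver = adi_ver, stringsAsFactors = FALSE
    )
    truth <- list(
      mu = mu, beta_age = beta_age, beta_sex = beta_sex, beta_tiv = beta_tiv,
      site_shift = shift, site_scale = scale, eps = eps, het_sd = het_sd,
      het_sd_nc = spec$het_sd_nc, het_sd_asd = spec$het_sd_asd
    )
    structure(list(profiles = profiles, phenotypes = phenotypes, truth = truth,
                   spec = spec), class = "synthetic_cohort")
  })
}

#' Reconstruct profiles from a cohort's stored ground truth
#'
#' Rebuilds the volume matrix from the planted effects; by construction
#' `reconstruct_profiles(cohort) == cohort$profiles` exactly, which recovery
#' tests assert.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Subject x region matrix.
#' @export
reconstruct_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  ph <- cohort$phenotypes
  n <- nrow(ph)
  out <- matrix(tr$mu, n, length(tr$mu), byrow = TRUE) +
    outer(ph$age, tr$beta_age) + outer(as.numeric(ph$sex), tr$beta_sex) +
    outer(ph$tiv, tr$beta_tiv) + tr$site_shift[ph$site, , drop = FALSE] +
    tr$site_scale[ph$site, , drop = FALSE] * tr$eps
  dimnames(out) <- dimnames(cohort$profiles)
  out
}

#' Specify a synthetic gene-by-region expression matrix
#'
#' @param n_genes Total genes.
#' @param n_planted Genes with a true spatial association to the target map.
#' @param rho_target Target absolute Spearman correlation of planted genes with
#'   the target map, in (0, 1].
#' @param noise_sd SD of the null genes' expression values.
#' @param seed Integer seed.
#' @return Object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 500L, n_planted = 25L, rho_target = 0.6,
                            noise_sd = 1, seed = 1L) {
  if (n_planted > n_genes) stop("n_planted must be <= n_genes")
  if (rho_target <= 0 || rho_target > 1) stop("rho_target must be in (0, 1]")
  structure(list(n_genes = as.integer(n_genes), n_planted = as.integer(n_planted),
                 rho_target = rho_target, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "expression_spec")
}

#' Generate expression with a planted subset spatially tied to a target map
#'
#' Planted genes mix the normal scores of `delta_map`'s ranks with independent
#' Gaussian noise at a mixing weight `2 * sin(pi * rho_target / 6)` — the
#' bivariate-normal inversion of Spearman's rho — so their expected |Spearman
#' correlation| with `delta_map` is approximately `rho_target`
#' (exactly 1 when `rho_target = 1`, where the noise weight vanishes).
#' Remaining genes are exchangeable `N(0, noise_sd)` noise.
#'
#' @param spec An [expression_spec()].
#' @param delta_map Numeric vector over regions (must not be constant).
#' @return List with `expression` (gene x region matrix, rownames gene ids,
#'   colnames from `delta_map` names if present) and `planted` (gene ids with a
#'   true association).
#' @export
generate_expression <- function(spec, delta_map) {
  stopifnot(inherits(spec, "expression_spec"))
  if (length(unique(delta_map)) < 2L) {
    stop("degenerate target: delta_map is constant")
  }
  R <- length(delta_map)
  # normal scores of the target ranks: any monotone transform preserves Spearman
  z <- qnorm((rank(delta_map, ties.method = "average") - 0.5) / R)
  z <- z / stats::sd(z)
  rho_p <- 2 * sin(pi * spec$rho_target / 6)
  with_seed(spec$seed, {
    gene_ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
    planted_idx <- if (spec$n_planted > 0L) seq_len(spec$n_planted) else integer(0)
    expr <- matrix(rnorm(spec$n_genes * R, 0, spec$noise_sd), spec$n_genes, R)
    for (g in planted_idx) {
      sign_g <- if (g %% 2L == 0L) -1 else 1  # plant both directions
      expr[g, ] <- sign_g * (rho_p * z + sqrt(1 - rho_p^2) * rnorm(R))
    }
    dimnames(expr) <- list(gene_ids, names(delta_map))
    list(expression = expr, planted = gene_ids[planted_idx])
  })
}

#' Simulate feature matrices with a known linear age signal
#'
#' Builds `n_features` features that all load on one noisy age surrogate
#' `s = age + e`, with `Var(e)` chosen so the population R^2 of the best
#' predictor of age from the features equals `r2`. The irreducible residual SD
#' is then `sd(age) * sqrt(1 - r2)` and the minimal achievable mean absolute
#' error is `resid_sd * sqrt(2 / pi)` (Gaussian residual), both returned so
#' regression benchmarks can compare against the noise-implied floor.
#'
#' @param n Subjects.
#' @param n_features Features (columns).
#' @param r2 Population R^2 of age on the latent surrogate.
#' @param age_range Years, uniform draw.
#' @param seed Integer seed.
#' @return List: `X`, `age`, `resid_sd`, `mae_floor`.
#' @export
simulate_age_features <- function(n, n_features = 20L, r2 = 0.8,
                                  age_range = c(5, 20), seed = 1L) {
  stopifnot(n >= 2L, n_features >= 1L, r2 > 0, r2 <= 1)
  var_age <- diff(age_range)^2 / 12
  var_e <- var_age * (1 / r2 - 1)
  with_seed(seed, {
    age <- runif(n, age_range[1], age_range[2])
    s <- age + rnorm(n, 0, sqrt(var_e))
    loadings <- runif(n_features, 0.5, 1.5)
    X <- outer(s, loadings) + matrix(rnorm(n * n_features, 0, 0.05), n, n_features)
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    resid_sd <- sqrt(var_age * (1 - r2))
    list(X = X, age = age, resid_sd = resid_sd, mae_floor = resid_sd * sqrt(2 / pi))
  })
}
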