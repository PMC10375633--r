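# Internal helpers shared across modules.

#' Region labels for a two-hemisphere parcellation
#'
#' Builds hemisphere-tagged labels `L_1..L_k, R_1..R_k` for an even number of
#' cortical parcels split equally between hemispheres.
#'
#' @param n_regions Even total number of regions.
#' @return Character vector of length `n_regions`.
#' @export
make_region_labels <- function(n_regions) {
  if (n_regions %% 2L != 0L) {
    stop("n_regions must be even (equal split across hemispheres), got ", n_regions)
  }
  k <- n_regions / 2L
  c(paste0("L_", seq_len(k)), paste0("R_", seq_len(k)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage tag, staying < 2^31.
derive_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Coerce covariates (NULL, vector, matrix or data.frame) to a numeric model
# matrix with intercept; errors on rank deficiency.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    X <- matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  if (is.vector(covariates) && !is.list(covariates)) covariates <- matrix(covariates, ncol = 1L)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) {
    stop("covariate rows (", nrow(covariates), ") do not match observations (", n, ")")
  }
  X <- cbind(`(Intercept)` = 1, covariates)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient after adding intercept")
  X
}

check_no_missing <- function(x, what) {
  if (anyNA(x) || any(!is.finite(as.matrix(x)))) {
    stop(what, " contains missing or non-finite values")
  }
  invisible(TRUE)
}
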