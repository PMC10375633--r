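# Region-level expression processing and transcription-neuroimaging
# association.
#
# Donor-brain microarray samples carry stereotaxic (MNI, mm) coordinates;
# samples are assigned to cortical parcels by nearest-voxel distance (<= 3 mm),
# expression is averaged per parcel, and each gene's spatial profile is
# correlated (Spearman) with the patient-minus-control map of regional
# contributions, with Benjamini-Hochberg FDR control across genes.

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust normalization of one gene's values: a sigmoid of the
#' median/IQR-standardized values (IQR scaled by 1.35 to estimate the SD),
#' min-max rescaled to the unit interval.
#'
#' @param x Numeric vector, length >= 3, with positive IQR.
#' @return Vector in `[0, 1]`, same length.
#' @export
srs_normalize <- function(x) {
  if (length(x) < 3L) stop("need at least 3 values")
  iqr <- stats::IQR(x)
  if (iqr <= 0) stop("degenerate distribution: zero IQR")
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Assign samples to parcellation regions by nearest-voxel distance
#'
#' A sample is assigned to the region whose nearest voxel lies within
#' `max_distance` mm (boundary inclusive); nearest-region ties go to the
#' region earlier in `region_voxels`' order; samples farther than
#' `max_distance` from every region stay unassigned (NA).
#'
#' @param coords Sample x 3 matrix of coordinates (mm).
#' @param region_voxels Named list: region label -> voxel coordinate matrix
#'   (k x 3).
#' @param max_distance Inclusion radius in mm, default 3.
#' @return data.frame: sample (row index or rowname), region (NA if
#'   unassigned), distance (mm to the nearest voxel of the assigned region).
#' @export
assign_samples_to_regions <- function(coords, region_voxels, max_distance = 3) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  check_no_missing(coords, "coords")
  if (length(region_voxels) == 0L) stop("empty region set")
  labels <- names(region_voxels)
  if (is.null(labels)) stop("region_voxels must be a named list")
  n <- nrow(coords)
  dmin <- matrix(Inf, n, length(region_voxels))
  for (j in seq_along(region_voxels)) {
    V <- as.matrix(region_voxels[[j]])
    stopifnot(ncol(V) == 3L, nrow(V) >= 1L)
    # squared distances sample x voxel without forming loops in R
    cross <- coords %*% t(V)
    d2 <- outer(rowSums(coords^2), rowSums(V^2), `+`) - 2 * cross
    dmin[, j] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  best <- apply(dmin, 1L, which.min)  # ties -> lowest index, deterministic
  bestd <- dmin[cbind(seq_len(n), best)]
  region <- ifelse(bestd <= max_distance, labels[best], NA_character_)
  data.frame(sample = if (!is.null(rownames(coords))) rownames(coords) else seq_len(n),
             region = region,
             distance = ifelse(is.na(region), NA_real_, bestd),
             stringsAsFactors = FALSE)
}

#' Average sample expression within each region
#'
#' @param expr Sample x gene numeric matrix.
#' @param assignment Region label per sample (NA = unassigned, dropped).
#' @return List: `expression` (gene x region matrix, regions with >= 1 sample),
#'   `empty_regions` (labels seen in `levels(assignment)` with no samples).
#' @export
aggregate_region_expression <- function(expr, assignment) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == length(assignment))
  keep <- !is.na(assignment)
  f <- factor(assignment[keep])
  sums <- rowsum(expr[keep, , drop = FALSE], f)
  means <- sums / as.vector(table(f))
  declared <- if (is.factor(assignment)) levels(assignment)
              else unique(assignment[keep])
  list(expression = t(means),
       empty_regions = setdiff(declared, levels(f)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` over the sorted p-values, capped at
#' 1; rejections at `q < threshold` coincide with the classical step-up rule.
#'
#' @param p P-values in `[0, 1]`.
#' @param threshold Rejection threshold on q, default 0.05.
#' @return List: `q` (same order as `p`), `rejected` (logical).
#' @export
bh_fdr <- function(p, threshold = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q <- pmax(q, p)  # guard against floating-point dips below p at j = m
  list(q = q, rejected = q < threshold)
}

#' Gene-wise spatial association with a regional delta map
#'
#' Per gene: Spearman correlation (two-sided p) between the gene's regional
#' expression profile and the delta map over their common regions, followed by
#' BH-FDR across genes.
#'
#' @param delta Named numeric vector over regions (non-constant).
#' @param expr Gene x region matrix with region-label columns.
#' @param fdr_threshold Significance threshold on q, default 0.05.
#' @param min_regions Minimum common regions, default 10.
#' @return data.frame of class `association_result`: gene_id, rho, p, q,
#'   significant; attribute `regions_used`.
#' @export
associate_delta_expression <- function(delta, expr, fdr_threshold = 0.05,
                                       min_regions = 10L) {
  expr <- as.matrix(expr)
  if (is.null(names(delta)) || is.null(colnames(expr))) {
    if (length(delta) == ncol(expr)) {
      common <- seq_along(delta)
      dsub <- delta; esub <- expr
    } else stop("unnamed inputs of different width: cannot align regions")
  } else {
    common <- intersect(names(delta), colnames(expr))
    if (length(common) < min_regions) {
      stop("only ", length(common), " common regions (need >= ", min_regions,
           "); unmatched: ",
           paste(utils::head(setdiff(names(delta), colnames(expr)), 5L), collapse = ", "))
    }
    dsub <- delta[common]; esub <- expr[, common, drop = FALSE]
  }
  if (length(unique(dsub)) < 2L) stop("delta map is constant over the common regions")
  nres <- ncol(esub)
  dr <- rank(dsub, ties.method = "average")
  res <- t(apply(esub, 1L, function(g) {
    ct <- suppressWarnings(stats::cor.test(rank(g, ties.method = "average"), dr,
                                           method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }))
  fdr <- bh_fdr(res[, 2L], fdr_threshold)
  gene_ids <- if (is.null(rownames(esub))) paste0("gene_", seq_len(nrow(esub))) else rownames(esub)
  out <- data.frame(gene_id = gene_ids, rho = res[, 1L], p = res[, 2L],
                    q = fdr$q, significant = fdr$rejected,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "regions_used") <- nres
  class(out) <- c("association_result", class(out))
  out
}
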