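#' Binned Hi-C contact matrix
#'
#' The central container of the package: a dense symmetric count matrix over
#' the bins of a [genome_spec()], with an optional balanced matrix, per-bin
#' balancing weights, and a per-bin validity mask. Masked bins are excluded
#' from every downstream statistic. The main diagonal is zero by convention
#' and excluded everywhere.
#'
#' @param genome a `genome_spec`.
#' @param counts symmetric non-negative matrix, one row/column per bin.
#' @param mask logical vector, `TRUE` for valid bins (default all valid).
#' @return an object of class `contact_matrix` with fields `bins`, `counts`,
#'   `balanced` (NULL until [balance_matrix()]), `weights`, `mask`,
#'   `resolution`, `genome`.
#' @export
contact_matrix <- function(genome, counts, mask = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  bins <- genome_bins(genome)
  n <- nrow(bins)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(n, n)))
    stop("counts must be ", n, " x ", n, " for this genome")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stop("counts must be symmetric")
  # the diagonal is kept as given (zero for simulated matrices; sum-pooled
  # short-range counts after coarsening) but excluded from every statistic
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n, is.logical(mask))
  structure(
    list(bins = bins, counts = counts, balanced = NULL, weights = NULL,
         mask = mask, resolution = genome$resolution, genome = genome),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins,",
      length(x$genome$chrom_lengths), "chromosome(s),",
      format(x$resolution, big.mark = ","), "bp resolution\n")
  cat("  total counts:", sum(x$counts) / 2,
      "| masked bins:", sum(!x$mask),
      "| balanced:", !is.null(x$balanced), "\n")
  invisible(x)
}

# matrix of the working values: balanced if present (and requested), raw otherwise
working_matrix <- function(cm, use = c("auto", "balanced", "counts")) {
  use <- match.arg(use)
  if (use == "counts") return(cm$counts)
  if (use == "balanced" && is.null(cm$balanced))
    stop("matrix has not been balanced; call balance_matrix() first")
  if (!is.null(cm$balanced)) cm$balanced else cm$counts
}

# logical matrix: both bins valid
pair_valid <- function(cm) {
  outer(cm$mask, cm$mask, "&")
}

# logical matrix: same chromosome
same_chrom_matrix <- function(cm) {
  outer(cm$bins$chrom, cm$bins$chrom, "==")
}

# bin-start separation in bp (cis interpretation)
separation_matrix <- function(cm) {
  abs(outer(cm$bins$start, cm$bins$start, "-")) +
    ifelse(same_chrom_matrix(cm), 0, NA)
}

#' Mask low-coverage bins
#'
#' Bins whose raw marginal sum falls below `min_fraction_of_median` times the
#' median marginal (computed over currently valid bins) are masked.
#' Idempotent: re-applying with the same threshold changes nothing.
#'
#' @param cm a `contact_matrix` with raw counts.
#' @param min_fraction_of_median threshold as a fraction of the median
#'   marginal; default 0.1.
#' @return the matrix with an updated mask.
#' @export
mask_low_coverage <- function(cm, min_fraction_of_median = 0.1) {
  stopifnot(inherits(cm, "contact_matrix"))
  marg <- rowSums(cm$counts)
  med <- stats::median(marg[cm$mask])
  new_mask <- cm$mask & (marg >= min_fraction_of_median * med)
  if (!any(new_mask)) stop("all bins masked by coverage filter")
  cm$mask <- new_mask
  cm
}

#' Balance a contact matrix to equal marginals
#'
#' Iterative proportional correction on the unmasked submatrix: per-bin
#' weights `w` are found such that the balanced matrix `w_i * w_j * c_ij` has
#' equal row sums over unmasked bins (coefficient of variation of the
#' marginals at most `tolerance`). Weights are scaled so the mean balanced
#' marginal is 1. Fails loudly on non-convergence; never returns a silent
#' partial result.
#'
#' @param cm a `contact_matrix`.
#' @param tolerance target coefficient of variation of the unmasked
#'   marginals; default 1e-9.
#' @param max_iterations iteration cap; default 5000.
#' @return the matrix with `balanced` and `weights` fields filled in.
#' @export
balance_matrix <- function(cm, tolerance = 1e-9, max_iterations = 5000) {
  stopifnot(inherits(cm, "contact_matrix"))
  valid <- cm$mask
  sub <- cm$counts[valid, valid, drop = FALSE]
  nv <- nrow(sub)
  if (nv < 2) stop("fewer than 2 unmasked bins; cannot balance")
  w <- rep(1, nv)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    marg <- as.vector(sub %*% w) * w
    if (any(marg == 0))
      stop("zero marginal on an unmasked bin; mask it before balancing")
    cv <- stats::sd(marg) / mean(marg)
    if (cv <= tolerance) { converged <- TRUE; break }
    s <- marg / mean(marg)
    w <- w / sqrt(s)
  }
  if (!converged)
    stop("balancing did not converge within ", max_iterations,
         " iterations (marginal CV = ", format(cv, digits = 3), ")")
  # scale so that the mean balanced marginal is 1
  marg <- as.vector(sub %*% w) * w
  w <- w / sqrt(mean(marg))
  weights <- rep(NA_real_, nrow(cm$bins))
  weights[valid] <- w
  bal <- matrix(NA_real_, nrow(cm$bins), nrow(cm$bins))
  bal[valid, valid] <- outer(w, w) * sub
  cm$weights <- weights
  cm$balanced <- bal
  cm
}

#' Mean contact value per bin separation
#'
#' The distance-decay expectation: for each chromosome, the mean (balanced)
#' contact value over unmasked cis pairs at each bin separation
#' `d = 1 .. nbins - 1`, plus a genome-wide pooled profile and the mean over
#' unmasked trans pairs. Separations with no unmasked pair are `NA`.
#'
#' @param cm a `contact_matrix`.
#' @param use `"auto"` (balanced if available), `"balanced"`, or `"counts"`.
#' @return an `expected_profile`: list with `per_chrom` (named list of
#'   vectors, value at position d = mean at separation d bins), `pooled`,
#'   `trans_mean`, `resolution`.
#' @export
expected_by_distance <- function(cm, use = "auto") {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- working_matrix(cm, use)
  chroms <- names(cm$genome$chrom_lengths)
  per_chrom <- list()
  pooled_sum <- numeric(0)
  pooled_n <- numeric(0)
  for (ch in chroms) {
    idx <- which(cm$bins$chrom == ch)
    nb <- length(idx)
    if (nb < 2) { per_chrom[[ch]] <- numeric(0); next }
    sub <- m[idx, idx, drop = FALSE]
    vsub <- cm$mask[idx]
    prof <- rep(NA_real_, nb - 1)
    for (d in seq_len(nb - 1)) {
      i <- seq_len(nb - d)
      vals <- sub[cbind(i, i + d)]
      ok <- vsub[i] & vsub[i + d] & !is.na(vals)
      if (any(ok)) {
        prof[d] <- mean(vals[ok])
        if (length(pooled_sum) < d) {
          pooled_sum[d] <- 0; pooled_n[d] <- 0
          pooled_sum[is.na(pooled_sum)] <- 0
          pooled_n[is.na(pooled_n)] <- 0
        }
        pooled_sum[d] <- pooled_sum[d] + sum(vals[ok])
        pooled_n[d] <- pooled_n[d] + sum(ok)
      }
    }
    per_chrom[[ch]] <- prof
  }
  pooled <- ifelse(pooled_n > 0, pooled_sum / pooled_n, NA_real_)
  tr <- !same_chrom_matrix(cm) & pair_valid(cm) & upper.tri(m)
  trans_mean <- if (any(tr)) mean(m[tr], na.rm = TRUE) else NA_real_
  structure(list(per_chrom = per_chrom, pooled = pooled,
                 trans_mean = trans_mean, resolution = cm$resolution),
            class = "expected_profile")
}

#' Observed-over-expected transform
#'
#' Divides each cis entry by the per-chromosome expected value at its
#' separation, and each trans entry by the genome-wide trans expectation.
#' The diagonal and masked bins are `NA`. By construction the mean O/E over
#' each unmasked cis diagonal is 1.
#'
#' @param cm a `contact_matrix`.
#' @param profile an `expected_profile` from [expected_by_distance()]; if
#'   missing, computed from `cm`.
#' @param use which matrix to transform; see [expected_by_distance()].
#' @return matrix of O/E values (same dimensions as the contact matrix).
#' @export
observed_over_expected <- function(cm, profile = NULL, use = "auto") {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(profile)) profile <- expected_by_distance(cm, use)
  m <- working_matrix(cm, use)
  n <- nrow(m)
  oe <- matrix(NA_real_, n, n)
  for (ch in names(profile$per_chrom)) {
    idx <- which(cm$bins$chrom == ch)
    nb <- length(idx)
    if (nb < 2) next
    prof <- profile$per_chrom[[ch]]
    sub <- m[idx, idx, drop = FALSE]
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    e <- matrix(NA_real_, nb, nb)
    pos <- d > 0
    e[pos] <- prof[d[pos]]
    oe[idx, idx] <- sub / e
  }
  tr <- !same_chrom_matrix(cm)
  if (any(tr) && !is.na(profile$trans_mean) && profile$trans_mean > 0)
    oe[tr] <- m[tr] / profile$trans_mean
  bad <- !pair_valid(cm)
  oe[bad] <- NA_real_
  diag(oe) <- NA_real_
  oe
}

#' Sum-pool a matrix to a coarser resolution
#'
#' Bins are grouped per chromosome in runs of `factor`; counts are summed, so
#' the total count is preserved exactly. A coarse bin is valid if any of its
#' constituents is valid.
#'
#' @param cm a `contact_matrix`.
#' @param factor integer coarsening factor (>= 2).
#' @return a new `contact_matrix` at `factor` times the resolution.
#' @export
coarsen_matrix <- function(cm, factor) {
  stopifnot(inherits(cm, "contact_matrix"), factor >= 2, factor == round(factor))
  g2 <- genome_spec(cm$genome$chrom_lengths, cm$resolution * factor)
  group <- integer(nrow(cm$bins))
  off <- 0L
  for (ch in names(cm$genome$chrom_lengths)) {
    idx <- which(cm$bins$chrom == ch)
    grp <- (seq_along(idx) - 1L) %/% factor + 1L
    group[idx] <- off + grp
    off <- off + max(grp)
  }
  n2 <- off
  agg <- matrix(0, n2, nrow(cm$bins))
  agg[cbind(group, seq_along(group))] <- 1
  counts2 <- agg %*% cm$counts %*% t(agg)
  mask2 <- as.vector(agg %*% cm$mask) > 0
  contact_matrix(g2, counts2, mask = mask2)
}

#' Pearson correlation between two contact matrices
#'
#' Replicate-reproducibility statistic: matrices are optionally coarsened to
#' a common resolution, depth-normalized to equal totals, and correlated over
#' unmasked upper-triangle pairs (cis by default, trans optionally included).
#'
#' @param a,b `contact_matrix` objects on the same genome.
#' @param resolution optional target resolution in bp (a multiple of both
#'   matrices' resolutions).
#' @param scope `"cis"` (default) or `"all"`.
#' @param use `"counts"` (default) or `"balanced"`.
#' @return Pearson correlation coefficient.
#' @export
matrix_correlation <- function(a, b, resolution = NULL, scope = c("cis", "all"),
                               use = "counts") {
  scope <- match.arg(scope)
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!is.null(resolution)) {
    fa <- resolution / a$resolution
    fb <- resolution / b$resolution
    if (fa != round(fa) || fb != round(fb))
      stop("target resolution must be a multiple of both matrix resolutions")
    if (fa > 1) a <- coarsen_matrix(a, fa)
    if (fb > 1) b <- coarsen_matrix(b, fb)
  }
  if (!identical(dim(a$counts), dim(b$counts)) ||
      !identical(a$bins$chrom, b$bins$chrom) ||
      !identical(a$bins$start, b$bins$start))
    stop("bin grids are incompatible")
  ma <- working_matrix(a, use)
  mb <- working_matrix(b, use)
  ma <- ma / sum(ma)
  mb <- mb / sum(mb)
  keep <- upper.tri(ma) & pair_valid(a) & pair_valid(b)
  if (scope == "cis") keep <- keep & same_chrom_matrix(a)
  stats::cor(ma[keep], mb[keep], use = "complete.obs")
}
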