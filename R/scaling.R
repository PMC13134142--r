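# Distance-stratified contact statistics: decay curves, long-range contact
# fractions, per-bin distal-to-local ratio (DLR), and per-bin
# interchromosomal contact frequency (ICF). Separation is always measured
# between bin starts; a pair exactly at a threshold counts as local/short.

#' Contact frequency versus genomic distance
#'
#' Cis pair values are summed into contiguous logarithmic separation
#' intervals — the classical P(s)-style decay curve used as a per-stage QC
#' and comparison metric.
#'
#' @param cm a `contact_matrix`.
#' @param n_log_bins number of logarithmic intervals (>= 2).
#' @param use `"counts"` (default), `"balanced"`, or `"auto"`.
#' @param normalize if TRUE, totals are divided by their sum.
#' @return data.frame(start_bp, end_bp, total, n_pairs); attribute `mode`
#'   records the matrix used.
#' @export
contact_frequency_vs_distance <- function(cm, n_log_bins = 20,
                                          use = "counts", normalize = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (n_log_bins < 2) stop("n_log_bins must be >= 2")
  m <- working_matrix(cm, use)
  sep <- separation_matrix(cm)
  keep <- upper.tri(m) & !is.na(sep) & sep > 0 & pair_valid(cm) & !is.na(m)
  s <- sep[keep]; v <- m[keep]
  lo <- log10(min(s)); hi <- log10(max(s))
  edges <- 10^seq(lo, hi, length.out = n_log_bins + 1)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-9)
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  total <- vapply(seq_len(n_log_bins), function(k) sum(v[idx == k]), 0)
  npair <- vapply(seq_len(n_log_bins), function(k) sum(idx == k), 0L)
  if (normalize && sum(total) > 0) total <- total / sum(total)
  out <- data.frame(start_bp = edges[-length(edges)], end_bp = edges[-1],
                    total = total, n_pairs = npair)
  attr(out, "mode") <- use
  out
}

#' Fraction of cis contacts beyond a separation cutoff
#'
#' Sum of unmasked cis contacts with bin-start separation strictly greater
#' than `cutoff_bp`, divided by the sum of all unmasked cis contacts.
#'
#' @param cm a `contact_matrix`.
#' @param cutoff_bp separation cutoff; default 50 Mb.
#' @param use matrix selector; default raw counts.
#' @return proportion in `[0, 1]`.
#' @export
long_range_fraction <- function(cm, cutoff_bp = 50e6, use = "counts") {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- working_matrix(cm, use)
  sep <- separation_matrix(cm)
  keep <- upper.tri(m) & !is.na(sep) & sep > 0 & pair_valid(cm) & !is.na(m)
  tot <- sum(m[keep])
  if (tot == 0) return(NA_real_)
  sum(m[keep & !is.na(sep) & sep > cutoff_bp]) / tot
}

#' Per-bin distal-to-local ratio (DLR)
#'
#' For each bin, the log2 ratio of its cis contacts at separations greater
#' than `threshold_bp` (distal) to those within `threshold_bp` (local,
#' separation > 0). Undefined (NA) where either sum is zero. Applied to the
#' balanced matrix by default, as the score is meant for corrected data.
#'
#' @param cm a `contact_matrix`.
#' @param threshold_bp distal/local boundary; default 3 Mb. Pairs at exactly
#'   the threshold count as local.
#' @param use matrix selector; default `"auto"` (balanced if available).
#' @return a `dlr_track` data.frame(chrom, start, end, dlr, local, distal).
#' @export
dlr <- function(cm, threshold_bp = 3e6, use = "auto") {
  stopifnot(inherits(cm, "contact_matrix"))
  if (threshold_bp < cm$resolution)
    stop("threshold_bp must be at least one bin")
  m <- working_matrix(cm, use)
  sep <- separation_matrix(cm)
  n <- nrow(m)
  local_sum <- distal_sum <- rep(NA_real_, n)
  pv <- pair_valid(cm)
  for (i in seq_len(n)) {
    if (!cm$mask[i]) next
    cis_ok <- !is.na(sep[i, ]) & sep[i, ] > 0 & pv[i, ] & !is.na(m[i, ])
    local_sum[i] <- sum(m[i, cis_ok & sep[i, ] <= threshold_bp])
    distal_sum[i] <- sum(m[i, cis_ok & sep[i, ] > threshold_bp])
  }
  val <- ifelse(!is.na(local_sum) & local_sum > 0 & distal_sum > 0,
                log2(distal_sum / local_sum), NA_real_)
  out <- data.frame(cm$bins[, c("chrom", "start", "end")], dlr = val,
                    local = local_sum, distal = distal_sum)
  class(out) <- c("dlr_track", "data.frame")
  out
}

#' Per-bin interchromosomal contact frequency (ICF)
#'
#' For each bin, the trans share of its total contacts:
#' `trans / (trans + cis)`. Undefined (NA) for bins with zero total.
#'
#' @param cm a `contact_matrix` containing trans contacts.
#' @param use matrix selector; default raw counts.
#' @param log2_ratio if TRUE, return `log2(trans / cis)` instead of the
#'   proportion.
#' @return an `icf_track` data.frame(chrom, start, end, icf, cis, trans).
#' @export
icf <- function(cm, use = "counts", log2_ratio = FALSE) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- working_matrix(cm, use)
  same <- same_chrom_matrix(cm)
  pv <- pair_valid(cm)
  m0 <- m; m0[is.na(m0)] <- 0; m0[!pv] <- 0; diag(m0) <- 0
  cis_sum <- rowSums(m0 * same)
  trans_sum <- rowSums(m0 * !same)
  tot <- cis_sum + trans_sum
  val <- if (log2_ratio) {
    ifelse(cm$mask & cis_sum > 0 & trans_sum > 0,
           log2(trans_sum / cis_sum), NA_real_)
  } else {
    ifelse(cm$mask & tot > 0, trans_sum / tot, NA_real_)
  }
  out <- data.frame(cm$bins[, c("chrom", "start", "end")], icf = val,
                    cis = cis_sum, trans = trans_sum)
  class(out) <- c("icf_track", "data.frame")
  out
}

#' Group summaries and a rank-based location test for a per-bin track
#'
#' Summarizes a score track within groups (e.g. compartment A vs B) and runs
#' a two-sided Wilcoxon rank-sum test between two named groups.
#'
#' @param values per-bin numeric track (NA allowed).
#' @param labels per-bin group labels.
#' @param test_groups length-2 character: the groups to compare (default:
#'   the two most frequent).
#' @return list with `summary` (data.frame group, n, mean, median, sd) and
#'   `test` (list groups, statistic, p_value).
#' @export
stratify_track <- function(values, labels, test_groups = NULL) {
  if (length(values) != length(labels)) stop("track and labels differ in length")
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  groups <- sort(unique(labels))
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- values[labels == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v))
  }))
  if (is.null(test_groups)) {
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) < 2) return(list(summary = summ, test = NULL))
    test_groups <- names(tab)[1:2]
  }
  va <- values[labels == test_groups[1]]
  vb <- values[labels == test_groups[2]]
  if (length(va) < 2 || length(vb) < 2)
    stop("each tested group needs >= 2 defined values")
  wt <- stats::wilcox.test(va, vb, exact = FALSE)
  list(summary = summ,
       test = list(groups = test_groups, statistic = unname(wt$statistic),
                   p_value = wt$p.value))
}
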