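# Independent brute-force oracles: plain double loops over the bin table,
# sharing no code with the implementation they check.

oracle_dlr <- function(cm, threshold_bp = 3e6, m = NULL) {
  if (is.null(m)) m <- if (!is.null(cm$balanced)) cm$balanced else cm$counts
  bins <- cm$bins
  n <- nrow(bins)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!cm$mask[i]) next
    loc <- 0; dis <- 0
    for (j in seq_len(n)) {
      if (j == i || !cm$mask[j]) next
      if (bins$chrom[j] != bins$chrom[i]) next
      v <- m[i, j]
      if (is.na(v)) next
      sep <- abs(bins$start[i] - bins$start[j])
      if (sep <= threshold_bp) loc <- loc + v else dis <- dis + v
    }
    if (loc > 0 && dis > 0) out[i] <- log2(dis / loc)
  }
  out
}

oracle_icf <- function(cm) {
  bins <- cm$bins
  n <- nrow(bins)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!cm$mask[i]) next
    cis <- 0; trans <- 0
    for (j in seq_len(n)) {
      if (j == i || !cm$mask[j]) next
      v <- cm$counts[i, j]
      if (bins$chrom[j] == bins$chrom[i]) cis <- cis + v else trans <- trans + v
    }
    if (cis + trans > 0) out[i] <- trans / (cis + trans)
  }
  out
}

oracle_long_range_fraction <- function(cm, cutoff_bp) {
  bins <- cm$bins
  n <- nrow(bins)
  tot <- 0; lr <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!cm$mask[i] || !cm$mask[j]) next
    if (bins$chrom[i] != bins$chrom[j]) next
    v <- cm$counts[i, j]
    tot <- tot + v
    if (abs(bins$start[i] - bins$start[j]) > cutoff_bp) lr <- lr + v
  }
  lr / tot
}

# raw insulation score (single window, in bins) before z-scoring
oracle_insulation_raw <- function(cm, w, m = NULL) {
  if (is.null(m)) m <- if (!is.null(cm$balanced)) cm$balanced else cm$counts
  bins <- cm$bins
  n <- nrow(bins)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- bins$chrom[i]
    first <- min(which(bins$chrom == ch)); last <- max(which(bins$chrom == ch))
    if (i - w < first || i + w > last || !cm$mask[i]) next
    vals <- c()
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      if (cm$mask[a] && cm$mask[b] && !is.na(m[a, b]))
        vals <- c(vals, m[a, b])
    }
    if (length(vals)) out[i] <- mean(vals)
  }
  out
}

oracle_inter_tad <- function(cm, doms, edges) {
  bins <- cm$bins
  n <- nrow(bins)
  which_dom <- function(i) {
    for (k in seq_len(nrow(doms)))
      if (bins$chrom[i] == doms$chrom[k] && bins$start[i] >= doms$start[k] &&
          bins$start[i] < doms$end[k]) return(k)
    NA
  }
  dom <- vapply(seq_len(n), which_dom, 0)
  tot <- 0
  sums <- numeric(length(edges) - 1)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!cm$mask[i] || !cm$mask[j]) next
    if (bins$chrom[i] != bins$chrom[j]) next
    v <- cm$counts[i, j]
    tot <- tot + v
    if (is.na(dom[i]) || is.na(dom[j]) || dom[i] == dom[j]) next
    sep <- abs(bins$start[i] - bins$start[j])
    for (w in seq_len(length(edges) - 1))
      if (sep > edges[w] && sep <= edges[w + 1]) sums[w] <- sums[w] + v
  }
  sums / tot
}

# mean distance of the farthest 5% of r for a uniform ball of radius R,
# plus the classifier fractions implied by that radius (Monte-Carlo)
oracle_ball_fractions <- function(n = 2e5, R = 1, seed = 42,
                                  top_fraction = 0.05) {
  set.seed(seed)
  r <- R * runif(n)^(1 / 3)
  k <- ceiling(top_fraction * n)
  rad <- mean(sort(r, decreasing = TRUE)[1:k])
  rel <- r / rad
  c(radius = rad,
    center = mean(rel < 0.2),
    peripheral = mean(rel > 0.8))
}
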