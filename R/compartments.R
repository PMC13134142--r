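# A/B compartment calling from the leading eigenvector of the O/E
# correlation matrix, sign orientation against a reference track,
# stage-to-stage switching, saddle plots, and class contact ratios.

#' First eigenvector of the O/E correlation matrix (one chromosome)
#'
#' Forms the Pearson correlation matrix of the cis O/E rows over unmasked
#' bins and returns the unit-norm eigenvector of its largest eigenvalue —
#' the classical compartment PC1. The sign is arbitrary until
#' [orient_pc1()].
#'
#' @param oe cis O/E matrix for a single chromosome (square; NA allowed on
#'   the diagonal and masked bins).
#' @param mask logical per-bin validity (default: bins with any finite O/E).
#' @return list with `pc1` (full-length, NA on masked bins, unit norm over
#'   the rest) and `eigval_fraction` (leading eigenvalue over the trace).
#' @export
compute_pc1 <- function(oe, mask = NULL) {
  n <- nrow(oe)
  if (is.null(mask)) mask <- apply(oe, 1, function(r) any(is.finite(r)))
  idx <- which(mask)
  if (length(idx) < 3) stop("need >= 3 unmasked bins for PC1")
  sub <- oe[idx, idx, drop = FALSE]
  # the only NAs inside the unmasked submatrix sit on the self-diagonal
  # (plus separations with no defined expectation); impute them with the
  # column mean so the fast complete-observation correlation path applies
  cmeans <- colMeans(sub, na.rm = TRUE)
  nas <- which(is.na(sub), arr.ind = TRUE)
  if (nrow(nas) > 0) sub[nas] <- cmeans[nas[, 2]]
  if (anyNA(sub)) stop("degenerate correlation matrix (empty O/E rows)")
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate correlation matrix (constant O/E rows)")
  cc <- stats::cor(sub)
  es <- eigen(cc, symmetric = TRUE)
  v <- es$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  out <- rep(NA_real_, n)
  out[idx] <- v
  list(pc1 = out, eigval_fraction = es$values[1] / sum(pmax(es$values, 0)))
}

#' Orient a PC1 vector against a reference track
#'
#' Automated replacement for manual sign curation: the vector is flipped
#' when its Pearson correlation with the reference (e.g. gene density, GC,
#' or planted truth) is negative, so that positive values mean compartment A.
#'
#' @param pc1 raw eigenvector (NA allowed).
#' @param reference per-bin reference track on the same bins.
#' @return list with `pc1` (oriented) and `flipped` (logical).
#' @export
orient_pc1 <- function(pc1, reference) {
  ok <- !is.na(pc1) & !is.na(reference)
  if (sum(ok) < 2 || stats::sd(reference[ok]) == 0)
    stop("reference track has zero variance on the shared bins")
  r <- stats::cor(pc1[ok], reference[ok])
  flip <- !is.na(r) && r < 0
  list(pc1 = if (flip) -pc1 else pc1, flipped = flip)
}

#' Genome-wide compartment track
#'
#' Runs [compute_pc1()] per chromosome on the cis O/E of a balanced matrix,
#' orients each chromosome against `reference`, and labels bins A (PC1 > 0),
#' B (PC1 < 0), or NA (masked).
#'
#' @param cm a balanced `contact_matrix`.
#' @param reference per-bin orientation track (genome-wide).
#' @param use matrix selector passed to [expected_by_distance()].
#' @return a `compartment_track`: data.frame(chrom, start, end, pc1, label)
#'   with per-chromosome `flipped` and `eigval_fraction` attributes.
#' @export
compartment_track <- function(cm, reference, use = "auto") {
  stopifnot(inherits(cm, "contact_matrix"))
  oe <- observed_over_expected(cm, use = use)
  n <- nrow(cm$bins)
  pc1 <- rep(NA_real_, n)
  flips <- logical(0); evf <- numeric(0)
  for (ch in names(cm$genome$chrom_lengths)) {
    idx <- which(cm$bins$chrom == ch)
    if (length(idx) < 3) next
    raw <- compute_pc1(oe[idx, idx, drop = FALSE], mask = cm$mask[idx])
    ori <- orient_pc1(raw$pc1, reference[idx])
    pc1[idx] <- ori$pc1
    flips[ch] <- ori$flipped
    evf[ch] <- raw$eigval_fraction
  }
  out <- data.frame(cm$bins[, c("chrom", "start", "end")], pc1 = pc1,
                    label = ifelse(is.na(pc1), NA_character_,
                                   ifelse(pc1 > 0, "A", "B")))
  attr(out, "flipped") <- flips
  attr(out, "eigval_fraction") <- evf
  class(out) <- c("compartment_track", "data.frame")
  out
}

track_labels <- function(track) {
  if (inherits(track, "compartment_track")) track$label
  else if (is.data.frame(track)) track$label
  else as.character(track)
}

#' Classify per-bin compartment switching between two stages
#'
#' @param track_a,track_b `compartment_track`s (or label vectors) on the
#'   same bin grid.
#' @return a `switch_table`: list with `categories` (per-bin, one of A>A,
#'   A>B, B>A, B>B, or NA), `counts`, `fractions` (over classified bins),
#'   and `switching_fraction` = (A>B + B>A) / classified.
#' @export
classify_switching <- function(track_a, track_b) {
  la <- track_labels(track_a); lb <- track_labels(track_b)
  if (length(la) != length(lb)) stop("tracks are on different bin grids")
  cat_lab <- ifelse(is.na(la) | is.na(lb), NA_character_,
                    paste(la, lb, sep = ">"))
  lev <- c("A>A", "A>B", "B>A", "B>B")
  counts <- table(factor(cat_lab, levels = lev))
  n_class <- sum(counts)
  fr <- if (n_class > 0) as.numeric(counts) / n_class else rep(NA_real_, 4)
  names(fr) <- lev
  structure(list(categories = cat_lab, counts = counts, fractions = fr,
                 switching_fraction = unname(fr["A>B"] + fr["B>A"])),
            class = "switch_table")
}

#' @export
print.switch_table <- function(x, ...) {
  cat("switch_table:", sum(x$counts), "classified bins;",
      sprintf("switching fraction %.3f\n", x$switching_fraction))
  print(x$counts)
  invisible(x)
}

#' Saddle plot and compartment strength
#'
#' Bins are ranked by PC1 and split into `n_quantiles` equal-occupancy
#' groups (ascending: group 1 = strongest B, group Q = strongest A). Entry
#' (q, r) is the mean cis O/E over unmasked pairs between the groups.
#' Strength = (mean of the AA corner + mean of the BB corner) /
#' (2 x mean of the two AB corners), the corners being the extreme
#' `corner_fraction` of quantiles. Rank-based, so invariant to any monotone
#' rescaling of PC1.
#'
#' @param cm a balanced `contact_matrix`.
#' @param track `compartment_track` or per-bin PC1 vector.
#' @param n_quantiles number of PC1 quantiles (default 50, reduced to the
#'   number of classified bins if fewer).
#' @param corner_fraction fraction of quantiles in each corner; default 0.2.
#' @param oe optional precomputed O/E matrix.
#' @return a `saddle_result`: list with `matrix` (Q x Q), `strength`,
#'   `quantiles` (per-bin group index), `corner_size`.
#' @export
saddle <- function(cm, track, n_quantiles = 50, corner_fraction = 0.2,
                   oe = NULL) {
  stopifnot(inherits(cm, "contact_matrix"), n_quantiles >= 2)
  pc1 <- if (is.data.frame(track)) track$pc1 else as.numeric(track)
  if (length(pc1) != nrow(cm$bins)) stop("track and matrix bins differ")
  if (is.null(oe)) oe <- observed_over_expected(cm)
  ok <- cm$mask & !is.na(pc1)
  q <- min(n_quantiles, sum(ok))
  grp <- rep(NA_integer_, length(pc1))
  grp[ok] <- ceiling(rank(pc1[ok], ties.method = "first") / sum(ok) * q)
  cis <- same_chrom_matrix(cm)
  s <- matrix(NA_real_, q, q)
  for (a in seq_len(q)) for (b in a:q) {
    ia <- which(grp == a); ib <- which(grp == b)
    if (length(ia) == 0 || length(ib) == 0)
      stop("empty PC1 quantile after masking")
    block <- oe[ia, ib, drop = FALSE]
    keep <- cis[ia, ib, drop = FALSE] & !is.na(block)
    if (a == b) keep <- keep & upper.tri(block)
    if (any(keep)) s[a, b] <- s[b, a] <- mean(block[keep])
  }
  k <- max(1L, ceiling(corner_fraction * q))
  lo <- seq_len(k); hi <- (q - k + 1L):q
  bb <- mean(s[lo, lo], na.rm = TRUE)
  aa <- mean(s[hi, hi], na.rm = TRUE)
  ab <- mean(s[lo, hi], na.rm = TRUE)
  structure(list(matrix = s, strength = (aa + bb) / (2 * ab),
                 corner_means = c(AA = aa, BB = bb, AB = ab),
                 quantiles = grp, corner_size = k),
            class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat("saddle_result:", nrow(x$matrix), "x", ncol(x$matrix),
      sprintf("quantile grid; strength %.3f\n", x$strength))
  invisible(x)
}

#' Log2 observed/expected contact ratios for A-A, B-B, A-B pairs
#'
#' For each compartment pair class, log2 of the mean observed balanced
#' contact over the mean distance-expected contact (cis scope), or over the
#' genome-wide trans expectation (trans scope), across unmasked pairs of the
#' class.
#'
#' @param cm a balanced `contact_matrix`.
#' @param track `compartment_track` or per-bin A/B label vector.
#' @param scope `"cis"` or `"trans"`.
#' @return named numeric: `AA`, `BB`, `AB` log2 ratios (NA for empty class).
#' @export
compartment_contact_ratio <- function(cm, track, scope = c("cis", "trans")) {
  scope <- match.arg(scope)
  stopifnot(inherits(cm, "contact_matrix"))
  lab <- track_labels(track)
  if (length(lab) != nrow(cm$bins)) stop("track and matrix bins differ")
  m <- working_matrix(cm, "auto")
  prof <- expected_by_distance(cm)
  n <- nrow(m)
  # expectation matrix matching the observed scale
  e <- matrix(NA_real_, n, n)
  for (ch in names(prof$per_chrom)) {
    idx <- which(cm$bins$chrom == ch)
    nb <- length(idx)
    if (nb < 2) next
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    pc <- prof$per_chrom[[ch]]
    blk <- matrix(NA_real_, nb, nb)
    blk[d > 0] <- pc[d[d > 0]]
    e[idx, idx] <- blk
  }
  tr <- !same_chrom_matrix(cm)
  e[tr] <- prof$trans_mean
  keep_base <- upper.tri(m) & pair_valid(cm) & !is.na(m) & !is.na(e)
  keep_base <- keep_base & (if (scope == "cis") !tr else tr)
  la <- matrix(lab, n, n); lbm <- t(la)
  out <- c(AA = NA_real_, BB = NA_real_, AB = NA_real_)
  classes <- list(AA = la == "A" & lbm == "A",
                  BB = la == "B" & lbm == "B",
                  AB = (la == "A" & lbm == "B") | (la == "B" & lbm == "A"))
  for (nm in names(classes)) {
    sel <- keep_base & !is.na(classes[[nm]]) & classes[[nm]]
    if (any(sel)) out[nm] <- log2(mean(m[sel]) / mean(e[sel]))
  }
  out
}
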