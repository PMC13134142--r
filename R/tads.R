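# Insulation-score TAD analysis: multi-window separation score, boundary
# calling by prominent local minima, aggregate pileups, domain strength
# across stages, and inter-TAD distance-window contact proportions.

#' Multi-window insulation (TAD-separation) score
#'
#' For each window size `w` (in bp) and each bin `i`, the raw score is the
#' mean contact between the `w`-bin block upstream and the `w`-bin block
#' downstream of `i`. Raw scores are z-scored per chromosome and window, and
#' the final track is the mean z-score across windows. Bins closer than the
#' window to a chromosome edge are NA. Z-scoring makes the track invariant
#' to global rescaling of the matrix.
#'
#' @param cm a `contact_matrix` (balanced by default).
#' @param window_sizes window sizes in bp, multiples of the resolution;
#'   default c(150e3, 250e3, 500e3) for 50-kb bins.
#' @param use matrix selector.
#' @return an `insulation_track` data.frame(chrom, start, end, score) with a
#'   `windows` attribute; `raw` columns per window are kept for oracles.
#' @export
insulation_score <- function(cm, window_sizes = c(150e3, 250e3, 500e3),
                             use = "auto") {
  stopifnot(inherits(cm, "contact_matrix"))
  wbins <- window_sizes / cm$resolution
  if (any(wbins != round(wbins)) || any(wbins < 1))
    stop("window sizes must be positive multiples of the resolution")
  wbins <- as.integer(wbins)
  m <- working_matrix(cm, use)
  n <- nrow(cm$bins)
  raw <- matrix(NA_real_, n, length(wbins))
  z <- matrix(NA_real_, n, length(wbins))
  for (ch in names(cm$genome$chrom_lengths)) {
    idx <- which(cm$bins$chrom == ch)
    nb <- length(idx)
    sub <- m[idx, idx, drop = FALSE]
    vsub <- cm$mask[idx]
    for (k in seq_along(wbins)) {
      w <- wbins[k]
      if (2 * w + 1 > nb) {
        if (w >= nb) stop("window ", window_sizes[k], " bp exceeds ", ch)
        next
      }
      for (i in (w + 1):(nb - w)) {
        if (!vsub[i]) next
        up <- (i - w):(i - 1); dn <- (i + 1):(i + w)
        blk <- sub[up, dn, drop = FALSE]
        ok <- outer(vsub[up], vsub[dn], "&") & !is.na(blk)
        if (any(ok)) raw[idx[i], k] <- mean(blk[ok])
      }
      def <- idx[!is.na(raw[idx, k])]
      if (length(def) > 1) {
        mu <- mean(raw[def, k]); sdv <- stats::sd(raw[def, k])
        z[def, k] <- if (sdv > 0) (raw[def, k] - mu) / sdv else 0
      }
    }
  }
  score <- rowMeans(z, na.rm = TRUE)
  score[!is.finite(score)] <- NA_real_
  out <- data.frame(cm$bins[, c("chrom", "start", "end")], score = score)
  for (k in seq_along(wbins)) out[[paste0("raw_w", wbins[k])]] <- raw[, k]
  attr(out, "windows") <- window_sizes
  class(out) <- c("insulation_track", "data.frame")
  out
}

# local minima of v (NA-tolerant); leftmost bin of a flat minimum; depth
# measured against the nearer flanking local maxima
local_minima_with_depth <- function(v) {
  n <- length(v)
  res <- list()
  i <- 1
  while (i <= n) {
    if (is.na(v[i])) { i <- i + 1; next }
    # extent of the flat run at v[i]
    j <- i
    while (j < n && !is.na(v[j + 1]) && v[j + 1] == v[i]) j <- j + 1
    left <- if (i > 1) v[i - 1] else NA
    right <- if (j < n) v[j + 1] else NA
    is_min <- !is.na(left) && !is.na(right) && left > v[i] && right > v[i]
    if (is_min) {
      # walk outward to the flanking local maxima
      lmax <- v[i - 1]; k <- i - 1
      while (k > 1 && !is.na(v[k - 1]) && v[k - 1] >= v[k]) {
        k <- k - 1; lmax <- max(lmax, v[k])
      }
      rmax <- v[j + 1]; k <- j + 1
      while (k < n && !is.na(v[k + 1]) && v[k + 1] >= v[k]) {
        k <- k + 1; rmax <- max(rmax, v[k])
      }
      res[[length(res) + 1]] <- c(pos = i, depth = min(lmax, rmax) - v[i])
    }
    i <- j + 1
  }
  if (length(res) == 0)
    return(data.frame(pos = integer(0), depth = numeric(0)))
  as.data.frame(do.call(rbind, res))
}

#' Call TAD boundaries and domains from an insulation track
#'
#' Boundaries are local minima of the score whose depth relative to the
#' flanking local maxima is at least `delta` (leftmost bin of a flat
#' minimum). Domains are formed between consecutive boundaries on a
#' chromosome and kept when their size lies in `[min_size, max_size]`.
#' Adding a constant to the track changes nothing.
#'
#' @param track an `insulation_track` (or data.frame chrom/start/end/score).
#' @param delta minimum boundary depth; default 0.01.
#' @param min_size,max_size domain size bounds in bp; defaults 150 kb and
#'   500 kb.
#' @return a `tad_set`: list with `boundaries` (chrom, start, end, bin,
#'   depth) and `domains` (chrom, start, end, size); all candidate domains
#'   (any size) are kept in `domains_all`.
#' @export
find_boundaries <- function(track, delta = 0.01, min_size = 150e3,
                            max_size = 500e3) {
  bnd <- list(); dom <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    mm <- local_minima_with_depth(track$score[sel])
    mm <- mm[mm$depth >= delta, , drop = FALSE]
    if (nrow(mm) > 0) {
      bi <- sel[mm$pos]
      bnd[[ch]] <- data.frame(chrom = ch, start = track$start[bi],
                              end = track$end[bi], bin = bi,
                              depth = mm$depth)
      if (nrow(mm) > 1) {
        st <- track$start[bi[-length(bi)]]
        en <- track$start[bi[-1]]
        dom[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                                size = en - st)
      }
    }
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               bin = integer(0), depth = numeric(0))
  domains_all <- if (length(dom)) do.call(rbind, dom) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               size = numeric(0))
  rownames(boundaries) <- rownames(domains_all) <- NULL
  keep <- domains_all$size >= min_size & domains_all$size <= max_size
  structure(list(boundaries = boundaries,
                 domains = domains_all[keep, , drop = FALSE],
                 domains_all = domains_all,
                 params = list(delta = delta, min_size = min_size,
                               max_size = max_size)),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat("tad_set:", nrow(x$boundaries), "boundaries,",
      nrow(x$domains), "domains within size bounds\n")
  invisible(x)
}

# bilinear sampling of src at fractional (row, col), NA-aware: weights of
# missing neighbours are dropped and the rest renormalized
bilinear_resize <- function(src, npx) {
  ns <- nrow(src)
  out <- matrix(NA_real_, npx, npx)
  coord <- (seq_len(npx) - 0.5) / npx * ns + 0.5  # source row coordinate
  lo <- pmin(pmax(floor(coord), 1), ns)
  hi <- pmin(lo + 1, ns)
  fr <- pmin(pmax(coord - lo, 0), 1)
  for (a in seq_len(npx)) {
    for (b in seq_len(npx)) {
      vals <- c(src[lo[a], lo[b]], src[lo[a], hi[b]],
                src[hi[a], lo[b]], src[hi[a], hi[b]])
      wts <- c((1 - fr[a]) * (1 - fr[b]), (1 - fr[a]) * fr[b],
               fr[a] * (1 - fr[b]), fr[a] * fr[b])
      ok <- !is.na(vals)
      if (any(ok) && sum(wts[ok]) > 0)
        out[a, b] <- sum(vals[ok] * wts[ok]) / sum(wts[ok])
    }
  }
  out
}

#' Aggregate rescaled O/E pileup over domains
#'
#' Each domain window (domain plus `flank_bp` on either side) is extracted
#' from the O/E matrix, rescaled to a fixed `npx` x `npx` pixel grid by
#' NA-aware bilinear interpolation, and averaged across domains. Domains
#' whose window crosses a chromosome edge are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param cm a balanced `contact_matrix`.
#' @param tads a `tad_set` or a domains data.frame(chrom, start, end).
#' @param flank_bp flank on each side; default 0.5 Mb.
#' @param npx output grid size; default 90 (30 pixels per flank/domain
#'   third when flank equals the mean domain size; the grid itself is
#'   uniform over the window).
#' @param oe optional precomputed O/E matrix.
#' @return `npx` x `npx` averaged pileup matrix; attribute `n_domains`.
#' @export
tad_pileup <- function(cm, tads, flank_bp = 0.5e6, npx = 90, oe = NULL) {
  doms <- if (inherits(tads, "tad_set")) tads$domains else tads
  if (nrow(doms) < 1) stop("need at least one domain")
  if (is.null(oe)) oe <- observed_over_expected(cm)
  acc <- matrix(0, npx, npx); cnt <- matrix(0, npx, npx)
  used <- 0L; skipped <- character(0)
  for (k in seq_len(nrow(doms))) {
    ch <- doms$chrom[k]
    idx <- which(cm$bins$chrom == ch)
    w0 <- doms$start[k] - flank_bp; w1 <- doms$end[k] + flank_bp
    sel <- idx[cm$bins$start[idx] >= w0 & cm$bins$start[idx] < w1]
    if (length(sel) < 2 || w0 < 0 ||
        w1 > cm$genome$chrom_lengths[[ch]]) {
      skipped <- c(skipped, sprintf("%s:%d-%d", ch, doms$start[k], doms$end[k]))
      next
    }
    px <- bilinear_resize(oe[sel, sel, drop = FALSE], npx)
    ok <- !is.na(px)
    acc[ok] <- acc[ok] + px[ok]
    cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  if (used == 0) stop("all domains skipped (chromosome edges)")
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  attr(out, "n_domains") <- used
  attr(out, "skipped") <- skipped
  out
}

#' Average insulation profile anchored at boundaries
#'
#' @param track an `insulation_track`.
#' @param boundaries boundary table (needs `bin` column), e.g. from
#'   [find_boundaries()].
#' @param flank_bins bins on either side of each boundary; default 10.
#' @return numeric vector of length `2 * flank_bins + 1` (mean score by
#'   offset, NA-aware).
#' @export
boundary_insulation_profile <- function(track, boundaries, flank_bins = 10) {
  offs <- -flank_bins:flank_bins
  n <- nrow(track)
  prof <- vapply(offs, function(o) {
    at <- boundaries$bin + o
    ok <- at >= 1 & at <= n & track$chrom[pmin(pmax(at, 1), n)] == boundaries$chrom
    mean(track$score[at[ok]], na.rm = TRUE)
  }, 0)
  names(prof) <- offs
  prof
}

#' Domain strength of one TAD
#'
#' log2 of the mean intra-domain O/E over the mean O/E between the domain
#' and its equal-length upstream and downstream flanks. 0 for a featureless
#' matrix; log2(b) for a planted multiplicative boost b.
#'
#' @param cm a balanced `contact_matrix`.
#' @param domain one-row data.frame(chrom, start, end).
#' @param oe optional precomputed O/E matrix.
#' @return strength scalar (log2).
#' @export
domain_strength <- function(cm, domain, oe = NULL) {
  if (is.null(oe)) oe <- observed_over_expected(cm)
  ch <- domain$chrom[1]
  idx <- which(cm$bins$chrom == ch)
  inside <- idx[cm$bins$start[idx] >= domain$start[1] &
                  cm$bins$start[idx] < domain$end[1]]
  nb <- length(inside)
  if (nb < 1) stop("domain covers no bins")
  up <- (min(inside) - nb):(min(inside) - 1)
  dn <- (max(inside) + 1):(max(inside) + nb)
  if (min(up) < min(idx) || max(dn) > max(idx))
    stop("equal-length flanks unavailable at the chromosome edge")
  intra <- oe[inside, inside]
  intra_mean <- mean(intra[upper.tri(intra)], na.rm = TRUE)
  flank_vals <- c(oe[inside, up], oe[inside, dn])
  flank_mean <- mean(flank_vals, na.rm = TRUE)
  log2(intra_mean / flank_mean)
}

#' Domain-strength dynamics across stages
#'
#' Computes [domain_strength()] for a shared domain set (defined in one
#' reference stage) in every stage matrix, and summarizes each domain's
#' series by its relative variance (variance of the per-stage strengths
#' divided by their mean).
#'
#' @param matrices named list of balanced `contact_matrix` objects (stages).
#' @param tads shared `tad_set` or domains data.frame.
#' @return list with `strengths` (domains x stages matrix) and `dynamics`
#'   data.frame(chrom, start, end, mean, variance, relative_variance),
#'   ranked by decreasing relative variance.
#' @export
strength_dynamics <- function(matrices, tads) {
  doms <- if (inherits(tads, "tad_set")) tads$domains else tads
  if (nrow(doms) < 1) stop("need at least one domain")
  s <- matrix(NA_real_, nrow(doms), length(matrices))
  colnames(s) <- names(matrices)
  for (j in seq_along(matrices)) {
    oe <- observed_over_expected(matrices[[j]])
    for (k in seq_len(nrow(doms)))
      s[k, j] <- tryCatch(domain_strength(matrices[[j]], doms[k, ], oe = oe),
                          error = function(e) NA_real_)
  }
  mu <- rowMeans(s)
  va <- apply(s, 1, stats::var)
  dyn <- data.frame(doms[, c("chrom", "start", "end")], mean = mu,
                    variance = va, relative_variance = va / mu)
  dyn <- dyn[order(-dyn$relative_variance), ]
  rownames(dyn) <- NULL
  list(strengths = s, dynamics = dyn)
}

#' Inter-TAD contact proportions by distance window
#'
#' An inter-TAD pair is a cis bin pair whose two bins lie in two different
#' domains. For each separation window `(edge_k, edge_{k+1}]` the proportion
#' is the inter-TAD contact sum in that window divided by the total unmasked
#' cis contact sum. Append `Inf` to the edges for an open-ended class (e.g.
#' "> 80 Mb").
#'
#' @param cm a `contact_matrix`.
#' @param tads `tad_set` or domains data.frame (non-overlapping).
#' @param window_edges increasing separation edges in bp; default
#'   c(0, 20e6, 40e6, 60e6, 80e6, Inf).
#' @param use matrix selector; default raw counts.
#' @return data.frame(start_bp, end_bp, proportion, inter_tad_sum).
#' @export
inter_tad_distance_proportions <- function(cm, tads,
                                           window_edges = c(0, 20e6, 40e6,
                                                            60e6, 80e6, Inf),
                                           use = "counts") {
  doms <- if (inherits(tads, "tad_set")) tads$domains else tads
  if (is.unsorted(window_edges, strictly = TRUE))
    stop("window edges must be strictly increasing")
  for (ch in unique(doms$chrom)) {
    dd <- doms[doms$chrom == ch, ]
    dd <- dd[order(dd$start), ]
    if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)]))
      stop("overlapping domains on ", ch)
  }
  m <- working_matrix(cm, use)
  sep <- separation_matrix(cm)
  dom_id <- rep(NA_integer_, nrow(cm$bins))
  for (k in seq_len(nrow(doms))) {
    hit <- cm$bins$chrom == doms$chrom[k] &
      cm$bins$start >= doms$start[k] & cm$bins$start < doms$end[k]
    dom_id[hit] <- k
  }
  keep <- upper.tri(m) & !is.na(sep) & sep > 0 & pair_valid(cm) & !is.na(m)
  total <- sum(m[keep])
  ia <- matrix(dom_id, nrow(m), ncol(m)); ib <- t(ia)
  inter <- keep & !is.na(ia) & !is.na(ib) & ia != ib
  k <- length(window_edges) - 1
  sums <- numeric(k)
  for (w in seq_len(k)) {
    sel <- inter & sep > window_edges[w] & sep <= window_edges[w + 1]
    sums[w] <- sum(m[sel])
  }
  data.frame(start_bp = window_edges[-length(window_edges)],
             end_bp = window_edges[-1],
             proportion = if (total > 0) sums / total else rep(NA_real_, k),
             inter_tad_sum = sums)
}
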