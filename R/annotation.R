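# Interval arithmetic over BED-like labeled sets: parsing, merging,
# coverage fold-enrichment of states against features, track aggregation
# over intervals, and interval-size distributions. Interval overlap is
# delegated to GenomicRanges/IRanges; all public coordinates stay 0-based
# half-open.

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_df0 <- function(gr, label = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  if (!is.null(label)) df$label <- label
  df
}

#' Read a BED3+ file as a labeled interval set
#'
#' @param path BED file (tab-separated, no header; optional 4th column is
#'   the label).
#' @param genome optional `genome_spec` for bounds checking.
#' @return data.frame(chrom, start, end, label), sorted by (chrom, start).
#' @export
read_bed <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    label = if (ncol(df) >= 4) as.character(df[[4]]) else ".")
  if (any(out$start >= out$end)) stop("interval with start >= end")
  if (!is.null(genome)) {
    if (!all(out$chrom %in% names(genome$chrom_lengths)))
      stop("unknown chromosome in BED file")
    if (any(out$end > genome$chrom_lengths[out$chrom]))
      stop("interval beyond chromosome end")
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write intervals as BED
#'
#' @param intervals data.frame(chrom, start, end[, label]).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$label)) df[[4]] <- intervals$label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals per label
#'
#' Overlapping and bookended intervals sharing a label are merged;
#' different labels never merge. Output is sorted.
#'
#' @param intervals data.frame(chrom, start, end, label).
#' @return merged data.frame in the same shape.
#' @export
merge_intervals <- function(intervals) {
  if (is.null(intervals$label)) intervals$label <- "."
  parts <- lapply(split(intervals, intervals$label), function(g) {
    granges_to_df0(GenomicRanges::reduce(as_granges0(g)), label = g$label[1])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

total_bp <- function(df) sum(df$end - df$start)

# total overlap bp between two 0-based sets (each merged internally first)
overlap_bp <- function(a, b) {
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
}

#' Coverage fold-enrichment of states against features
#'
#' For every (state label, feature label) pair:
#' `(overlap bp / state bp) / (feature bp / genome bp)` — the factor by
#' which the state's composition is enriched in the feature relative to the
#' genome-wide expectation. 1 means genome-like composition.
#'
#' @param states,features data.frame(chrom, start, end, label).
#' @param genome a `genome_spec` (supplies the genome size).
#' @return list with `enrichment` (states x features matrix), `overlap_bp`
#'   matrix, `state_bp`, `feature_bp`, `genome_bp`.
#' @export
coverage_fold_enrichment <- function(states, features, genome) {
  genome_bp <- sum(genome$chrom_lengths)
  if (nrow(states) == 0) stop("state with zero bp")
  if (nrow(features) == 0) stop("feature with zero bp")
  slabs <- sort(unique(states$label))
  flabs <- sort(unique(features$label))
  smerged <- lapply(slabs, function(l)
    merge_intervals(states[states$label == l, ]))
  fmerged <- lapply(flabs, function(l)
    merge_intervals(features[features$label == l, ]))
  names(smerged) <- slabs; names(fmerged) <- flabs
  sbp <- vapply(smerged, total_bp, 0)
  fbp <- vapply(fmerged, total_bp, 0)
  if (any(sbp == 0)) stop("state with zero bp")
  if (any(fbp == 0)) stop("feature with zero bp")
  ov <- matrix(0, length(slabs), length(flabs),
               dimnames = list(slabs, flabs))
  for (s in slabs) for (f in flabs)
    ov[s, f] <- overlap_bp(smerged[[s]], fmerged[[f]])
  enr <- sweep(ov, 1, sbp, "/")
  enr <- sweep(enr, 2, fbp / genome_bp, "/")
  list(enrichment = enr, overlap_bp = ov, state_bp = sbp, feature_bp = fbp,
       genome_bp = genome_bp)
}

# TRUE for bins covered by intervals over at least min_overlap of their
# width
bin_in_intervals <- function(bins, intervals, min_overlap = 0.5) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(FALSE, nrow(bins)))
  gb <- as_granges0(bins)
  gi <- GenomicRanges::reduce(as_granges0(intervals))
  cov <- rep(0, nrow(bins))
  hits <- GenomicRanges::findOverlaps(gb, gi)
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    ow <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gb)[qh], IRanges::ranges(gi)[S4Vectors::subjectHits(hits)]))
    cov <- cov + as.numeric(tapply(ow, factor(qh, levels = seq_len(nrow(bins))),
                                   sum, default = 0))
    cov[is.na(cov)] <- 0
  }
  cov / (bins$end - bins$start) >= min_overlap
}

#' Aggregate a per-bin track over intervals
#'
#' Each interval's value is the overlap-bp-weighted mean of the bin values
#' it covers; intervals touching no defined bin get NA.
#'
#' @param track per-bin numeric values.
#' @param genome the `genome_spec` defining the bin grid of `track`.
#' @param intervals data.frame(chrom, start, end[, label]).
#' @return the intervals data.frame with a `mean` column appended.
#' @export
aggregate_track_over_intervals <- function(track, genome, intervals) {
  bins <- genome_bins(genome)
  stopifnot(length(track) == nrow(bins))
  gb <- as_granges0(bins)
  gi <- as_granges0(intervals)
  hits <- GenomicRanges::findOverlaps(gi, gb)
  out <- intervals
  out$mean <- NA_real_
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gi)[qh],
                                            IRanges::ranges(gb)[sh]))
    v <- track[sh]
    ok <- !is.na(v)
    num <- tapply(w[ok] * v[ok], factor(qh[ok], levels = seq_len(nrow(intervals))),
                  sum)
    den <- tapply(w[ok], factor(qh[ok], levels = seq_len(nrow(intervals))), sum)
    out$mean <- as.numeric(num) / as.numeric(den)
  }
  out
}

#' Interval size distribution on a log10 scale
#'
#' @param intervals data.frame(chrom, start, end).
#' @return list with `log10_size` (per interval) and `summary` (quantiles
#'   0, .25, .5, .75, 1 of the log10 sizes).
#' @export
interval_size_distribution <- function(intervals) {
  if (nrow(intervals) == 0) stop("empty interval set")
  sz <- log10(intervals$end - intervals$start)
  list(log10_size = sz,
       summary = stats::quantile(sz, c(0, 0.25, 0.5, 0.75, 1)))
}
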