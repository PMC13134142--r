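# Shared fixtures: tiny genomes, deterministic matrices, and planted-truth
# synthetic builders used across the suite.

toy_genome <- function(nbins = 10, res = 1e6, chroms = c(chr1 = NA)) {
  lens <- rep(nbins * res, length(chroms))
  names(lens) <- names(chroms)
  genome_spec(lens, res)
}

# contact matrix with constant off-diagonal counts
uniform_cm <- function(nbins = 10, res = 1e6, value = 1, chroms = 1) {
  nm <- paste0("chr", seq_len(chroms))
  g <- genome_spec(stats::setNames(rep(nbins * res, chroms), nm), res)
  n <- n_bins(g)
  m <- matrix(value, n, n)
  diag(m) <- 0
  contact_matrix(g, m)
}

# random symmetric positive matrix (counts-like), seeded
random_cm <- function(nbins = 50, res = 1e6, seed = 1, chroms = 1,
                      lambda = 20) {
  set.seed(seed)
  nm <- paste0("chr", seq_len(chroms))
  g <- genome_spec(stats::setNames(rep(nbins * res, chroms), nm), res)
  n <- n_bins(g)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- rpois(sum(ut), lambda) + 1
  m <- m + t(m)
  contact_matrix(g, m)
}

# checkerboard stage on one chromosome; random_profile draws a seeded
# +1/-1 profile with no positional autocorrelation instead of fixed blocks
checker_stage <- function(nbins = 200, s = 0.4, depth = 2e6, seed = 1,
                          block = 5, alpha = 1, label = "stage",
                          random_profile = FALSE, ...) {
  prof <- if (random_profile) {
    set.seed(seed + 5000)
    sample(c(1, -1), nbins, replace = TRUE)
  } else rep(rep(c(1, -1), each = block), length.out = nbins)
  stage_spec(label, alpha = alpha, profile = prof, s = s, depth = depth,
             seed = seed, ...)
}

# tiling TAD fixture at 50-kb resolution: sizes drawn in [150, 500] kb
tad_fixture <- function(seed = 1, chrom_len = 10e6, b = 2, depth = 2e6,
                        alpha = 1) {
  set.seed(seed)
  sizes <- c(); pos <- 0
  while (pos < chrom_len - 5e5) {
    sz <- sample(seq(150e3, 500e3, by = 50e3), 1)
    sizes <- c(sizes, sz); pos <- pos + sz
  }
  starts <- cumsum(c(0, sizes[-length(sizes)]))
  tads <- data.frame(chrom = "chr1", start = starts, end = starts + sizes)
  g <- genome_spec(c(chr1 = chrom_len), 50e3)
  st <- stage_spec("tadstage", alpha = alpha, profile = rep(1, n_bins(g)),
                   s = 0, tads = tads, tad_boost = b, depth = depth,
                   seed = seed + 1000)
  list(genome = g, tads = tads, stage = st,
       boundaries_bp = starts[-1])
}

# uniform-in-ball ensemble with many beads for Monte-Carlo style checks
ball_ensemble <- function(n_beads = 1e5, n_models = 1, radius = 5,
                          beta = 0, lad_frac = 0, seed = 1,
                          degraded_fraction = 0) {
  reps <- ceiling(n_beads / 100)
  bb <- genome_bins(genome_spec(c(chr1 = 100e6), 1e6))[, 1:3]
  bb <- do.call(rbind, replicate(reps, bb, simplify = FALSE))[seq_len(n_beads), ]
  lad <- rep(FALSE, n_beads)
  if (lad_frac > 0) lad[seq_len(round(lad_frac * n_beads))] <- TRUE
  simulate_bead_ensemble(ensemble_spec(
    n_models = n_models, bead_bins = bb, lad_flag = lad, radius = radius,
    beta = beta, degraded_fraction = degraded_fraction, seed = seed))
}
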