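# Synthetic multi-stage Hi-C generator. Every emitted object carries its
# planted truth (compartment profile, switch table, TAD intervals, LAD
# flags), so each downstream statistic can be tested for recovery without
# any external data.

# evaluate expr with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify one synthetic Hi-C stage
#'
#' Defines the expected-count model for one stage of a differentiation
#' series. Expected cis contact between bins i and j on one chromosome is
#' multiplicative: `(|i-j|)^-alpha * (1 + s * p_i * p_j)`, times `tad_boost`
#' if both bins fall in the same planted TAD, times `long_range_boost` if
#' the bin-start separation exceeds `long_range_cutoff`. Expected trans
#' contact is `trans_level * (1 + s * p_i * p_j)`. Expectations are scaled
#' so their genome-wide sum equals `depth`, then counts are drawn Poisson.
#'
#' @param label stage name (e.g. `"BFU"`, `"Ortho"`).
#' @param alpha distance-decay exponent (> 0).
#' @param profile per-bin compartment profile, values +1 (A-like) / -1
#'   (B-like), length = number of genome bins.
#' @param s compartment strength, `0 <= s < 1`.
#' @param tads data.frame(chrom, start, end) of planted TADs in bp,
#'   non-overlapping within a chromosome; may be NULL.
#' @param tad_boost intra-TAD multiplicative boost `b > 1` (1 = none).
#' @param long_range_boost multiplier `lambda >= 1` for cis pairs separated
#'   by more than `long_range_cutoff` bp.
#' @param long_range_cutoff separation cutoff in bp for the boost.
#' @param trans_level relative trans contact level `tau >= 0`.
#' @param depth expected total count over all bin pairs.
#' @param seed RNG seed for this stage's Poisson draw.
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(label, alpha = 1, profile, s = 0.4, tads = NULL,
                       tad_boost = 1, long_range_boost = 1,
                       long_range_cutoff = 50e6, trans_level = 0,
                       depth = 1e6, seed = 1) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (s < 0 || s >= 1) stop("s must satisfy 0 <= s < 1 (expected counts stay positive)")
  if (tad_boost < 1) stop("tad_boost must be >= 1")
  if (long_range_boost < 1) stop("long_range_boost must be >= 1")
  if (trans_level < 0) stop("trans_level must be >= 0")
  if (!all(profile %in% c(-1, 1))) stop("profile values must be +1 or -1")
  if (!is.null(tads)) {
    for (ch in unique(tads$chrom)) {
      tt <- tads[tads$chrom == ch, ]
      tt <- tt[order(tt$start), ]
      if (nrow(tt) > 1 && any(tt$start[-1] < tt$end[-nrow(tt)]))
        stop("planted TADs overlap on ", ch)
    }
  }
  structure(list(label = label, alpha = alpha, profile = profile, s = s,
                 tads = tads, tad_boost = tad_boost,
                 long_range_boost = long_range_boost,
                 long_range_cutoff = long_range_cutoff,
                 trans_level = trans_level, depth = depth, seed = seed),
            class = "stage_spec")
}

# per-bin TAD id (NA outside any planted TAD); a bin belongs to a TAD when
# its start lies inside the interval
tad_id_per_bin <- function(bins, tads) {
  id <- rep(NA_integer_, nrow(bins))
  if (is.null(tads) || nrow(tads) == 0) return(id)
  for (k in seq_len(nrow(tads))) {
    hit <- bins$chrom == tads$chrom[k] &
      bins$start >= tads$start[k] & bins$start < tads$end[k]
    id[hit] <- k
  }
  id
}

#' Expected (noise-free) contact matrix of a stage
#'
#' The closed-form expectation of [simulate_contact_matrix()], scaled to the
#' stage's depth. Useful as an analytic oracle.
#'
#' @param genome a `genome_spec`.
#' @param stage a `stage_spec`.
#' @return numeric matrix of expected counts (symmetric, zero diagonal).
#' @export
expected_contact_matrix <- function(genome, stage) {
  bins <- genome_bins(genome)
  n <- nrow(bins)
  if (length(stage$profile) != n)
    stop("profile length (", length(stage$profile),
         ") does not match bin count (", n, ")")
  p <- stage$profile
  same <- outer(bins$chrom, bins$chrom, "==")
  dbin <- abs(outer(seq_len(n), seq_len(n), "-"))
  # chromosome-local bin separation (global index distance equals local
  # distance within a chromosome because bins are dense and sorted)
  comp <- 1 + stage$s * outer(p, p)
  e <- matrix(0, n, n)
  cis <- same & dbin > 0
  e[cis] <- (dbin[cis]^(-stage$alpha)) * comp[cis]
  sep_bp <- abs(outer(bins$start, bins$start, "-"))
  boost <- cis & sep_bp > stage$long_range_cutoff
  e[boost] <- e[boost] * stage$long_range_boost
  tid <- tad_id_per_bin(bins, stage$tads)
  if (any(!is.na(tid)) && stage$tad_boost != 1) {
    same_tad <- outer(tid, tid, function(a, b) !is.na(a) & !is.na(b) & a == b)
    intra <- cis & same_tad
    e[intra] <- e[intra] * stage$tad_boost
  }
  if (stage$trans_level > 0) e[!same] <- stage$trans_level * comp[!same]
  diag(e) <- 0
  tot <- sum(e[upper.tri(e)])
  if (tot > 0) e <- e * (stage$depth / tot)
  e
}

#' Simulate a Poisson contact matrix for one stage
#'
#' Draws counts from independent Poisson laws with the means of
#' [expected_contact_matrix()] (upper triangle, then symmetrized; zero
#' diagonal). Identical seed gives a bit-identical matrix. The planted truth
#' (profile, TADs, stage spec) is attached as the `truth` field.
#'
#' @param genome a `genome_spec`.
#' @param stage a `stage_spec`.
#' @return a `contact_matrix` with a `truth` list field.
#' @export
simulate_contact_matrix <- function(genome, stage) {
  e <- expected_contact_matrix(genome, stage)
  n <- nrow(e)
  ut <- upper.tri(e)
  counts <- matrix(0, n, n)
  counts[ut] <- with_seed(stage$seed, stats::rpois(sum(ut), e[ut]))
  counts <- counts + t(counts)
  cm <- contact_matrix(genome, counts)
  cm$truth <- list(profile = stage$profile, tads = stage$tads, stage = stage)
  cm
}

#' Simulate a multi-stage series with planted compartment switching
#'
#' The first stage uses its own compartment profile; at each consecutive
#' transition a seeded random subset of bins (fraction `switch_fraction`,
#' count = `round(fraction * n_bins)`) flips sign. `ab_bias` sets the share
#' of flips taken from currently-A bins (A->B switches); 0.5 is symmetric.
#'
#' @param genome a `genome_spec`.
#' @param stages list of `stage_spec` (>= 1); profiles of stages after the
#'   first are overwritten by the switching process.
#' @param switch_fraction fraction of bins flipped per transition, `[0, 1)`.
#' @param ab_bias proportion of flipped bins drawn from A bins; default 0.5.
#' @return list with `matrices` (list of `contact_matrix`), `profiles`
#'   (per-stage signed profiles), and `switch_truth`: a data.frame of
#'   (transition, bin, category) with category in A>A, A>B, B>A, B>B.
#' @export
simulate_stage_series <- function(genome, stages, switch_fraction = 0.02,
                                  ab_bias = 0.5) {
  if (length(stages) == 0) stop("empty stage list")
  if (switch_fraction < 0 || switch_fraction >= 1)
    stop("switch_fraction must be in [0, 1)")
  nb <- n_bins(genome)
  profiles <- vector("list", length(stages))
  profiles[[1]] <- stages[[1]]$profile
  truth <- list()
  if (length(stages) > 1) {
    for (k in 2:length(stages)) {
      prev <- profiles[[k - 1]]
      n_flip <- round(switch_fraction * nb)
      flip <- with_seed(stages[[k]]$seed + 104729L, {
        a_bins <- which(prev == 1)
        b_bins <- which(prev == -1)
        n_ab <- min(round(ab_bias * n_flip), length(a_bins))
        n_ba <- min(n_flip - n_ab, length(b_bins))
        c(sample(a_bins, n_ab), sample(b_bins, n_ba))
      })
      cur <- prev
      cur[flip] <- -cur[flip]
      profiles[[k]] <- cur
      cat_lab <- ifelse(prev == 1,
                        ifelse(cur == 1, "A>A", "A>B"),
                        ifelse(cur == 1, "B>A", "B>B"))
      truth[[k - 1]] <- data.frame(
        transition = paste(stages[[k - 1]]$label, stages[[k]]$label, sep = ">"),
        bin = seq_len(nb), category = cat_lab, stringsAsFactors = FALSE)
    }
  }
  mats <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    st$profile <- profiles[[k]]
    mats[[k]] <- simulate_contact_matrix(genome, st)
  }
  names(mats) <- vapply(stages, `[[`, "", "label")
  list(matrices = mats, profiles = profiles,
       switch_truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(transition = character(0), bin = integer(0),
                    category = character(0)))
}

#' Specify a synthetic bead-model ensemble
#'
#' @param n_models number of simulated nuclei (>= 1).
#' @param bead_bins data.frame(chrom, start, end) of the genomic bin each
#'   bead represents (typically 1 Mb bins).
#' @param lad_flag logical per bead: is it in a LAD?
#' @param radius nominal nuclear radius (arbitrary units).
#' @param beta peripheral bias for LAD beads (>= 0; 0 = uniform). LAD radial
#'   positions are drawn with density proportional to r^(2 + beta), so the
#'   mean relative radius is (3 + beta) / (4 + beta); beta = 0 recovers the
#'   uniform-ball 3/4.
#' @param degraded_fraction fraction of models emitted deliberately broken
#'   for QC testing (alternately: < 20 valid beads, or coordinates inflated
#'   10x).
#' @param seed RNG seed.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models, bead_bins, lad_flag = NULL, radius = 5,
                          beta = 0, degraded_fraction = 0, seed = 1) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  if (is.null(lad_flag)) lad_flag <- rep(FALSE, nrow(bead_bins))
  stopifnot(length(lad_flag) == nrow(bead_bins))
  structure(list(n_models = n_models, bead_bins = bead_bins,
                 lad_flag = lad_flag, radius = radius, beta = beta,
                 degraded_fraction = degraded_fraction, seed = seed),
            class = "ensemble_spec")
}

# one uniform-in-ball / biased draw of bead positions
draw_bead_positions <- function(nb, radius, lad, beta) {
  dir <- matrix(stats::rnorm(3 * nb), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  u <- stats::runif(nb)
  expo <- ifelse(lad, 1 / (3 + beta), 1 / 3)
  r <- radius * u^expo
  dir * r
}

#' Simulate a bead-model ensemble
#'
#' Non-LAD beads are uniform in the ball of the nominal radius; LAD beads
#' are tilted outward by `beta` (see [ensemble_spec()]). A seeded subset of
#' models is emitted degraded (too few valid beads, or a 10x inflated
#' radius) so that QC filtering is testable. Identical seed, identical
#' ensemble.
#'
#' @param spec an `ensemble_spec`.
#' @return a `bead_ensemble`: list of models, each a list with `id` and a
#'   `beads` data.frame (chrom, start, end, x, y, z, valid, lad); plus
#'   `degraded` (integer ids of planted-broken models) and the spec.
#' @export
simulate_bead_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  nb <- nrow(spec$bead_bins)
  n_deg <- round(spec$degraded_fraction * spec$n_models)
  with_seed(spec$seed, {
    deg_ids <- if (n_deg > 0) sort(sample(spec$n_models, n_deg)) else integer(0)
    models <- vector("list", spec$n_models)
    for (m in seq_len(spec$n_models)) {
      xyz <- draw_bead_positions(nb, spec$radius, spec$lad_flag, spec$beta)
      valid <- rep(TRUE, nb)
      if (m %in% deg_ids) {
        if (match(m, deg_ids) %% 2 == 1) {
          # too few valid beads: keep 19 (one under the QC default)
          drop <- if (nb > 19) 20:nb else seq_len(nb)
          xyz[drop, ] <- NA_real_
          valid[drop] <- FALSE
        } else {
          xyz <- xyz * 10  # inflated radius; caught by SD-based filtering
        }
      }
      models[[m]] <- list(id = sprintf("model_%03d", m),
                          beads = data.frame(spec$bead_bins,
                                             x = xyz[, 1], y = xyz[, 2],
                                             z = xyz[, 3], valid = valid,
                                             lad = spec$lad_flag))
    }
    structure(list(models = models, degraded = deg_ids, spec = spec),
              class = "bead_ensemble")
  })
}

#' Generate annotation fixtures: states, features, LADs, and a lamin-like track
#'
#' Emits, deterministically under the seed: a chromatin-"state" partition of
#' the genome (7 labels), feature intervals (CpG-island / exon / TSS / TES
#' -like categories), LAD intervals with log-spread sizes (well over one
#' order of magnitude), and a per-bin log2 ChIP/input-like track carrying a
#' planted +`lad_shift` mean shift inside LADs over unit-SD Gaussian noise.
#'
#' @param genome a `genome_spec`.
#' @param seed RNG seed.
#' @param lad_shift planted track shift inside LADs; default 0.5.
#' @return list with `states`, `features`, `lads` (data.frames of chrom,
#'   start, end, label) and `track` (per-bin numeric).
#' @export
make_annotation_fixture <- function(genome, seed = 1, lad_shift = 0.5) {
  bins <- genome_bins(genome)
  with_seed(seed, {
    states <- list(); feats <- list(); lads <- list()
    for (ch in names(genome$chrom_lengths)) {
      len <- genome$chrom_lengths[[ch]]
      # state partition: random segment lengths, labels state1..state7
      cuts <- sort(sample(seq(1e5, len - 1e5, by = 1e5),
                          min(30, max(2, floor(len / 3e6)))))
      edges <- unique(c(0, cuts, len))
      states[[ch]] <- data.frame(
        chrom = ch, start = edges[-length(edges)], end = edges[-1],
        label = paste0("state", sample(1:7, length(edges) - 1, replace = TRUE)))
      # feature intervals: short, category-labelled, within bounds
      fl <- lapply(c("CpG", "exon", "TSS", "TES"), function(lab) {
        k <- 25
        w <- sample(c(2e3, 5e3, 1e4), k, replace = TRUE)
        st <- sort(sample(seq(0, len - max(w), by = 1e4), k))
        data.frame(chrom = ch, start = st, end = pmin(st + w, len), label = lab)
      })
      feats[[ch]] <- do.call(rbind, fl)
      # LADs: log-uniform sizes 100 kb .. ~3.2 Mb, non-overlapping; ~50
      # candidates per chromosome so a two-chromosome genome carries on the
      # order of 100 LADs, the scale at which shift detection is tested
      n_lads <- 50
      sizes <- round(10^stats::runif(n_lads, 5, 6.5))
      anchors <- sort(sample(seq(0, len - max(sizes), length.out = 4 * n_lads),
                             n_lads))
      st <- pmin(anchors, len - sizes)
      lad <- data.frame(chrom = ch, start = st, end = st + sizes, label = "LAD")
      lad <- lad[order(lad$start), ]
      keep <- rep(TRUE, nrow(lad)); last_end <- -1
      for (i in seq_len(nrow(lad))) {
        if (lad$start[i] < last_end) keep[i] <- FALSE
        else last_end <- lad$end[i]
      }
      lads[[ch]] <- lad[keep, ]
    }
    states <- do.call(rbind, states); rownames(states) <- NULL
    feats <- do.call(rbind, feats); rownames(feats) <- NULL
    lads <- do.call(rbind, lads); rownames(lads) <- NULL
    in_lad <- bin_in_intervals(bins, lads, min_overlap = 0.5)
    track <- stats::rnorm(nrow(bins)) + ifelse(in_lad, lad_shift, 0)
    # lad_bins is the planted truth of which bins received the shift
    list(states = states, features = feats, lads = lads, track = track,
         lad_bins = in_lad)
  })
}

#' Write the annotation fixture to disk (BED + bedGraph)
#'
#' @param fix output of [make_annotation_fixture()].
#' @param genome the `genome_spec` used to build it.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written.
#' @export
write_annotation_fixture <- function(fix, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(states = file.path(dir, "states.bed"),
             features = file.path(dir, "features.bed"),
             lads = file.path(dir, "lads.bed"),
             track = file.path(dir, "track.bedgraph"))
  for (nm in c("states", "features", "lads")) write_bed(fix[[nm]], paths[[nm]])
  write_bedgraph(fix$track, genome_bins(genome), paths[["track"]])
  paths
}
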