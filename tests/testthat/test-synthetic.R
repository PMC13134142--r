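test_that("genome bin grid is dense, sorted, and sized by ceiling", {
  g <- genome_spec(c(chr1 = 10.5e6, chr2 = 3e6), 1e6)
  b <- genome_bins(g)
  expect_equal(n_bins(g), 14)
  expect_equal(b$index, seq_len(14))
  expect_equal(b$end[11], 10.5e6)  # last bin truncated at chromosome end
  expect_true(all(b$start < b$end))
  expect_error(genome_spec(c(chr1 = -1), 1e6), "lengths")
  expect_error(genome_spec(c(chr1 = 1e6), 0), "resolution")
})

test_that("simulated matrices are symmetric, integer, non-negative, zero-diagonal", {
  g <- toy_genome(40, chroms = c(chr1 = NA, chr2 = NA))
  st <- checker_stage(80, s = 0.3, depth = 5e5, seed = 7, trans_level = 0.05)
  cm <- simulate_contact_matrix(g, st)
  expect_identical(cm$counts, t(cm$counts))
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  expect_true(all(diag(cm$counts) == 0))
})

test_that("same seed gives bit-identical matrices; profile mismatch errors", {
  g <- toy_genome(30)
  st <- checker_stage(30, seed = 11, depth = 1e5)
  expect_identical(simulate_contact_matrix(g, st)$counts,
                   simulate_contact_matrix(g, st)$counts)
  st_bad <- checker_stage(29, seed = 11)
  expect_error(simulate_contact_matrix(g, st_bad), "profile length")
  expect_error(stage_spec("x", profile = rep(1, 10), s = 1), "s must")
})

test_that("per-diagonal means follow the closed-form power-law expectation", {
  g <- toy_genome(100)
  st <- checker_stage(100, s = 0, depth = 2e6, seed = 3)
  e <- expected_contact_matrix(g, st)
  cm <- simulate_contact_matrix(g, st)
  # all expected values on one diagonal are equal when s = 0, b = 1
  for (d in c(1, 5, 20)) {
    i <- seq_len(100 - d)
    evals <- e[cbind(i, i + d)]
    expect_lt(diff(range(evals)), 1e-9)
    realized <- mean(cm$counts[cbind(i, i + d)])
    se <- sqrt(evals[1] / length(i))
    expect_lt(abs(realized - evals[1]), 3.3 * se)
  }
  # expectations non-increasing with distance when no long-range boost
  dmeans <- vapply(1:99, function(d) e[1, 1 + d], 0)
  expect_true(all(diff(dmeans) <= 1e-12))
})

test_that("O/E of same-label pairs approaches 1+s, opposite-label 1-s", {
  # random profiles keep the per-distance expectation unmodulated, so the
  # distance-normalized class means converge to 1 +/- s
  g <- toy_genome(60)
  s <- 0.5
  ratios <- vapply(1:20, function(seed) {
    st <- checker_stage(60, s = s, depth = 4e5, seed = seed,
                        random_profile = TRUE)
    cm <- simulate_contact_matrix(g, st)
    oe <- observed_over_expected(cm, use = "counts")
    p <- st$profile
    same <- outer(p, p) > 0 & upper.tri(oe)
    opp <- outer(p, p) < 0 & upper.tri(oe)
    c(mean(oe[same], na.rm = TRUE), mean(oe[opp], na.rm = TRUE))
  }, c(0, 0))
  expect_equal(mean(ratios[1, ]), 1 + s, tolerance = 0.05)
  expect_equal(mean(ratios[2, ]), 1 - s, tolerance = 0.05)
})

test_that("stage series plants the requested number of switches", {
  g <- toy_genome(2000, res = 1e5)
  stages <- lapply(1:3, function(k)
    checker_stage(2000, depth = 1e5, seed = k, label = paste0("st", k)))
  ser <- simulate_stage_series(g, stages, switch_fraction = 0.02)
  expect_length(unique(ser$switch_truth$transition), 2)
  for (tr in unique(ser$switch_truth$transition)) {
    tt <- ser$switch_truth[ser$switch_truth$transition == tr, ]
    expect_equal(sum(tt$category %in% c("A>B", "B>A")), 40)  # round(.02*2000)
  }
  # zero switching plants nothing
  ser0 <- simulate_stage_series(g, stages, switch_fraction = 0)
  expect_false(any(ser0$switch_truth$category %in% c("A>B", "B>A")))
  expect_error(simulate_stage_series(g, list(), 0.02), "empty")
})

test_that("flipped-bin sets differ across transitions with different seeds", {
  g <- toy_genome(500, res = 1e5)
  stages <- lapply(1:3, function(k)
    checker_stage(500, depth = 5e4, seed = 10 * k, label = paste0("st", k)))
  ser <- simulate_stage_series(g, stages, switch_fraction = 0.05)
  flips <- lapply(split(ser$switch_truth, ser$switch_truth$transition),
                  function(tt) tt$bin[tt$category %in% c("A>B", "B>A")])
  expect_false(setequal(flips[[1]], flips[[2]]))
})

test_that("asymmetric switching favors the planted direction", {
  g <- toy_genome(1000, res = 1e5)
  stages <- lapply(1:2, function(k) checker_stage(1000, depth = 5e4, seed = k))
  ser <- simulate_stage_series(g, stages, switch_fraction = 0.04, ab_bias = 0.8)
  tt <- ser$switch_truth
  expect_gt(sum(tt$category == "A>B"), sum(tt$category == "B>A"))
})

test_that("uniform-ball beads have mean relative radius 3/4; LAD bias is outward", {
  ens <- ball_ensemble(n_beads = 1e5, seed = 21)
  cd <- center_and_distances(ens$models[[1]])
  expect_equal(mean(cd$distances) / 5, 0.75, tolerance = 0.005)
  # strong peripheral bias pushes LAD beads outward
  ens2 <- ball_ensemble(n_beads = 2e4, beta = 10, lad_frac = 0.5, seed = 22)
  b <- ens2$models[[1]]$beads
  d <- center_and_distances(ens2$models[[1]])$distances
  expect_gt(mean(d[b$lad]), mean(d[!b$lad]))
  # beta = 0 leaves LAD beads indistinguishable (uniform placement)
  ens3 <- ball_ensemble(n_beads = 5e4, beta = 0, lad_frac = 0.5, seed = 23)
  d3 <- center_and_distances(ens3$models[[1]])$distances
  b3 <- ens3$models[[1]]$beads
  expect_equal(mean(d3[b3$lad]), mean(d3[!b3$lad]), tolerance = 0.02)
})

test_that("degraded fraction yields exactly that many QC violations", {
  ens <- ball_ensemble(n_beads = 100, n_models = 100,
                       degraded_fraction = 0.1, seed = 5)
  expect_length(ens$degraded, 10)
  qc <- qc_filter(ens)
  expect_equal(nrow(qc$exclusions), 10)
  expect_setequal(qc$exclusions$model, sprintf("model_%03d", ens$degraded))
  # determinism
  ens_b <- ball_ensemble(n_beads = 100, n_models = 100,
                         degraded_fraction = 0.1, seed = 5)
  expect_identical(ens$models[[1]]$beads, ens_b$models[[1]]$beads)
})

test_that("annotation fixture is deterministic, in-bounds, with log-spread LADs", {
  g <- genome_spec(c(chr1 = 60e6, chr2 = 40e6), 1e6)
  f1 <- make_annotation_fixture(g, seed = 4)
  f2 <- make_annotation_fixture(g, seed = 4)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  p1 <- write_annotation_fixture(f1, g, d1)
  p2 <- write_annotation_fixture(f2, g, d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  expect_equal(read_bedgraph(p1[["track"]], g), f1$track, tolerance = 1e-9)
  for (nm in c("states", "features", "lads")) {
    iv <- f1[[nm]]
    expect_true(all(iv$start >= 0))
    expect_true(all(iv$end <= g$chrom_lengths[iv$chrom]))
    expect_true(all(iv$start < iv$end))
  }
  sizes <- f1$lads$end - f1$lads$start
  expect_gte(log10(max(sizes) / min(sizes)), 1)  # spans an order of magnitude
})
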