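cube_model <- function(a = 2, offset = c(0, 0, 0)) {
  corners <- as.matrix(expand.grid(c(-a, a), c(-a, a), c(-a, a)))
  list(id = "cube",
       beads = data.frame(chrom = "chr1", start = 0:7 * 1e6, end = 1:8 * 1e6,
                          x = corners[, 1] + offset[1],
                          y = corners[, 2] + offset[2],
                          z = corners[, 3] + offset[3], valid = TRUE))
}

test_that("center and distances: single bead, cube symmetry, translation invariance", {
  one <- list(id = "m", beads = data.frame(chrom = "chr1", start = 0, end = 1e6,
                                           x = 3, y = -4, z = 12, valid = TRUE))
  cd <- center_and_distances(one)
  expect_equal(unname(cd$center), c(3, -4, 12))
  expect_equal(cd$distances, 0)
  cd_cube <- center_and_distances(cube_model(a = 2))
  expect_equal(unname(cd_cube$center), c(0, 0, 0))
  expect_equal(cd_cube$distances, rep(2 * sqrt(3), 8))
  shifted <- center_and_distances(cube_model(a = 2, offset = c(10, -5, 7)))
  expect_equal(shifted$distances, cd_cube$distances)
})

test_that("nuclear radius: ties, arithmetic on 1..100, and the uniform-ball value", {
  expect_equal(nuclear_radius(rep(10, 20)), 10)
  expect_equal(nuclear_radius(1:100), 98)  # mean of 96..100
  orc <- oracle_ball_fractions(n = 2e5, R = 1, seed = 42)
  ens <- ball_ensemble(n_beads = 1e5, radius = 5, seed = 77)
  cd <- center_and_distances(ens$models[[1]])
  expect_equal(nuclear_radius(cd$distances) / 5, orc[["radius"]],
               tolerance = 0.005)
  expect_equal(nuclear_radius(cd$distances) / 5, 0.9914, tolerance = 0.005)
})

test_that("QC excludes 19-bead and inflated-radius models with logged reasons", {
  ens <- ball_ensemble(n_beads = 100, n_models = 40,
                       degraded_fraction = 0.1, seed = 12)
  qc <- qc_filter(ens, min_beads = 20, sd_multiplier = 3)
  expect_equal(nrow(qc$exclusions), 4)
  expect_setequal(unique(qc$exclusions$reason),
                  c("min_beads", "radius_outlier"))
  few <- qc$exclusions$model[qc$exclusions$reason == "min_beads"]
  nv <- vapply(ens$models, function(m) sum(m$beads$valid), 0L)
  ids <- vapply(ens$models, `[[`, "", "id")
  expect_true(all(nv[match(few, ids)] == 19))
  expect_length(qc$ensemble$models, 36)
  # homogeneous ensemble: SD rule removes nothing
  clean <- ball_ensemble(n_beads = 100, n_models = 20, seed = 13)
  expect_equal(nrow(qc_filter(clean)$exclusions), 0)
  # a single 10x model among normal ones is an outlier at 3 SD
  mix <- ball_ensemble(n_beads = 100, n_models = 30, seed = 14)
  mix$models[[5]]$beads[, c("x", "y", "z")] <-
    mix$models[[5]]$beads[, c("x", "y", "z")] * 10
  qc2 <- qc_filter(mix, sd_multiplier = 3)
  expect_equal(qc2$exclusions$model, "model_005")
  expect_equal(qc2$exclusions$reason, "radius_outlier")
})

test_that("bead classes: cuts, boundaries, conservation, rigid invariance", {
  expect_equal(classify_beads(c(0, 0.5, 0.85), 1),
               c("center", "intermediate", "peripheral"))
  # boundary values land in intermediate (strict inequalities elsewhere)
  expect_equal(classify_beads(c(0.2, 0.8), 1),
               c("intermediate", "intermediate"))
  expect_equal(classify_beads(1.3, 1), "peripheral")  # beyond radius allowed
  ens <- ball_ensemble(n_beads = 2000, seed = 9)
  m <- ens$models[[1]]
  cd <- center_and_distances(m)
  rad <- nuclear_radius(cd$distances)
  cls <- classify_beads(cd$distances, rad)
  expect_equal(sum(table(cls)), sum(m$beads$valid))
  # rotation about z and uniform scaling leave classes unchanged
  th <- 0.7; rot <- matrix(c(cos(th), -sin(th), 0,
                             sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$beads[, c("x", "y", "z")] <-
    as.matrix(m$beads[, c("x", "y", "z")]) %*% rot * 4.2
  cd2 <- center_and_distances(m2)
  cls2 <- classify_beads(cd2$distances, nuclear_radius(cd2$distances))
  expect_equal(cls2, cls)
})

test_that("uniform-ball class fractions match the Monte-Carlo oracle within 1%", {
  orc <- oracle_ball_fractions(n = 2e5, seed = 101)
  ens <- ball_ensemble(n_beads = 3e4, n_models = 4, seed = 55)
  fr <- rowMeans(vapply(ens$models, function(m) {
    cd <- center_and_distances(m)
    cls <- classify_beads(cd$distances, nuclear_radius(cd$distances))
    c(center = mean(cls == "center"), peripheral = mean(cls == "peripheral"))
  }, c(0, 0)))
  expect_equal(fr[["peripheral"]], orc[["peripheral"]], tolerance = 0.01)
  expect_equal(fr[["center"]], orc[["center"]], tolerance = 0.01)
})

test_that("bead model I/O: TSV round-trip, cmm parsing, invalid beads flagged", {
  ens <- ball_ensemble(n_beads = 30, n_models = 2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_bead_models(ens, path)
  back <- read_bead_models(path, dialect = "tsv")
  expect_length(back$models, 2)
  expect_equal(back$models[[1]]$beads$x, ens$models[[1]]$beads$x,
               tolerance = 1e-6)
  # cmm-like XML: a marker missing z is flagged invalid, not dropped
  cmm <- tempfile(fileext = ".cmm")
  writeLines(c('<marker_set name="nuc1">',
               '<marker chrom="chr1" start="0" end="1000000" x="1" y="2" z="3"/>',
               '<marker chrom="chr1" start="1000000" end="2000000" x="4" y="5"/>',
               '</marker_set>'), cmm)
  ens2 <- read_bead_models(cmm, dialect = "cmm")
  expect_length(ens2$models, 1)
  expect_equal(nrow(ens2$models[[1]]$beads), 2)
  expect_equal(ens2$models[[1]]$beads$valid, c(TRUE, FALSE))
  # duplicated genomic bin within a model is rejected on request
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tx\ty\tz\tmodel",
               "chr1\t0\t1000000\t1\t1\t1\tm1",
               "chr1\t0\t1000000\t2\t2\t2\tm1"), dup)
  expect_error(read_bead_models(dup, "tsv", check_duplicates = TRUE),
               "duplicated genomic bin")
})

test_that("ensemble radial profile averages models and flags LAD bins", {
  g <- genome_spec(c(chr1 = 100e6), 1e6)
  bb <- genome_bins(g)[, 1:3]
  lad_iv <- data.frame(chrom = "chr1", start = 0, end = 30e6)
  lad <- bb$start < 30e6
  spec <- ensemble_spec(n_models = 30, bead_bins = bb, lad_flag = lad,
                        radius = 5, beta = 6, seed = 2)
  ens <- simulate_bead_ensemble(spec)
  prof <- ensemble_radial_profile(ens, g, lad_intervals = lad_iv)
  fr <- prof$frac_center + prof$frac_intermediate + prof$frac_peripheral
  expect_true(all(abs(fr - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(prof$n_models == 30))
  expect_equal(prof$lad, lad)
  expect_gt(mean(prof$mean_rel_dist[prof$lad]),
            mean(prof$mean_rel_dist[!prof$lad]))
  # an ensemble of identical models equals the single-model profile
  ens1 <- simulate_bead_ensemble(
    ensemble_spec(1, bb, lad_flag = lad, radius = 5, beta = 0, seed = 4))
  twice <- ens1; twice$models <- c(ens1$models, ens1$models)
  p1 <- ensemble_radial_profile(ens1, g)
  p2 <- ensemble_radial_profile(twice, g)
  expect_equal(p2$mean_rel_dist, p1$mean_rel_dist)
  expect_equal(p2$frac_peripheral, p1$frac_peripheral)
})
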