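test_that("insulation of a uniform matrix is flat zero and matches the oracle", {
  cm <- uniform_cm(30, res = 50e3)
  ins <- insulation_score(cm, c(150e3, 250e3))
  expect_true(all(abs(ins$score) < 1e-9, na.rm = TRUE))
  # interior bins defined, edges NA
  expect_true(is.na(ins$score[1]))
  rcm <- random_cm(100, res = 50e3, seed = 44)
  ins2 <- insulation_score(rcm, 250e3)  # 5 bins
  expect_equal(ins2$raw_w5, oracle_insulation_raw(rcm, 5, m = rcm$counts),
               tolerance = 1e-12)
  expect_error(insulation_score(uniform_cm(4, res = 50e3), 250e3), "exceeds")
})

test_that("insulation is invariant to global matrix rescaling", {
  rcm <- random_cm(60, res = 50e3, seed = 3)
  ins1 <- insulation_score(rcm, c(150e3, 250e3))
  rcm2 <- rcm; rcm2$counts <- rcm2$counts * 37
  ins2 <- insulation_score(rcm2, c(150e3, 250e3))
  expect_equal(ins1$score, ins2$score, tolerance = 1e-9)
})

test_that("boundary calling: constant track none, planted minima found, shift-invariant", {
  flat <- data.frame(chrom = "chr1", start = 0:49 * 5e4,
                     end = 1:50 * 5e4, score = 0)
  expect_equal(nrow(find_boundaries(flat)$boundaries), 0)
  v <- rep(0, 50); v[c(10, 25, 40)] <- -1
  tr <- flat; tr$score <- v
  fb <- find_boundaries(tr, delta = 0.01)
  expect_equal(fb$boundaries$bin, c(10, 25, 40))
  tr2 <- tr; tr2$score <- tr2$score + 5
  expect_equal(find_boundaries(tr2, delta = 0.01)$boundaries$bin,
               fb$boundaries$bin)
  # shallow dip below delta is rejected
  v3 <- rep(0, 50); v3[20] <- -0.005
  tr3 <- flat; tr3$score <- v3
  expect_equal(nrow(find_boundaries(tr3, delta = 0.01)$boundaries), 0)
  # flat minimum: leftmost bin wins
  v4 <- rep(0, 50); v4[20:22] <- -1
  tr4 <- flat; tr4$score <- v4
  expect_equal(find_boundaries(tr4)$boundaries$bin, 20)
})

test_that("planted TAD boundaries are recovered within one bin", {
  hits <- unlist(lapply(1:10, function(seed) {
    fx <- tad_fixture(seed = seed, b = 2, depth = 2e6)
    cm <- balance_matrix(simulate_contact_matrix(fx$genome, fx$stage))
    ins <- insulation_score(cm, c(150e3, 250e3, 500e3))
    fb <- find_boundaries(ins, delta = 0.01)
    vapply(fx$boundaries_bp, function(b)
      any(abs(fb$boundaries$start - b) <= 50e3), TRUE)
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("boundary recovery degrades as the planted boost approaches one", {
  rec <- vapply(c(1, 1.5, 2), function(b) {
    fx <- tad_fixture(seed = 2, b = b, depth = 2e6)
    cm <- balance_matrix(simulate_contact_matrix(fx$genome, fx$stage))
    ins <- insulation_score(cm, c(150e3, 250e3, 500e3))
    fb <- find_boundaries(ins, delta = 0.01)
    mean(vapply(fx$boundaries_bp, function(bb)
      any(abs(fb$boundaries$start - bb) <= 50e3), TRUE))
  }, 0)
  expect_lt(rec[1], rec[3])
  expect_gte(rec[3], 0.9)
})

test_that("domains outside the size bounds are excluded but boundaries kept", {
  v <- rep(0, 60); v[c(10, 22, 40)] <- -1  # 600 kb and 900 kb gaps at 50 kb
  tr <- data.frame(chrom = "chr1", start = 0:59 * 5e4, end = 1:60 * 5e4,
                   score = v)
  fb <- find_boundaries(tr, min_size = 150e3, max_size = 500e3)
  expect_equal(nrow(fb$boundaries), 3)
  expect_equal(nrow(fb$domains), 0)
  expect_equal(nrow(fb$domains_all), 2)
})

test_that("pileup: flat matrix gives a flat unit map; duplication changes nothing", {
  cm <- uniform_cm(60, res = 50e3)
  dom <- data.frame(chrom = "chr1", start = 1e6, end = 1.5e6)
  px <- tad_pileup(cm, dom, flank_bp = 0.5e6, npx = 30)
  expect_true(all(abs(px - 1) < 1e-9, na.rm = TRUE))
  px3 <- tad_pileup(cm, dom[c(1, 1, 1), ], flank_bp = 0.5e6, npx = 30)
  expect_equal(px, px3, ignore_attr = TRUE)
  # domain at the chromosome edge is skipped, not fatal when others remain
  edge <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(5e5, 1.5e6))
  pxe <- tad_pileup(cm, edge, flank_bp = 0.5e6, npx = 30)
  expect_equal(attr(pxe, "n_domains"), 1)
  expect_length(attr(pxe, "skipped"), 1)
})

test_that("pileup central block reflects the planted intra-TAD boost", {
  g <- genome_spec(c(chr1 = 10e6), 50e3)
  tads <- data.frame(chrom = "chr1", start = c(2e6, 5e6, 8e6),
                     end = c(2.4e6, 5.4e6, 8.4e6))
  st <- stage_spec("s", alpha = 1, profile = rep(1, n_bins(g)), s = 0,
                   tads = tads, tad_boost = 2, depth = 8e6, seed = 6)
  cm <- simulate_contact_matrix(g, st)
  px <- tad_pileup(cm, tads, flank_bp = 0.4e6, npx = 90)
  central <- mean(px[31:60, 31:60], na.rm = TRUE)
  flank <- mean(px[31:60, 1:30], na.rm = TRUE)
  expect_equal(central / flank, 2, tolerance = 0.2)
})

test_that("domain strength: zero on flat data, log2(b) on planted boost", {
  cm <- uniform_cm(60, res = 50e3)
  dom <- data.frame(chrom = "chr1", start = 1e6, end = 1.5e6)
  expect_equal(domain_strength(cm, dom), 0, tolerance = 1e-9)
  g <- genome_spec(c(chr1 = 10e6), 50e3)
  tads <- data.frame(chrom = "chr1", start = 5e6, end = 5.4e6)
  st <- stage_spec("s", alpha = 1, profile = rep(1, n_bins(g)), s = 0,
                   tads = tads, tad_boost = 2, depth = 8e6, seed = 3)
  cm2 <- simulate_contact_matrix(g, st)
  expect_equal(domain_strength(cm2, tads[1, ]), 1, tolerance = 0.15)
  edge_dom <- data.frame(chrom = "chr1", start = 0, end = 5e5)
  expect_error(domain_strength(cm, edge_dom), "chromosome edge")
})

test_that("strength dynamics separate constant from decaying boosts", {
  g <- genome_spec(c(chr1 = 10e6), 50e3)
  tads <- data.frame(chrom = "chr1", start = c(2e6, 5e6, 8e6),
                     end = c(2.4e6, 5.4e6, 8.4e6))
  series <- function(boosts) {
    mats <- lapply(seq_along(boosts), function(k) {
      st <- stage_spec(paste0("s", k), alpha = 1,
                       profile = rep(1, n_bins(g)), s = 0, tads = tads,
                       tad_boost = boosts[k], depth = 6e6, seed = 40 + k)
      simulate_contact_matrix(g, st)
    })
    names(mats) <- paste0("s", seq_along(boosts))
    strength_dynamics(mats, tads)
  }
  const <- series(c(2, 2, 2))
  decay <- series(c(2.5, 1.8, 1.2))
  expect_lt(max(abs(const$dynamics$relative_variance)), 0.05)
  expect_gt(min(decay$dynamics$relative_variance),
            max(const$dynamics$relative_variance))
})

test_that("inter-TAD proportions: degenerate domain sets and oracle equality", {
  cm <- uniform_cm(40)
  whole <- data.frame(chrom = "chr1", start = 0, end = 40e6)
  pr <- inter_tad_distance_proportions(cm, whole, c(0, 10e6, Inf))
  expect_true(all(pr$proportion == 0))  # one domain: no inter-TAD pairs
  two <- data.frame(chrom = "chr1", start = c(0, 20e6), end = c(20e6, 40e6))
  edges <- c(0, 10e6, 25e6, Inf)
  pr2 <- inter_tad_distance_proportions(cm, two, edges)
  expect_equal(pr2$proportion, oracle_inter_tad(cm, two, edges),
               tolerance = 1e-12)
  over <- data.frame(chrom = "chr1", start = c(0, 10e6), end = c(20e6, 30e6))
  expect_error(inter_tad_distance_proportions(cm, over, edges), "overlapping")
})

test_that("ultra-long-range boost raises the >80 Mb inter-TAD share", {
  g <- genome_spec(c(chr1 = 150e6), 1e6)
  tads <- data.frame(chrom = "chr1", start = seq(0, 140e6, 10e6),
                     end = seq(10e6, 150e6, 10e6))
  prop80 <- vapply(c(1, 3), function(lam) {
    st <- stage_spec("s", alpha = 1, profile = rep(1, 150), s = 0,
                     long_range_boost = lam, long_range_cutoff = 80e6,
                     depth = 2e6, seed = 19)
    cm <- simulate_contact_matrix(g, st)
    pr <- inter_tad_distance_proportions(cm, tads, c(0, 80e6, Inf))
    pr$proportion[2]
  }, 0)
  expect_gt(prop80[2], prop80[1])
})

test_that("boundary-anchored insulation profile dips at the anchor", {
  fx <- tad_fixture(seed = 5, b = 2, depth = 2e6)
  cm <- balance_matrix(simulate_contact_matrix(fx$genome, fx$stage))
  ins <- insulation_score(cm, c(150e3, 250e3, 500e3))
  fb <- find_boundaries(ins)
  prof <- boundary_insulation_profile(ins, fb$boundaries, flank_bins = 5)
  expect_lt(prof[["0"]], prof[["-5"]])
  expect_lt(prof[["0"]], prof[["5"]])
})
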