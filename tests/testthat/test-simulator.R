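test_that("occupancy peaks at the loading site and honors unload barriers", {
  cfg <- sim_preset("wt")
  occ <- sim_occupancy(cfg, grid_kb = 10, max_kb = 800)
  expect_equal(occ$O[1, 1], 1)
  expect_equal(max(occ$O), 1)
  expect_true(all(occ$O >= 0))
  # nothing beyond the front cap
  expect_true(all(occ$O[occ$dL > cfg$front_cap_kb, ] == 0))
  expect_true(all(occ$O[, occ$dR > cfg$front_cap_kb] == 0))
  gone <- sim_config(barriers = data.frame(arm = "left", offset_kb = 100,
                                           beta = 1, mode = "unload"))
  og <- sim_occupancy(gone, grid_kb = 10, max_kb = 800)
  expect_true(all(og$O[og$dL > 100, ] == 0))
  expect_true(any(og$O[og$dL <= 100, ] > 0))
})

test_that("a full stall pins the left arm while the right arm runs on", {
  cfg <- sim_preset("flip25")  # stall at 70 kb, beta 1
  occ <- sim_occupancy(cfg, grid_kb = 5, max_kb = 700)
  # left marginal dies shortly past the barrier; right marginal keeps going
  expect_lt(max(occ$marginal_left[occ$dL > 70 + 3 * cfg$sigma_kb]), 0.01)
  expect_gt(occ$marginal_right[which.min(abs(occ$dR - 400))], 0.1)
  # the pinned ridge sits at dL ~ barrier for distal dR
  far <- which.min(abs(occ$dR - 300))
  expect_equal(occ$dL[which.max(occ$O[, far])], 70)
})

test_that("expected matrix is a symmetric probability with a flat no-SMC map", {
  cfg <- sim_preset("dsmc", n_pairs = 1000)
  P <- expected_matrix(cfg)
  expect_equal(sum(P$mat[upper.tri(P$mat, diag = TRUE)]), 1)
  expect_true(isSymmetric(P$mat))
  prof <- secondary_diagonal(log_map(P), anchor = cfg$genome$parS_bp)
  keep <- !prof$excluded & prof$offsets_kb > 100 & prof$offsets_kb < 1900
  # without tethers the anti-diagonal only carries smooth distance decay:
  # monotone to the antipode, no alignment band
  expect_lt(max(diff(prof$score[keep] [order(prof$offsets_kb[keep])]
                     [1:100])), 0.01)
  wt <- expected_matrix(sim_preset("wt", n_pairs = 1000))
  prof_wt <- secondary_diagonal(log_map(wt), anchor = cfg$genome$parS_bp)
  band <- prof_wt$offsets_kb < 500 & !prof_wt$excluded
  expect_gt(mean(prof_wt$score[band]) - mean(prof$score[band]), 1)
})

test_that("a speed-symmetric barrier-free model is arm-reflection invariant", {
  g <- genome_spec("sym", 4000000, ori_bp = 0, parS_bp = 0)
  cfg <- sim_config(genome = g, v_left = 17, v_right = 17, n_pairs = 1000)
  P <- expected_matrix(cfg)$mat
  n <- nrow(P)
  # bin centers at 5 kb + 10 kb * (i-1) reflect through the origin onto the
  # centers in reverse order
  perm <- rev(seq_len(n))
  expect_equal(P, P[perm, perm], tolerance = 1e-12)
})

test_that("sampled pairs honor counts, fractions, geometry, and the seed", {
  g <- caulobacter_genome()
  frag <- synthetic_fragments(g, seed = 31)
  cfg <- sim_preset("wt", seed = 31, n_pairs = 10000)
  pr <- sample_pairs(cfg, frag)
  expect_equal(nrow(pr), 10000)
  expect_equal(as.vector(table(pr$label)[c("valid", "self_ligation",
                                           "non_ligation")]),
               c(7000, 1500, 1500))
  expect_identical(sample_pairs(cfg, frag), pr)
  expect_false(identical(sample_pairs(sim_preset("wt", seed = 32,
                                                 n_pairs = 10000), frag), pr))
  # the constructed geometry reproduces the classification rules exactly
  expect_equal(classify_pairs(pr, frag), pr$label)
  f1 <- assign_fragment(pr$pos1, frag)
  f2 <- assign_fragment(pr$pos2, frag)
  expect_true(all((f1 == f2) == (pr$label != "valid")))
})

test_that("sampled contact counts follow the expected matrix probabilities", {
  g <- caulobacter_genome()
  frag <- synthetic_fragments(g, seed = 33)
  cfg <- sim_preset("wt", seed = 33, n_pairs = 3e5)
  pr <- sample_pairs(cfg, frag)
  m <- bin_pairs(pr, g, classes = pr$label)
  P <- expected_matrix(cfg)$mat
  # condition on off-diagonal cells: same-bin draws are resampled whenever a
  # restriction fragment spans the whole bin, which distorts the diagonal on
  # purpose (valid pairs must join distinct fragments)
  ut <- upper.tri(P)
  obs <- m$mat[ut]
  expe <- P[ut] / sum(P[ut]) * sum(obs)
  # pool cells so chi-square expectations stay comfortably above 5
  grp <- findInterval(cumsum(expe) / sum(expe), seq(0.002, 1, by = 0.002),
                      rightmost.closed = TRUE)
  o <- tapply(obs, grp, sum)
  e <- tapply(expe, grp, sum)
  chi <- sum((o - e)^2 / e)
  p <- pchisq(chi, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("the time course starts flat and its fronts advance linearly", {
  g <- caulobacter_genome()
  frag <- synthetic_fragments(g, seed = 34)
  cfg <- sim_preset("timecourse", seed = 34, n_pairs = 1e5)
  sets <- simulate_timecourse(cfg, times = c(0, 10), frag = frag)
  expect_named(sets, c("t0", "t10"))
  m0 <- hic_matrix(sets$t0, g)
  # with no tethers yet, only the intra-arm distance-decay shoulder near the
  # anchor remains: any apparent "extent" stays within that artifact floor
  e0 <- alignment_extent(arm_profile(m0, arm = "left", anchor = g$parS_bp))
  expect_lt(e0$extent_kb, 80)
  p0 <- secondary_diagonal(m0, anchor = g$parS_bp)
  band <- !p0$excluded & p0$offsets_kb >= 300 & p0$offsets_kb <= 500
  bg <- !p0$excluded & p0$offsets_kb >= 1200 & p0$offsets_kb <= 1800
  expect_lt(mean(p0$score[band]) - mean(p0$score[bg]), 0.5)
  # ground-truth fronts: min(v * t, cap) per arm
  cfg10 <- cfg; cfg10$t_min <- 10
  occ <- sim_occupancy(cfg10, grid_kb = 5, max_kb = 700)
  expect_true(all(occ$O[occ$dL > 190, ] == 0))
  expect_true(all(occ$O[, occ$dR > 160] == 0))
  expect_gt(occ$marginal_left[which.min(abs(occ$dL - 180))], 0)
})

test_that("simulated ChIP enrichment peaks at parS and at stall barriers", {
  cfg <- sim_preset("wt", seed = 35, chip_depth = 5e6)
  chip <- simulate_chip(cfg)
  ratio <- enrichment_ratio(chip$tagged, chip$untagged)
  g <- cfg$genome
  peak_bin <- which.max(ratio$values)
  parS_bin <- floor(g$parS_bp / 1000) + 1
  expect_lt(abs(peak_bin - parS_bin), 6)
  # a stall barrier accumulates SMC: the ratio just at the barrier offset
  # exceeds the ratio past it
  stall <- sim_preset("flip25", seed = 35, chip_depth = 5e6)
  rs <- enrichment_ratio(simulate_chip(stall)$tagged,
                         simulate_chip(stall)$untagged)
  at <- track_at_offsets(rs, 70, anchor = g$parS_bp)
  past <- track_at_offsets(rs, 150, anchor = g$parS_bp)
  expect_gt(at, 1.2 * past)
  # artifact peaks show up in both samples and shrink in the ratio
  art <- sim_preset("wt", seed = 36, chip_depth = 5e6,
                    artifact = data.frame(pos_bp = 1.5e6, strength = 40))
  ca <- simulate_chip(art)
  abin <- floor(1.5e6 / 1000) + 1
  expect_gt(ca$tagged$values[abin], 5 * stats::median(ca$tagged$values))
  expect_gt(ca$untagged$values[abin], 5 * stats::median(ca$untagged$values))
  ra <- enrichment_ratio(ca$tagged, ca$untagged)
  expect_lt(ra$values[abin], 2)
})

test_that("estimated extent rises monotonically with processivity", {
  g <- caulobacter_genome()
  frag <- synthetic_fragments(g, seed = 37)
  ext <- vapply(c(150, 300, 600), function(lam) {
    cfg <- sim_preset("wt", seed = 37, lambda_kb = lam, n_pairs = 2e5)
    ml <- hic_matrix(sample_pairs(cfg, frag), g)
    alignment_extent(arm_profile(ml, arm = "right",
                                 anchor = g$parS_bp))$extent_kb
  }, numeric(1))
  expect_true(all(diff(ext) > 0))
})
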