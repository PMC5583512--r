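toy_log_matrix <- function(n = 41, value = -5, genome = NULL) {
  # ori at the central bin so anti-diagonal indexing stays in range
  g <- if (is.null(genome))
    genome_spec("toy", n * 10000, ori_bp = (n %/% 2) * 10000) else genome
  contact_matrix(matrix(value, n, n), 10000, "log", g)
}

test_that("secondary diagonal extracts anti-diagonal scores around the anchor", {
  m <- toy_log_matrix()
  p <- secondary_diagonal(m, exclusion_kb = 0)
  expect_true(all(p$score == -5))
  # single elevated entry at (b-3, b+3) peaks exactly at offset 30 kb
  b <- smcalign:::bin_of(m, m$genome$ori_bp)
  m2 <- m
  m2$mat[b - 3, b + 3] <- m2$mat[b + 3, b - 3] <- -1
  p2 <- secondary_diagonal(m2, exclusion_kb = 0)
  expect_equal(p2$offsets_kb[which.max(p2$score)], 30)
  # near-anchor and near-antipode offsets carry the exclusion flag
  p3 <- secondary_diagonal(m2, exclusion_kb = 30)
  expect_true(all(p3$excluded[p3$offsets_kb < 30]))
  expect_true(all(p3$excluded[max(p3$offsets_kb) - p3$offsets_kb < 30]))
  expect_error(secondary_diagonal(wt_run()$raw), "log-stage")
})

test_that("secondary diagonal is invariant under ori centering", {
  run <- wt_run()
  ml <- log_map(iterative_correction(run$raw))
  p1 <- secondary_diagonal(ml, anchor = run$genome$parS_bp)
  p2 <- secondary_diagonal(ori_center(ml), anchor = run$genome$parS_bp)
  expect_equal(p1$score, p2$score)
  expect_equal(p1$excluded, p2$excluded)
})

test_that("vertical line equals the anchor row, symmetric for symmetric maps", {
  m <- toy_log_matrix()
  b <- smcalign:::bin_of(m, m$genome$ori_bp)
  m$mat[b, ] <- m$mat[, b] <- seq(-8, -4, length.out = 41)
  p <- vertical_line(m)
  expect_equal(sort(p$score), sort(m$mat[b, ]))
  q <- 10L  # single elevated entry flags a single off-center peak
  m2 <- toy_log_matrix()
  m2$mat[b, q] <- m2$mat[q, b] <- 0
  p2 <- vertical_line(m2)
  peak_off <- p2$offsets_kb[which.max(p2$score)]
  expect_equal(abs(peak_off), abs(q - b) * 10)
})

test_that("alignment extent follows the half-max first-down-crossing rule", {
  off <- seq(0, 2000, by = 10)
  step <- ifelse(off <= 600, 3, 1)
  p <- score_profile(off, step)
  e <- alignment_extent(p)
  expect_equal(e$background, 1)
  expect_equal(e$threshold, 2)
  expect_equal(e$extent_kb, 600)
  expect_equal(e$flag, "ok")
  flat <- alignment_extent(score_profile(off, rep(2, length(off))))
  expect_equal(flat$extent_kb, 0)
  expect_equal(flat$flag, "no_signal")
  # a transient dip below threshold caps the extent at the first crossing
  dip <- step; dip[off >= 200 & off <= 240] <- 1
  expect_equal(alignment_extent(score_profile(off, dip))$extent_kb, 190)
})

test_that("alignment rate is the OLS slope over the fitted window", {
  expect_equal(alignment_rate(data.frame(t = c(10, 15, 25),
                                         extent_kb = c(200, 295, 485)))$slope_kb_per_min,
               19)
  expect_equal(alignment_rate(data.frame(t = c(10, 15, 25),
                                         extent_kb = c(160, 240, 400)))$slope_kb_per_min,
               16)
  # points outside the window are ignored; < 2 inside errors
  tab <- data.frame(t = c(0, 5, 10, 15, 25, 30),
                    extent_kb = c(0, 900, 200, 295, 485, 100))
  expect_equal(alignment_rate(tab)$slope_kb_per_min, 19)
  expect_error(alignment_rate(tab, window = c(26, 29)), "at least 2")
  # normal-equations oracle on noisy data
  set.seed(7)
  t <- runif(20, 10, 25)
  y <- 17 * t + rnorm(20, sd = 25)
  fit <- alignment_rate(data.frame(t = t, extent_kb = y), window = c(10, 25))
  slope_oracle <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(fit$slope_kb_per_min, slope_oracle, tolerance = 1e-10)
  expect_equal(fit$intercept_kb, mean(y) - slope_oracle * mean(t),
               tolerance = 1e-10)
})

test_that("an ideal symmetric band gives slope one and no streak flag", {
  g <- genome_spec("toy", 4000000, ori_bp = 0, parS_bp = 0)
  n <- smcalign::n_bins(g, 10000)
  M <- matrix(-8, n, n)
  b <- 1L
  for (k in 1:60) {  # dR = dL band out to 600 kb
    i <- ((b - 1 - k) %% n) + 1; j <- ((b - 1 + k) %% n) + 1
    M[i, j] <- M[j, i] <- -3
  }
  m <- contact_matrix(M, 10000, "log", g)
  r <- ridge_asymmetry(m, anchor = 0)
  expect_equal(r$slope, 1, tolerance = 1e-6)
  expect_lt(r$deviation_deg, 1e-3)
  expect_false(r$streak)
  expect_error(ridge_asymmetry(m, anchor = 0, left_range = c(100, 90)),
               "empty")
})

test_that("paired profile t test matches the closed-form statistic", {
  off <- seq(40, 70, by = 10)
  a <- score_profile(off, c(3, 1, 4, 2))
  b <- score_profile(off, c(1, 1, 2, 2))
  res <- profile_paired_t(a, b)
  # differences {2, 0, 2, 0}: t = mean/sd * sqrt(n) = 1 / (2/sqrt(3))... = 1.732
  expect_equal(res$statistic, 1.7320508, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$estimate, 1)
  expect_error(profile_paired_t(a, a), "degenerate")
  expect_error(profile_paired_t(a, score_profile(off + 10, c(1, 1, 2, 2))),
               "mismatched")
  # closed-form oracle across random draws, to 1e-10
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    px <- score_profile(seq_along(x) * 10, x)
    py <- score_profile(seq_along(x) * 10, y)
    got <- profile_paired_t(px, py)
    d <- x - y
    t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
    p_oracle <- 2 * pt(-abs(t_oracle), df = length(d) - 1)
    expect_equal(got$statistic, t_oracle, tolerance = 1e-10)
    expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
  }
})

test_that("pearson correlation matches hand values and the t-transform", {
  expect_equal(pearson_cor(1:5, 2 * (1:5))$estimate, 1)
  expect_equal(pearson_cor(1:5, 7 - (1:5))$estimate, -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$estimate, 0.8)
  expect_error(pearson_cor(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    got <- pearson_cor(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt((12 - 2) / (1 - r^2))
    expect_equal(got$estimate, r, tolerance = 1e-10)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), 10), tolerance = 1e-10)
  }
})
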