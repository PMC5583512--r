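# Shared fixtures, built in code.

# small toy circle for coordinate arithmetic tests
toy_genome <- function(len = 100000, ori = 0) {
  genome_spec("toy", len, ori_bp = ori, parS_bp = (ori - 2000) %% len)
}

# random circular DNA sequence with a seeded base composition
random_sequence <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# memoized medium-depth wild-type run shared across test files
wt_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- caulobacter_genome()
      frag <- synthetic_fragments(g, seed = 11)
      cfg <- sim_preset("wt", seed = 11, n_pairs = 2e5)
      pairs <- sample_pairs(cfg, frag)
      cache <<- list(genome = g, frag = frag, config = cfg, pairs = pairs,
                     raw = bin_pairs(pairs, g, classes = pairs$label))
    }
    cache
  }
})

# independent alternating row/column (Sinkhorn) scaling oracle
sinkhorn_oracle <- function(M, iters = 200) {
  for (i in seq_len(iters)) {
    M <- M / rowSums(M)
    M <- t(t(M) / colSums(M))
  }
  M / sum(M)
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}

# independent bookkeeping oracles for contact matrices
matrix_total_upper <- function(m) {
  v <- m$mat
  sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
}

matrix_mass_oracle <- function(m) {
  v <- m$mat
  if (length(m$mask)) {
    v[m$mask, ] <- NA
    v[, m$mask] <- NA
  }
  sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
}

bin_starts_oracle <- function(m) {
  n <- nrow(m$mat)
  ((seq_len(n) - 1 + m$rotation) %% n) * m$bin_size
}
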