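test_that("RPKPM normalizes by bin length and sequencing depth", {
  g <- genome_spec("g", 1000000)
  set.seed(21)
  reads <- c(rep(500, 100), sample(1e6, 999900, replace = TRUE) - 1)
  tr <- rpkpm_track(reads, g)
  # a 1-kb bin with k of N reads: value = k / (N / 1e6)
  counts <- tabulate(floor(reads / 1000) + 1, nbins = 1000)
  expect_equal(tr$values, counts / (1e6 / 1e6))
  expect_equal(tr$values[1], counts[1])
  # all reads in one 1-kb bin: value = 1e6 regardless of depth
  solo <- rpkpm_track(rep(1500, 777), g)
  expect_equal(solo$values[2], 1e6)
  expect_error(rpkpm_track(numeric(0), g), "at least one read")
  # conservation: sum(value * bin_kb) = 1e6
  expect_equal(sum(tr$values * 1), 1e6)
})

test_that("the final partial bin is normalized by its true length", {
  g <- genome_spec("g", 10500)  # last bin is 500 bp
  tr <- rpkpm_track(c(rep(100, 50), rep(10100, 50)), g, bin_size = 1000)
  expect_equal(tr$values[1], 50 / 1 / (100 / 1e6))
  expect_equal(tr$values[11], 50 / 0.5 / (100 / 1e6))
})

test_that("enrichment ratio is one for identical tracks and scales linearly", {
  g <- genome_spec("g", 100000)
  a <- chip_track(rep(4, 100), 1000, g, label = "tagged")
  b <- chip_track(rep(4, 100), 1000, g, label = "untagged")
  expect_true(all(enrichment_ratio(a, b)$values == 1))
  a2 <- chip_track(rep(8, 100), 1000, g)
  expect_equal(enrichment_ratio(a2, b, pseudocount = 1e-12)$values,
               rep(2, 100), tolerance = 1e-9)
  wrong <- chip_track(rep(4, 50), 2000, g)
  expect_error(enrichment_ratio(a, wrong), "different bin grids")
})

test_that("gene occupancy is mean coverage times gene length in kb", {
  g <- genome_spec("g", 100000)
  genes <- data.frame(id = c("a", "b"), start = c(10000, 40500),
                      end = c(13000, 42500), strand = c("+", "-"),
                      weight = c(1, 1), stringsAsFactors = FALSE)
  const <- chip_track(rep(2, 100), 1000, g)
  occ <- gene_occupancy(const, genes)
  expect_equal(occ$occupancy, c(2 * 3, 2 * 2))
  zero <- chip_track(rep(0, 100), 1000, g)
  expect_equal(gene_occupancy(zero, genes)$occupancy, c(0, 0))
  # partial-bin overlap against a per-bp summation oracle
  set.seed(22)
  vals <- runif(100, 0, 5)
  tr <- chip_track(vals, 1000, g)
  frac_gene <- data.frame(id = "c", start = 40250, end = 43730, strand = "+",
                          weight = 1)
  got <- gene_occupancy(tr, frac_gene)$occupancy
  per_bp <- vals[floor(40250:43729 / 1000) + 1]
  expect_equal(got, mean(per_bp) * (43730 - 40250) / 1000, tolerance = 1e-9)
  outside <- data.frame(id = "d", start = 99000, end = 101000, strand = "+",
                        weight = 1)
  expect_error(gene_occupancy(tr, outside), "outside")
})

test_that("orientation is judged relative to translocation away from parS", {
  g <- caulobacter_genome()
  genes <- data.frame(
    id = c("r_plus", "r_minus", "l_plus", "l_minus"),
    start = c(200000, 300000, 3800000, 3900000),
    end = c(203000, 303000, 3803000, 3903000),
    strand = c("+", "-", "+", "-"),
    weight = c(1, 1, 1, 1), stringsAsFactors = FALSE)
  expect_equal(classify_orientation(genes, g),
               c("co_directional", "head_on", "head_on", "co_directional"))
  spanning <- data.frame(id = "s", start = 2020000, end = 2023000,
                         strand = "+", weight = 1)
  expect_error(classify_orientation(spanning, g), "ambiguous arm")
})

test_that("inverting a gene flips its orientation classification", {
  g <- caulobacter_genome()
  inv <- caulobacter_inversions()$flip25
  genes <- data.frame(id = c("in1", "in2", "out"),
                      start = c(3700000, 3900000, 3500000),
                      end = c(3703000, 3905000, 3504000),
                      strand = c("-", "+", "-"),
                      weight = c(5, 2, 1), stringsAsFactors = FALSE)
  before <- classify_orientation(genes, g)
  remapped <- invert_genes(genes, inv, g$length_bp)
  after <- classify_orientation(remapped, g)[match(genes$id, remapped$id)]
  flip <- function(x) ifelse(x == "head_on", "co_directional", "head_on")
  expect_equal(after[1:2], flip(before[1:2]))
  expect_equal(after[3], before[3])
})

test_that("orientation bias summarizes expression weight by class and arm", {
  g <- caulobacter_genome()
  genes <- data.frame(id = letters[1:4],
                      start = c(100000, 500000, 3600000, 3000000),
                      end = c(103000, 503000, 3603000, 3003000),
                      strand = c("+", "-", "-", "+"),
                      weight = c(3, 3, 2, 4), stringsAsFactors = FALSE)
  out <- orientation_bias(genes, g)
  # co-directional: a (right,+ ; 3) and c (left,- ; 2); head-on: b, d
  expect_equal(out$bias_weight, (3 + 2) / (3 + 4))
  expect_equal(out$bias_count, 1)
  expect_false(out$infinite)
  allco <- genes[c(1, 3), ]
  out2 <- orientation_bias(allco, g)
  expect_true(out2$infinite)
  expect_equal(out2$bias_weight, Inf)
  expect_error(orientation_bias(genes[0, ], g), "empty")
})

test_that("inversion-aware gene remapping commutes with reclassification", {
  g <- caulobacter_genome()
  inv <- caulobacter_inversions()$flip45
  set.seed(23)
  starts <- sort(sample(seq(3400000, 3990000, by = 1000), 25))
  genes <- data.frame(id = sprintf("g%02d", 1:25), start = starts,
                      end = starts + 800,
                      strand = sample(c("+", "-"), 25, TRUE),
                      weight = runif(25, 0, 10), stringsAsFactors = FALSE)
  remapped <- invert_genes(genes, inv, g$length_bp)
  expect_equal(sum(remapped$weight), sum(genes$weight))
  inside <- genes$start >= inv$start_bp & genes$end <= inv$end_bp
  cls_before <- classify_orientation(genes, g)
  cls_after <- classify_orientation(remapped[match(genes$id, remapped$id), ], g)
  expect_true(all(cls_after[inside] != cls_before[inside]))
  expect_true(all(cls_after[!inside] == cls_before[!inside]))
})
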