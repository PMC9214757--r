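test_that("expected matrix follows the bare power-law when all modifiers are off", {
  n <- 100; bs <- 4e4; depth <- 1e6
  sim <- simulate_contact_map(sim_config(c(chr1 = n * bs), bs,
                                         decay_exponent = 1,
                                         depth_scale = depth, seed = 5))
  E <- sim$truth$expected
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  off <- d > 0
  expect_equal(E[off], depth * (d[off] * bs)^(-1))
  expect_equal(diag(E), rep(depth / bs, n))  # diagonal pinned to d = 1
  expect_identical(E, t(E))
  expect_identical(sim$matrix$mat, t(sim$matrix$mat))
  expect_true(all(sim$matrix$mat >= 0 & sim$matrix$mat == round(sim$matrix$mat)))
})

test_that("checkerboard contrast g gives same/opposite expected ratio exp(2g)", {
  n <- 100; bs <- 4e5
  lab <- rep(c("A", "B"), each = 50)
  sim <- simulate_contact_map(sim_config(c(chr1 = n * bs), bs,
                                         compartment_contrast = 1,  # g = ln 2
                                         compartment_labels = lab,
                                         depth_scale = 1e6, seed = 2))
  E <- sim$truth$expected
  # same-label (1,41) and opposite-label (31,71) pairs, both at separation 40
  expect_equal(E[1, 41] / E[31, 71], exp(2 * log(2)))
  expect_equal(E[1, 41] / E[31, 71], 4)
})

test_that("same seed reproduces bit-identical counts; different seed does not", {
  cfg <- function(s) sim_config(c(chr1 = 4e6, chr2 = 2.4e6), 4e4,
                                bias_log_sd = 0.2, trans_background = 0.01,
                                depth_scale = 5e5, seed = s)
  a <- simulate_contact_map(cfg(7))
  b <- simulate_contact_map(cfg(7))
  c <- simulate_contact_map(cfg(8))
  expect_identical(a$matrix$mat, b$matrix$mat)
  expect_identical(a$truth$biases, b$truth$biases)
  expect_false(identical(a$matrix$mat, c$matrix$mat))
})

test_that("observed counts are Poisson-unbiased around the planted expectation", {
  n <- 60; bs <- 4e4
  cfg <- function(s) sim_config(c(chr1 = n * bs), bs, decay_exponent = 1,
                                depth_scale = 2e5, seed = s)
  E <- simulate_contact_map(cfg(1))$truth$expected
  reps <- 200
  acc <- matrix(0, n, n)
  for (s in seq_len(reps)) acc <- acc + simulate_contact_map(cfg(s))$matrix$mat
  m <- acc / reps
  # standardised deviation of the replicate mean from E
  z <- (m - E) / sqrt(E / reps)
  expect_lt(max(abs(z[upper.tri(z, diag = TRUE)])), 5)
  expect_gt(cor(m[upper.tri(m)], E[upper.tri(E)]), 0.99)
})

test_that("cis expectation is non-increasing in distance without structure", {
  sim <- sim_plain(n = 120, alpha = 0.8, seed = 3)
  E <- sim$truth$expected
  for (i in c(1, 40)) expect_true(all(diff(E[i, i:120]) <= 1e-12))
})

test_that("invalid configurations are rejected", {
  bad_tads <- data.frame(chrom = "chr1", start_bin = c(0, 5), end_bin = c(10, 15))
  expect_error(sim_config(c(chr1 = 4e6), 4e4, tads = bad_tads), "overlap")
  expect_error(sim_config(c(chr1 = 4e6), 4e4, depth_scale = 0), "positive")
  expect_error(sim_config(c(chr1 = 4e6), 4e4,
                          loops = data.frame(chrom = "chr1", bin_i = 5, bin_j = 5)),
               "bin_i < bin_j")
  expect_error(sim_config(c(chr1 = 3e4), 4e4), "two bins")
})

test_that("simulate_pc1_pair builds block-dependent correlation structure", {
  bins <- bin_table(c(chr1 = 100 * 4e5), 4e5)
  blocks <- data.frame(chrom = "chr1", start = 0, end = 50 * 4e5)
  # perfect correlation everywhere -> identical tracks
  p <- simulate_pc1_pair(bins, blocks, r_in = 1, r_out = 1, seed = 1)
  expect_equal(p$a$value, p$b$value)
  # sign construction: +1 inside the block, -1 outside
  p <- simulate_pc1_pair(bins, blocks, r_in = 1, r_out = -1, seed = 1)
  expect_equal(cor(p$a$value[1:50], p$b$value[1:50]), 1)
  expect_equal(cor(p$a$value[51:100], p$b$value[51:100]), -1)
  # Monte-Carlo: large-n within-block sample correlation near r_in
  big <- bin_table(c(chr1 = 5000 * 4e5), 4e5)
  blocks <- data.frame(chrom = "chr1", start = 0, end = 2500 * 4e5)
  p <- simulate_pc1_pair(big, blocks, r_in = 0.9, r_out = 0, seed = 4)
  expect_lt(abs(cor(p$a$value[p$in_block], p$b$value[p$in_block]) - 0.9), 0.05)
  expect_lt(abs(cor(p$a$value[!p$in_block], p$b$value[!p$in_block])), 0.05)
  expect_error(simulate_pc1_pair(0, blocks, 0.9, 0), "empty")
  expect_error(simulate_pc1_pair(bins, blocks, r_in = 0, r_out = 0.5), "r_out")
})

test_that("expression simulator separates groups only when an effect is planted", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:500))
  hi <- genes$gene_id[1:250]
  # null: no planted effect -> Wilcoxon non-significant in >= 90% of seeds
  # (a wide seed panel keeps the binomial noise of the fraction small)
  pvals <- vapply(1:200, function(s) {
    ex <- simulate_expression_table(genes, hi, effect = 0, seed = s)
    stats::wilcox.test(ex$value[1:250], ex$value[251:500], exact = FALSE)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  # strong effect -> planted ordering in every seed
  for (s in 1:5) {
    ex <- simulate_expression_table(genes, hi, effect = 3, seed = s)
    expect_gt(mean(log(ex$value[1:250])), mean(log(ex$value[251:500])))
  }
  # degenerate inputs
  ex0 <- simulate_expression_table(genes, character(), effect = 2, seed = 1)
  exb <- simulate_expression_table(genes, character(), effect = 0, seed = 1)
  expect_identical(ex0$value, exb$value)
  expect_error(simulate_expression_table(
    data.frame(gene_id = c("a", "a")), character(), 0), "duplicate")
})
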