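balanced_from <- function(mat, bins, mask = NULL) {
  contact_matrix(mat, bins, kind = "balanced", mask = mask)
}

test_that("quantile-normalised difference reproduces the rank-average worked example", {
  bins <- toy_bins(3)
  a <- balanced_from(toy_matrix(3, list(c(0, 1, 1), c(0, 2, 2), c(1, 2, 3)))$mat,
                     bins)
  b <- balanced_from(toy_matrix(3, list(c(0, 1, 10), c(0, 2, 20), c(1, 2, 30)))$mat,
                     bins)
  # both value multisets map to the averaged sorted profile (5.5, 11, 16.5)
  norm <- hicogeny:::quantile_normalize_values(list(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(norm[[1]], c(5.5, 11, 16.5))
  expect_equal(norm[[2]], c(5.5, 11, 16.5))
  d <- deconvolve(list(a, b))
  expect_equal(unname(d$mat), matrix(0, 3, 3))
})

test_that("deconvolution of identical matrices is zero and the map is antisymmetric", {
  sim1 <- sim_plain(n = 80, seed = 1, depth_per_bin = 100)
  sim2 <- sim_plain(n = 80, seed = 2, depth_per_bin = 300)
  a <- ice_normalize(sim1$matrix)$matrix
  b <- ice_normalize(sim2$matrix)$matrix
  zero <- deconvolve(list(a, a))
  expect_equal(max(abs(zero$mat), na.rm = TRUE), 0)
  ab <- deconvolve(list(a, b), pair = c(1, 2))
  ba <- deconvolve(list(a, b), pair = c(2, 1))
  expect_equal(ab$mat, -ba$mat)
  expect_equal(ab$kind, "difference")
  other <- ice_normalize(sim_plain(n = 60, seed = 3)$matrix)$matrix
  expect_error(deconvolve(list(a, other)), "bin tables")
})

test_that("own quantile normalisation agrees with the limma reference on equal counts", {
  skip_if_not_installed("limma")
  set.seed(5)
  x <- rexp(200, 0.1); y <- rlnorm(200, 2, 1)
  mine <- hicogeny:::quantile_normalize_values(list(x, y))
  ref <- limma::normalizeQuantiles(cbind(x, y), ties = TRUE)
  expect_equal(mine[[1]], unname(ref[, 1]))
  expect_equal(mine[[2]], unname(ref[, 2]))
})

test_that("conserved regions span everything for identical tracks and vanish for negated ones", {
  bins <- bin_table(c(chr1 = 200 * 4e5, chr2 = 150 * 4e5), 4e5)
  set.seed(9)
  v <- rnorm(350)
  a <- scalar_track(bins, v)
  full <- conserved_regions(a, scalar_track(bins, 2 * v + 1))
  expect_equal(nrow(full), 2)  # one region per chromosome
  expect_equal(full$mean_r, c(1, 1))
  expect_equal(full$start, c(0, 0))
  expect_equal(full$end, c(200 * 4e5, 150 * 4e5))
  none <- conserved_regions(a, scalar_track(bins, -v))
  expect_equal(nrow(none), 0)
})

test_that("planted conserved blocks are recovered at high Jaccard", {
  bins <- bin_table(c(chr1 = 1000 * 4e5), 4e5)
  blocks <- data.frame(chrom = "chr1",
                       start = c(40, 320, 640) * 4e5,
                       end = c(160, 440, 800) * 4e5)
  p <- simulate_pc1_pair(bins, blocks, r_in = 0.95, r_out = 0, seed = 12)
  regs <- conserved_regions(p$a, p$b)
  expect_gte(interval_jaccard(regs[c("chrom", "start", "end")], blocks), 0.8)
})

test_that("conserved-region calls are invariant to positive rescaling of either track", {
  bins <- bin_table(c(chr1 = 300 * 4e5), 4e5)
  blocks <- data.frame(chrom = "chr1", start = 50 * 4e5, end = 150 * 4e5)
  p <- simulate_pc1_pair(bins, blocks, r_in = 0.9, r_out = -0.2, seed = 2)
  r1 <- conserved_regions(p$a, p$b)
  r2 <- conserved_regions(scalar_track(bins, 5 * p$a$value),
                          scalar_track(bins, 0.2 * p$b$value))
  expect_equal(r1, r2)
})

test_that("profile clustering separates planted groups and is order-invariant", {
  bins <- bin_table(c(chr1 = 400 * 4e5), 4e5)
  set.seed(31)
  base1 <- rnorm(400); base2 <- rnorm(400)
  mk <- function(base) scalar_track(bins, base + rnorm(400, 0, 0.3))
  tracks <- list(a1 = mk(base1), a2 = mk(base1), a3 = mk(base1),
                 b1 = mk(base2), b2 = mk(base2))
  tree <- cluster_profiles(tracks)
  grp <- cutree(tree, k = 2)
  expect_equal(length(unique(grp[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(grp[c("b1", "b2")])), 1)
  expect_false(grp[["a1"]] == grp[["b1"]])
  # duplicated sample joins its twin first (lowest merge height)
  dup <- c(tracks, list(a1_copy = tracks$a1))
  tree2 <- cluster_profiles(dup)
  first <- sort(tree2$labels[-tree2$merge[1, ]])
  expect_equal(first, c("a1", "a1_copy"))
  # permuting the input leaves the topology unchanged
  perm <- tracks[c(4, 2, 5, 1, 3)]
  tree3 <- cluster_profiles(perm)
  co1 <- cophenetic(tree)
  co3 <- cophenetic(tree3)
  m1 <- as.matrix(co1)[sort(tree$labels), sort(tree$labels)]
  m3 <- as.matrix(co3)[sort(tree$labels), sort(tree$labels)]
  expect_equal(m1, m3)
  flat <- list(x = scalar_track(bins, rep(1, 400)), y = tracks$a1)
  expect_error(cluster_profiles(flat), "'x'")
})

test_that("region overlap arithmetic is exact", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(unname(region_overlap(a, b)), c(50, 50, 50))
  expect_equal(unname(region_overlap(a, a)), c(0, 100, 0))
  disj <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(region_overlap(a, disj)[["shared_bp"]], 0)
  bad <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150))
  expect_error(region_overlap(bad, a), "overlap")
})

test_that("Fisher enrichment matches hypergeometric enumeration on small tables", {
  # oracle: two-sided Fisher p by enumerating the hypergeometric support
  fisher_brute <- function(tab) {
    m <- sum(tab[, 1]); nn <- sum(tab[, 2]); k <- sum(tab[1, ])
    support <- max(0, k - nn):min(k, m)
    probs <- stats::dhyper(support, m, nn, k)
    p_obs <- stats::dhyper(tab[1, 1], m, nn, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  # the 5/5 diagonal table: p = 2/252
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(stats::fisher.test(tab)$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_brute(tab), 2 / 252, tolerance = 1e-12)
  set.seed(77)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_brute(tab),
                 tolerance = 1e-9)
  }
})

test_that("bin-level enrichment builds the right table and handles degenerate margins", {
  universe <- bin_table(c(chr1 = 10 * 4e5), 4e5)
  regions <- data.frame(chrom = "chr1", start = 0, end = 5 * 4e5)
  features <- data.frame(chrom = "chr1",
                         start = c(1, 2, 3, 4, 5) * 4e5 - 100,
                         end = c(1, 2, 3, 4, 5) * 4e5 + 100)
  res <- fisher_enrichment(regions, features, universe)
  expect_equal(sum(res$table), 10)
  expect_true(res$p <= 1 && res$p >= 0)
  # all bins inside regions: zero margin -> p = 1, odds ratio undefined
  all_in <- data.frame(chrom = "chr1", start = 0, end = 10 * 4e5)
  deg <- fisher_enrichment(all_in, features, universe)
  expect_equal(deg$p, 1)
  expect_true(is.na(deg$odds_ratio))
  # the exact diagonal table through the public interface
  reg5 <- data.frame(chrom = "chr1", start = 0, end = 5 * 4e5)
  feat5 <- data.frame(chrom = "chr1", start = (0:4) * 4e5 + 10,
                      end = (0:4) * 4e5 + 20)
  res5 <- fisher_enrichment(reg5, feat5, universe)
  expect_equal(unname(res5$table[1, ]), c(5, 0))
  expect_equal(unname(res5$table[2, ]), c(0, 5))
  expect_equal(res5$p, 2 / 252, tolerance = 1e-12)
  # batch adjustment fills p_adj with BH over the batch
  batch <- fisher_enrichment_batch(reg5, list(f1 = feat5, f2 = features),
                                   universe)
  expect_false(any(is.na(vapply(batch, `[[`, numeric(1), "p_adj"))))
  expect_error(fisher_enrichment(reg5, feat5, universe[0, ]), "empty universe")
})

test_that("null enrichment p-values are roughly uniform", {
  universe <- bin_table(c(chr1 = 200 * 4e5), 4e5)
  ps <- vapply(1:40, function(s) {
    set.seed(s)
    rs <- sort(sample(0:199, 4) * 4e5)
    regions <- data.frame(chrom = "chr1", start = rs[c(1, 3)],
                          end = rs[c(1, 3)] + 4e5)
    feats <- data.frame(chrom = "chr1", start = sample(0:199, 20) * 4e5 + 10,
                        end = sample(0:199, 20) * 4e5 + 20)
    fisher_enrichment(regions, feats, universe)$p
  }, numeric(1))
  # discrete p-values are conservative; check they are not concentrated low
  expect_gt(mean(ps > 0.2), 0.5)
})
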