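test_that("DI evaluates the chi-square-style formula on crafted neighbourhoods", {
  # 5-bin chromosome, window = 2 bins: bin 3 sees A = 4+6, B = 14+16
  n <- 5; bs <- 4e4
  M <- matrix(0, n, n)
  M[3, 1] <- M[1, 3] <- 4
  M[3, 2] <- M[2, 3] <- 6
  M[3, 4] <- M[4, 3] <- 14
  M[3, 5] <- M[5, 3] <- 16
  m <- contact_matrix(M, toy_bins(n), kind = "balanced")
  di <- directionality_index(m, window = 2 * bs)
  expect_equal(di$value[3], 10)   # A=10, B=30 -> +10
  # swap upstream/downstream: A=30, B=10 -> -10
  M2 <- M[n:1, n:1]
  di2 <- directionality_index(contact_matrix(M2, toy_bins(n), kind = "balanced"),
                              window = 2 * bs)
  expect_equal(di2$value[3], -10)
  # symmetric neighbourhood -> 0; empty neighbourhood -> undefined
  M3 <- matrix(0, n, n)
  M3[3, 2] <- M3[2, 3] <- 10
  M3[3, 4] <- M3[4, 3] <- 10
  di3 <- directionality_index(contact_matrix(M3, toy_bins(n), kind = "balanced"),
                              window = 2 * bs)
  expect_equal(di3$value[3], 0)
  expect_true(is.na(di3$value[1]))  # A + B = 0 -> undefined
  expect_error(directionality_index(m, window = bs), "2 bins")
})

test_that("DI is antisymmetric under chromosome reversal", {
  sim <- sim_plain(n = 150, seed = 8, tads = tiling_tads(150),
                   tad_enrichment = 3)
  bal <- ice_normalize(sim$matrix)$matrix
  di <- directionality_index(bal)
  rev_mat <- bal$mat[150:1, 150:1]
  rev_m <- contact_matrix(rev_mat, sim$bins, kind = "balanced",
                          mask = rev(bal$mask))
  di_rev <- directionality_index(rev_m)
  ok <- is.finite(di$value) & is.finite(rev(di_rev$value))
  expect_equal(di$value[ok], -rev(di_rev$value)[ok])
})

test_that("HMM recovers planted TAD boundaries at high F1", {
  n <- 500; bs <- 4e4
  tads <- tiling_tads(n)
  sim <- sim_plain(n = n, seed = 3, tads = tads, tad_enrichment = 3)
  bal <- ice_normalize(sim$matrix)$matrix
  ts <- hmm_call_tads(directionality_index(bal))
  truth <- tad_gap_midpoints(tads)
  called <- boundary_midbins(ts, "chr1", bs)
  f <- boundary_f1(called, truth, tol = 1)
  expect_gte(f[["f1"]], 0.8)
  expect_true(all(ts$boundaries$end - ts$boundaries$start < 4e5))
  # domains are sorted and non-overlapping
  d <- ts$domains
  expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
})

test_that("TAD calling is deterministic and silent on featureless input", {
  sim <- sim_plain(n = 200, seed = 5, tads = tiling_tads(200),
                   tad_enrichment = 3)
  bal <- ice_normalize(sim$matrix)$matrix
  di <- directionality_index(bal)
  expect_identical(hmm_call_tads(di), hmm_call_tads(di))
  zero_di <- scalar_track(toy_bins(100), rep(0, 100))
  expect_equal(nrow(hmm_call_tads(zero_di)$domains), 0)
})

test_that("insulation is flat on uniform fields and scale-invariant", {
  m <- distance_matrix(60, function(d) 50 + 0 * d)
  it <- insulation_score(m, window = 5 * 4e4)
  def <- is.finite(it$log2)
  expect_true(any(def))
  expect_lt(max(abs(it$log2[def])), 1e-12)
  sim <- sim_plain(n = 120, seed = 2, tads = tiling_tads(120),
                   tad_enrichment = 2)
  bal <- ice_normalize(sim$matrix)$matrix
  it1 <- insulation_score(bal)
  doubled <- contact_matrix(2 * bal$mat, bal$bins, kind = "balanced",
                            mask = bal$mask)
  it2 <- insulation_score(doubled)
  expect_equal(it2$log2, it1$log2)
  short <- distance_matrix(5, function(d) 10 + 0 * d)
  expect_warning(insulation_score(short, window = 10 * 4e4), "skipped")
})

test_that("insulation minima localise planted boundaries", {
  n <- 500
  tads <- tiling_tads(n)
  sim <- sim_plain(n = n, seed = 9, tads = tads, tad_enrichment = 3)
  bal <- ice_normalize(sim$matrix)$matrix
  mins <- insulation_minima(insulation_score(bal))
  truth <- tad_gap_midpoints(tads)
  hit <- mean(vapply(truth, function(t) any(abs(mins$bin_id - t) <= 1),
                     logical(1)))
  expect_gte(hit, 0.8)
})

test_that("TAD-centred aggregate profiles behave for constant and planted fields", {
  n <- 120
  tads <- data.frame(chrom = "chr1", start = c(20, 60) * 4e4,
                     end = c(40, 80) * 4e4)
  flat <- insulation_score(distance_matrix(n, function(d) 20 + 0 * d),
                           window = 10 * 4e4)
  prof1 <- tad_profile(flat, tads[1, ])
  expect_lt(diff(range(prof1$value)), 1e-9)
  prof2 <- tad_profile(flat, tads)
  expect_equal(prof2$value, prof1$value)
  # planted TADs: higher inside than at the edges
  sim <- sim_plain(n = 500, seed = 4, tads = tiling_tads(500),
                   tad_enrichment = 3)
  bal <- ice_normalize(sim$matrix)$matrix
  it <- insulation_score(bal)
  doms <- data.frame(chrom = "chr1",
                     start = tiling_tads(500)$start_bin * 4e4,
                     end = tiling_tads(500)$end_bin * 4e4)
  prof <- tad_profile(it, doms)
  centre <- prof$value[abs(prof$position - 0.5) < 0.1]
  edges <- prof$value[abs(prof$position) < 0.05 | abs(prof$position - 1) < 0.05]
  expect_gt(mean(centre), mean(edges))
  expect_error(tad_profile(flat, tads[0, ]), "covered")
})

test_that("TAD switch classification follows PC1 sign per stage", {
  bins <- toy_bins(40, bin_size = 4e5)
  tads <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30) * 4e5,
                     end = c(10, 20, 30, 40) * 4e5)
  v_a <- rep(c(1, 1, -1, -1), each = 10)
  v_b <- rep(c(1, -1, -1, 1), each = 10)
  res <- tad_switch_class(tads, scalar_track(bins, v_a), scalar_track(bins, v_b))
  expect_equal(res$transitions$transition,
               c("A->A", "A->B", "B->B", "B->A"))
  expect_equal(res$percent_switched, 50)
  same <- tad_switch_class(tads, scalar_track(bins, v_a), scalar_track(bins, v_a))
  expect_equal(same$percent_switched, 0)
  flip <- tad_switch_class(tads, scalar_track(bins, v_a), scalar_track(bins, -v_a))
  expect_equal(flip$percent_switched, 100)
  # fully masked PC1 -> unclassified
  v_na <- v_a; v_na[1:10] <- NA
  part <- tad_switch_class(tads, scalar_track(bins, v_na), scalar_track(bins, v_b))
  expect_equal(part$transitions$transition[1], "unclassified")
})
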