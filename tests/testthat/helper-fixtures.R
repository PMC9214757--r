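# Shared fixture builders. Everything is generated in code; no stored data.

toy_bins <- function(n, bin_size = 4e4, chroms = c(chr1 = 1)) {
  lens <- chroms * n * bin_size
  bin_table(lens, bin_size)
}

# dense symmetric matrix from an upper-triangle pixel list
toy_matrix <- function(n, pixels, bins = toy_bins(n), kind = "raw") {
  m <- matrix(0, n, n)
  for (p in pixels) {
    m[p[1] + 1, p[2] + 1] <- p[3]
    m[p[2] + 1, p[1] + 1] <- p[3]
  }
  contact_matrix(m, bins, kind = kind)
}

# exact distance-function matrix: value depends only on |i - j|
distance_matrix <- function(n, f, bins = toy_bins(n), kind = "balanced") {
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  contact_matrix(matrix(f(d), n, n), bins, kind = kind)
}

# deep, structure-free simulated map used by several recovery tests;
# depth_per_bin is the expected adjacent-bin count, whatever the exponent
sim_plain <- function(n = 400, alpha = 1, seed = 1, depth_per_bin = 1500,
                      bin_size = 4e4, ...) {
  simulate_contact_map(sim_config(
    c(chr1 = n * bin_size), bin_size, decay_exponent = alpha,
    depth_scale = depth_per_bin * bin_size^alpha, seed = seed, ...))
}

tiling_tads <- function(n, domain_bins = 20, gap_bins = 2, chrom = "chr1") {
  s <- seq(0, n - domain_bins, by = domain_bins + gap_bins)
  data.frame(chrom = chrom, start_bin = s, end_bin = s + domain_bins,
             stringsAsFactors = FALSE)
}

tad_gap_midpoints <- function(tads) {
  round((tads$end_bin[-nrow(tads)] + tads$start_bin[-1] - 1) / 2)
}

boundary_midbins <- function(tadset, chrom, bin_size) {
  b <- tadset$boundaries[tadset$boundaries$chrom == chrom, , drop = FALSE]
  round(((b$start + b$end) / 2) / bin_size - 0.5)
}
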