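#' Configuration for the synthetic contact-map generator
#'
#' Describes a genome and the structure planted in its expected contact map:
#' power-law distance decay, an A/B compartment checkerboard, TAD blocks,
#' focal loop pixels, multiplicative bin biases and a constant trans
#' background. Counts are later drawn as independent Poisson variables around
#' this expectation.
#'
#' The compartment modifier is symmetric in log space: pairs sharing a label
#' are multiplied by `exp(+g)` and opposite pairs by `exp(-g)` with
#' `g = log(1 + compartment_contrast)`, so the planted same/opposite contact
#' ratio at equal distance is exactly `exp(2 g)`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp.
#' @param decay_exponent Power-law exponent alpha of contact decay:
#'   expected cis counts scale as `(distance)^-alpha`.
#' @param compartment_contrast Checkerboard contrast `c >= 0`
#'   (`g = log(1 + c)`); 0 disables compartments.
#' @param compartment_block_bins Width of the alternating A/B blocks, in bins,
#'   used when `compartment_labels` is not given.
#' @param compartment_labels Optional explicit per-bin labels (`"A"`/`"B"`).
#' @param tads Optional data frame of planted domains with columns `chrom`,
#'   `start_bin`, `end_bin` (chromosome-local, 0-based, half-open). Domains
#'   must not overlap within a chromosome.
#' @param tad_enrichment Multiplier tau (> 1) applied to pixel pairs with both
#'   bins strictly inside one planted domain.
#' @param loops Optional data frame of planted focal peaks with columns
#'   `chrom`, `bin_i`, `bin_j` (chromosome-local, 0-based, `bin_i < bin_j`).
#' @param loop_enrichment Multiplier lambda (> 1) applied at loop pixels only.
#' @param bias_log_sd Standard deviation of log bin biases
#'   (`log b ~ Normal(0, bias_log_sd^2)`); 0 disables biases.
#' @param trans_background Expected trans count per pixel in units of
#'   `depth_scale` (before biases).
#' @param depth_scale Overall depth multiplier (> 0).
#' @param seed Master seed; each component draws from a named sub-stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths, bin_size,
                       decay_exponent = 1,
                       compartment_contrast = 0,
                       compartment_block_bins = 10,
                       compartment_labels = NULL,
                       tads = NULL, tad_enrichment = 3,
                       loops = NULL, loop_enrichment = 8,
                       bias_log_sd = 0, trans_background = 0,
                       depth_scale = 1, seed = 1L) {
  bins <- bin_table(chrom_lengths, bin_size)
  if (depth_scale <= 0) stopf("depth_scale must be positive")
  if (compartment_contrast < 0) stopf("compartment_contrast must be >= 0")
  if (bias_log_sd < 0) stopf("bias_log_sd must be >= 0")
  if (trans_background < 0) stopf("trans_background must be >= 0")
  if (!is.null(compartment_labels) && length(compartment_labels) != nrow(bins))
    stopf("compartment_labels must have one entry per bin")
  if (!is.null(tads)) {
    for (cn in unique(tads$chrom)) {
      k <- length(chrom_rows(bins, cn))
      if (k == 0) stopf("TAD on unknown chromosome %s", cn)
      iv <- tads[tads$chrom == cn, , drop = FALSE]
      if (any(iv$start_bin < 0) || any(iv$end_bin > k) ||
          any(iv$end_bin <= iv$start_bin))
        stopf("TAD interval out of bounds on %s", cn)
      iv <- iv[order(iv$start_bin), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv$start_bin[-1] < iv$end_bin[-nrow(iv)]))
        stopf("TAD intervals overlap on %s", cn)
    }
    if (tad_enrichment <= 1) stopf("tad_enrichment must be > 1")
  }
  if (!is.null(loops)) {
    for (r in seq_len(nrow(loops))) {
      k <- length(chrom_rows(bins, loops$chrom[r]))
      if (k == 0) stopf("loop on unknown chromosome %s", loops$chrom[r])
      if (loops$bin_i[r] >= loops$bin_j[r] ||
          loops$bin_i[r] < 0 || loops$bin_j[r] >= k)
        stopf("loop pixel must satisfy 0 <= bin_i < bin_j < n_bins")
    }
    if (loop_enrichment <= 1) stopf("loop_enrichment must be > 1")
  }
  structure(list(bins = bins, bin_size = bin_size,
                 decay_exponent = decay_exponent,
                 compartment_contrast = compartment_contrast,
                 compartment_block_bins = compartment_block_bins,
                 compartment_labels = compartment_labels,
                 tads = tads, tad_enrichment = tad_enrichment,
                 loops = loops, loop_enrichment = loop_enrichment,
                 bias_log_sd = bias_log_sd,
                 trans_background = trans_background,
                 depth_scale = depth_scale, seed = seed),
            class = "sim_config")
}

default_labels <- function(bins, block_bins) {
  lab <- character(nrow(bins))
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    blk <- ((seq_along(rows) - 1L) %/% block_bins) %% 2
    lab[rows] <- ifelse(blk == 0, "A", "B")
  }
  lab
}

#' Simulate a binned Hi-C contact map with planted structure
#'
#' Builds the noise-free expected matrix described by the configuration and
#' draws one symmetric matrix of independent Poisson counts around it. The
#' expected intra-chromosomal count at bin separation `d` is
#' `depth_scale * (d * bin_size)^-alpha` (the diagonal reuses the `d = 1`
#' value), modified multiplicatively by the compartment checkerboard, TAD
#' blocks, loop pixels and bin biases; trans pixels get
#' `trans_background * depth_scale * b_i * b_j`.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (raw `contact_matrix`), `bins`, and `truth`
#'   (class `truth_set`): planted `labels`, `tads`, `loops`, `biases`, and the
#'   noise-free `expected` matrix.
#' @export
simulate_contact_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- config$bins
  n <- nrow(bins)
  bs <- config$bin_size

  lab <- config$compartment_labels %||%
    default_labels(bins, config$compartment_block_bins)

  b <- rep(1, n)
  if (config$bias_log_sd > 0)
    b <- with_seed(stream_seed(config$seed, "bias"),
                   exp(stats::rnorm(n, 0, config$bias_log_sd)))

  E <- matrix(config$trans_background * config$depth_scale, n, n)
  g <- log(1 + config$compartment_contrast)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    d <- abs(outer(seq_len(k), seq_len(k), `-`))
    d[d == 0] <- 1  # diagonal pinned to the adjacent-bin value
    sub <- config$depth_scale * (d * bs)^(-config$decay_exponent)
    if (g > 0) {
      s <- outer(lab[rows] == "A", lab[rows] == "A", `==`)  # same-label?
      sub <- sub * exp(ifelse(s, g, -g))
    }
    if (!is.null(config$tads)) {
      iv <- config$tads[config$tads$chrom == cn, , drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        span <- (iv$start_bin[r] + 1):iv$end_bin[r]
        sub[span, span] <- sub[span, span] * config$tad_enrichment
      }
    }
    if (!is.null(config$loops)) {
      lp <- config$loops[config$loops$chrom == cn, , drop = FALSE]
      for (r in seq_len(nrow(lp))) {
        i <- lp$bin_i[r] + 1L; j <- lp$bin_j[r] + 1L
        sub[i, j] <- sub[i, j] * config$loop_enrichment
        sub[j, i] <- sub[j, i] * config$loop_enrichment
      }
    }
    E[rows, rows] <- sub
  }
  E <- E * outer(b, b)

  counts <- with_seed(stream_seed(config$seed, "counts"), {
    up <- upper.tri(E, diag = TRUE)
    M <- matrix(0, n, n)
    M[up] <- stats::rpois(sum(up), E[up])
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  })

  truth <- structure(list(labels = lab,
                          tads = config$tads,
                          loops = config$loops,
                          biases = b,
                          expected = E),
                     class = "truth_set")
  list(matrix = contact_matrix(counts, bins, kind = "raw"),
       bins = bins, truth = truth)
}

#' Simulate a pair of PC1-like tracks with block-structured correlation
#'
#' Draws two standard-normal tracks whose per-bin correlation is `r_in`
#' inside `conserved_blocks` and `r_out` elsewhere, as substrate for
#' sliding-window conservation analysis.
#'
#' @param bins A [bin_table()] (or an integer bin count; a single chromosome
#'   with 400-kb bins is then assumed).
#' @param conserved_blocks Data frame with `chrom`, `start`, `end` (bp); a bin
#'   is inside a block when its midpoint is.
#' @param r_in,r_out Correlations inside/outside the blocks
#'   (`-1 <= r_out < r_in <= 1`).
#' @param seed Seed for the draw.
#' @return A list of two `scalar_track`s (`a`, `b`) plus the per-bin
#'   `in_block` indicator.
#' @export
simulate_pc1_pair <- function(bins, conserved_blocks, r_in, r_out, seed = 1L) {
  if (is.numeric(bins) && length(bins) == 1) {
    if (bins < 1) stopf("empty track")
    bins <- bin_table(c(chr1 = bins * 4e5), 4e5)
  }
  if (nrow(bins) == 0) stopf("empty track")
  if (r_out > r_in || r_in > 1 || r_out < -1)
    stopf("need -1 <= r_out <= r_in <= 1")
  mid <- (bins$start + bins$end) / 2
  inb <- rep(FALSE, nrow(bins))
  for (r in seq_len(NROW(conserved_blocks))) {
    inb <- inb | (bins$chrom == conserved_blocks$chrom[r] &
                    mid >= conserved_blocks$start[r] &
                    mid < conserved_blocks$end[r])
  }
  rho <- ifelse(inb, r_in, r_out)
  vals <- with_seed(stream_seed(seed, "pc1pair"), {
    x <- stats::rnorm(nrow(bins))
    z <- stats::rnorm(nrow(bins))
    list(x = x, y = rho * x + sqrt(pmax(0, 1 - rho^2)) * z)
  })
  list(a = scalar_track(bins, vals$x),
       b = scalar_track(bins, vals$y),
       in_block = inb)
}

#' Simulate a log-normal expression table with a shifted group
#'
#' @param genes Data frame with a `gene_id` column (duplicates rejected).
#' @param high_set Character vector of gene ids whose log-mean is shifted up.
#' @param effect Shift of the log mean, in units of the log-sd (>= 0).
#' @param seed Seed for the draw.
#' @return Data frame `gene_id`, `value`.
#' @export
simulate_expression_table <- function(genes, high_set = character(), effect = 0,
                                      seed = 1L) {
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene ids")
  if (effect < 0) stopf("effect must be >= 0")
  hi <- genes$gene_id %in% high_set
  vals <- with_seed(stream_seed(seed, "expression"),
                    exp(stats::rnorm(nrow(genes), mean = 1 + effect * hi, sd = 1)))
  data.frame(gene_id = genes$gene_id, value = vals, stringsAsFactors = FALSE)
}
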