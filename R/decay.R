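#' Contact probability as a function of genomic distance
#'
#' For each separation `d = k * bin_size` (k >= 1), averages the
#' intra-chromosomal pixel values at that separation over all unmasked pixel
#' positions genome-wide (zeros included), then normalises the curve to sum
#' to 1 across the represented distances.
#'
#' @param m A `contact_matrix` (raw or balanced).
#' @return A `data.frame` of class `decay_curve` with `distance` (bp) and
#'   `probability`.
#' @export
contact_probability <- function(m) {
  if (!m$kind %in% c("raw", "balanced"))
    stopf("contact_probability expects a raw or balanced matrix")
  bins <- m$bins
  bs <- bin_size_of(bins)
  kmax <- max(table(bins$chrom)) - 1
  if (kmax < 1) stopf("no intra-chromosomal separations available")
  sums <- numeric(kmax)
  counts <- numeric(kmax)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    sub <- m$mat[rows, rows, drop = FALSE]
    u <- !m$mask[rows]
    if (k < 2) next
    for (d in 1:(k - 1)) {
      i <- seq_len(k - d)
      valid <- u[i] & u[i + d]
      if (!any(valid)) next
      v <- sub[cbind(i[valid], i[valid] + d)]
      sums[d] <- sums[d] + sum(v, na.rm = TRUE)
      counts[d] <- counts[d] + sum(!is.na(v))
    }
  }
  keep <- counts > 0
  if (!any(keep) || sum(sums) == 0)
    stopf("matrix has no intra-chromosomal entries")
  p <- sums[keep] / counts[keep]
  out <- data.frame(distance = which(keep) * bs, probability = p / sum(p))
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Smooth a decay curve and compute its log-log slope
#'
#' LOWESS-smooths `log10(probability)` against `log10(distance)` and takes
#' centred finite differences of the smoothed curve as the local slope
#' `d log p / d log s` (one-sided at the ends).
#'
#' @param curve A [contact_probability()] result.
#' @param smooth_frac LOWESS smoother span.
#' @return The curve with added `smoothed` and `slope` columns (support
#'   restricted to distances with positive probability).
#' @export
slope_curve <- function(curve, smooth_frac = 0.3) {
  keep <- curve$probability > 0
  if (sum(keep) < 10) stopf("need at least 10 distances with nonzero probability")
  x <- log10(curve$distance[keep])
  y <- log10(curve$probability[keep])
  fit <- stats::lowess(x, y, f = smooth_frac)
  ys <- fit$y[match(x, fit$x)]
  n <- length(x)
  slope <- numeric(n)
  slope[1] <- (ys[2] - ys[1]) / (x[2] - x[1])
  slope[n] <- (ys[n] - ys[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (ys[i + 1] - ys[i - 1]) / (x[i + 1] - x[i - 1])
  }
  out <- data.frame(distance = curve$distance[keep],
                    probability = curve$probability[keep],
                    smoothed = 10^ys, slope = slope)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Short- and long-range cis contact fractions
#'
#' Splits intra-chromosomal counts at a genomic-distance threshold (default
#' 2 Mb). Pixels exactly at the threshold count as long-range.
#'
#' @param m A raw `contact_matrix`.
#' @param threshold Distance threshold in bp.
#' @return Named numeric `c(short_frac, long_frac)`.
#' @export
cis_fractions <- function(m, threshold = 2e6) {
  if (m$kind != "raw") stopf("cis_fractions expects a raw matrix")
  bins <- m$bins
  short <- 0; long <- 0
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    sub <- m$mat[rows, rows, drop = FALSE]
    d <- abs(outer(bins$start[rows], bins$start[rows], `-`))
    up <- upper.tri(sub, diag = TRUE)
    short <- short + sum(sub[up & d < threshold])
    long <- long + sum(sub[up & d >= threshold])
  }
  tot <- short + long
  if (tot == 0) stopf("matrix has no cis counts")
  c(short_frac = short / tot, long_frac = long / tot)
}

#' Per-chromosome trans/cis contact partition
#'
#' Counts involving a chromosome are taken row-wise over the full symmetric
#' matrix (each cis pixel contributes from both of its bins; each trans pixel
#' once per involved chromosome), the standard coverage bookkeeping.
#'
#' @param m A raw `contact_matrix` with at least two chromosomes.
#' @return Data frame `chrom`, `trans_frac`, `cis_frac`.
#' @export
trans_cis_partition <- function(m) {
  if (m$kind != "raw") stopf("trans_cis_partition expects a raw matrix")
  bins <- m$bins
  cns <- chrom_names(bins)
  if (length(cns) < 2) stopf("need at least two chromosomes")
  out <- lapply(cns, function(cn) {
    rows <- chrom_rows(bins, cn)
    sub <- m$mat[rows, rows, drop = FALSE]
    cis <- sum(sub)
    trans <- sum(m$mat[rows, -rows])
    data.frame(chrom = cn, trans_frac = trans / (cis + trans),
               cis_frac = cis / (cis + trans), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

trans_pair_counts <- function(m) {
  bins <- m$bins
  cns <- chrom_names(bins)
  C <- length(cns)
  tp <- matrix(0, C, C, dimnames = list(cns, cns))
  for (a in seq_len(C - 1)) for (b in (a + 1):C) {
    ra <- chrom_rows(bins, cns[a]); rb <- chrom_rows(bins, cns[b])
    tp[a, b] <- tp[b, a] <- sum(m$mat[ra, rb])
  }
  tp
}

#' Observed/expected trans contacts per chromosome pair
#'
#' Expected counts under independence:
#' `expected(p, q) = T_p * T_q / (2 * T)` where `T_p` is chromosome `p`'s
#' total trans count and `T` the genome-wide trans total.
#'
#' @param m A raw `contact_matrix` with at least three chromosomes.
#' @return Symmetric matrix of obs/exp enrichments (diagonal `NA`).
#' @export
chrom_pair_enrichment <- function(m) {
  if (m$kind != "raw") stopf("chrom_pair_enrichment expects a raw matrix")
  cns <- chrom_names(m$bins)
  if (length(cns) < 3) stopf("need at least three chromosomes")
  tp <- trans_pair_counts(m)
  Tp <- rowSums(tp)
  Tt <- sum(tp) / 2
  if (Tt == 0) stopf("matrix has no trans counts")
  expd <- outer(Tp, Tp) / (2 * Tt)
  enr <- tp / expd
  diag(enr) <- NA
  enr
}

#' Chromosome-pair enrichment against chromosome-length ratio
#'
#' Pairs `log2(L_i / L_j)` (with `L_i > L_j`) with the trans obs/exp
#' enrichment of each chromosome pair, for trend fitting against length.
#'
#' @param m A raw `contact_matrix` with at least three chromosomes.
#' @return Data frame `chrom_i`, `chrom_j`, `log2_length_ratio`, `enrichment`.
#' @export
length_normalized_trend <- function(m) {
  enr <- chrom_pair_enrichment(m)
  bins <- m$bins
  cns <- chrom_names(bins)
  L <- vapply(cns, function(cn) max(bins$end[chrom_rows(bins, cn)]), numeric(1))
  rows <- list()
  for (a in seq_len(length(cns) - 1)) for (b in (a + 1):length(cns)) {
    i <- if (L[a] >= L[b]) a else b
    j <- if (L[a] >= L[b]) b else a
    rows[[length(rows) + 1L]] <-
      data.frame(chrom_i = cns[i], chrom_j = cns[j],
                 log2_length_ratio = log2(L[i] / L[j]),
                 enrichment = enr[i, j], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
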