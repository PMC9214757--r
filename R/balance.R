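#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by iteratively dividing each pixel by
#' the product of its row-sum factors until all unmasked row sums agree.
#' Bins with zero coverage, plus the lowest `mask_low_frac` coverage quantile,
#' are masked before correction.
#'
#' The returned biases satisfy `balanced(i,j) == raw(i,j) / (bias_i * bias_j)`
#' up to one global scale.
#'
#' @param m A `contact_matrix` (raw counts; a balanced matrix may be passed to
#'   re-balance, e.g. to verify the fixed point).
#' @param max_iter Maximum number of correction sweeps.
#' @param tol Convergence tolerance on the maximum relative deviation of
#'   unmasked row sums from their mean.
#' @param mask_low_frac Fraction of lowest-coverage bins masked before
#'   correction.
#' @return A list with `matrix` (kind `"balanced"`, masked bins `NA`, with a
#'   `converged` attribute) and `biases` (per-bin multipliers, `NA` on masked
#'   bins).
#' @export
ice_normalize <- function(m, max_iter = 200, tol = 1e-5, mask_low_frac = 0.02) {
  if (!m$kind %in% c("raw", "balanced"))
    stopf("ice_normalize expects a raw (or balanced) matrix")
  n <- nrow(m$mat)
  W <- m$mat
  W[is.na(W)] <- 0
  cov <- rowSums(W)
  mask <- m$mask | cov == 0
  if (mask_low_frac > 0 && any(!mask)) {
    thr <- stats::quantile(cov[cov > 0], mask_low_frac)
    mask <- mask | (cov > 0 & cov < thr)
  }
  if (sum(!mask) < 2) stopf("fewer than 2 unmasked bins after coverage filtering")
  W[mask, ] <- 0
  W[, mask] <- 0

  bias <- rep(NA_real_, n)
  bias[!mask] <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    s <- rowSums(W)[!mask]
    rel <- s / mean(s)
    if (max(abs(rel - 1)) < tol) { converged <- TRUE; break }
    v <- rep(1, n)
    v[!mask] <- rel
    W <- W / outer(v, v)
    bias[!mask] <- bias[!mask] * rel
  }
  W[mask, ] <- NA
  W[, mask] <- NA
  out <- contact_matrix(W, m$bins, kind = "balanced", mask = mask)
  attr(out, "converged") <- converged
  if (!converged) warnf("ICE did not converge within %d iterations", max_iter)
  list(matrix = out, biases = bias)
}

#' Observed/expected transformation of a balanced matrix
#'
#' Divides each intra-chromosomal pixel by the mean balanced value at its
#' genomic separation, computed per chromosome over unmasked pixel positions
#' with zeros included. Separations whose expected value is zero, and all
#' trans pixels, are undefined (`NA`).
#'
#' @param m A balanced `contact_matrix`.
#' @return A `contact_matrix` of kind `"observed_expected"`.
#' @export
observed_expected <- function(m) {
  if (m$kind != "balanced")
    stopf("observed_expected requires a balanced matrix (run ice_normalize first)")
  bins <- m$bins
  n <- nrow(m$mat)
  OE <- matrix(NA_real_, n, n)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    sub <- m$mat[rows, rows, drop = FALSE]
    u <- !m$mask[rows]
    for (d in 0:(k - 1)) {
      i <- seq_len(k - d)
      j <- i + d
      valid <- u[i] & u[j]
      if (!any(valid)) next
      e <- mean(sub[cbind(i[valid], j[valid])])
      if (!is.finite(e) || e == 0) next
      v <- sub[cbind(i, j)] / e
      v[!valid] <- NA
      OE[cbind(rows[i], rows[j])] <- v
      OE[cbind(rows[j], rows[i])] <- v
    }
  }
  contact_matrix(OE, bins, kind = "observed_expected", mask = m$mask)
}
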