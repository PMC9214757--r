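# Poisson upper tail P(X >= observed) for the loop test
loop_pvalue <- function(observed, expected) {
  stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Call focal chromatin loops with local expected models
#'
#' A simplified donut-style caller: every intra-chromosomal pixel in the
#' distance band `[min_dist, max_dist]` is tested against two local expected
#' models computed on the bias-corrected matrix — the donut annulus between
#' `peak_radius` and `donut_radius` (excluding the pixel's row and column)
#' and the lower-left quadrant block. The larger expected value, rescaled to
#' raw space through the bin biases, parameterises a Poisson upper-tail test;
#' Benjamini-Hochberg adjustment is applied over all tested pixels and
#' 8-connected significant pixels are merged into one call whose summit is
#' the most significant pixel (ties: larger observed count, then smaller
#' upstream bin).
#'
#' @param m A raw `contact_matrix`.
#' @param biases Per-bin bias vector from [ice_normalize()].
#' @param peak_radius Peak half-width in bins excluded from both expected
#'   models.
#' @param donut_radius Outer radius of the local neighbourhood in bins.
#' @param min_dist Minimum anchor separation in bins.
#' @param max_dist Maximum anchor separation in bp.
#' @param alpha Adjusted-p threshold for a significant pixel.
#' @param fold_min Minimum observed/expected ratio for a significant pixel;
#'   at deep coverage even mild local model misfit is statistically
#'   significant, so focal calls additionally require this enrichment.
#' @return A `data.frame` of class `loop_calls` (`chrom`, `bin_i`, `bin_j`
#'   chromosome-local 0-based summit bins, anchor coordinates, `observed`,
#'   `expected`, `p_adj`, `n_pixels`) with attribute `n_tested`.
#' @export
call_loops <- function(m, biases, peak_radius = 1, donut_radius = 5,
                       min_dist = 4, max_dist = 2e6, alpha = 0.001,
                       fold_min = 2) {
  if (m$kind != "raw") stopf("call_loops expects the raw matrix plus ICE biases")
  bins <- m$bins
  bs <- bin_size_of(bins)
  maxd_bins <- floor(max_dist / bs)
  if (maxd_bins < min_dist) stopf("distance band is empty")
  R <- donut_radius; P <- peak_radius

  donut_off <- list(); ll_off <- list()
  for (di in -R:R) for (dj in -R:R) {
    if (max(abs(di), abs(dj)) > R || max(abs(di), abs(dj)) <= P) next
    if (di != 0 && dj != 0) donut_off[[length(donut_off) + 1L]] <- c(di, dj)
    if (di >= 1 && dj <= -1) ll_off[[length(ll_off) + 1L]] <- c(di, dj)
  }

  res <- list(); n_tested <- 0L
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    n <- length(rows)
    if (n <= min_dist) next
    b <- biases[rows]
    Braw <- m$mat[rows, rows, drop = FALSE]
    Bbal <- Braw / outer(b, b)
    valid <- is.finite(Bbal)
    Bz <- Bbal; Bz[!valid] <- 0

    # distance-expected profile so neighbourhood means are taken on the
    # decay-flattened field (otherwise the convex power law biases the donut)
    dmat <- abs(col(Braw) - row(Braw))
    edist <- vapply(0:(n - 1), function(d) {
      i <- seq_len(n - d)
      v <- Bbal[cbind(i, i + d)]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    Emat <- matrix(edist[dmat + 1L], n, n)
    valid <- valid & Emat > 0
    Bz <- Bbal / Emat
    Bz[!valid] <- 0

    neigh <- function(offs) {
      S <- matrix(0, n, n); Cn <- matrix(0, n, n)
      for (o in offs) {
        di <- o[1]; dj <- o[2]
        ri <- max(1, 1 - di):min(n, n - di)
        rj <- max(1, 1 - dj):min(n, n - dj)
        S[ri, rj] <- S[ri, rj] + Bz[ri + di, rj + dj, drop = FALSE]
        Cn[ri, rj] <- Cn[ri, rj] + valid[ri + di, rj + dj, drop = FALSE]
      }
      S / pmax(Cn, 1) * (Cn > 0)
    }
    Ed <- neigh(donut_off)
    El <- neigh(ll_off)
    Ebal <- pmax(Ed, El) * Emat

    cand <- which(col(Braw) - row(Braw) >= min_dist &
                    col(Braw) - row(Braw) <= maxd_bins & valid &
                    Ebal > 0, arr.ind = TRUE)
    if (!nrow(cand)) next
    eraw <- Ebal[cand] * b[cand[, 1]] * b[cand[, 2]]
    obs <- Braw[cand]
    p <- loop_pvalue(obs, eraw)
    res[[cn]] <- data.frame(chrom = cn, i = cand[, 1], j = cand[, 2],
                            observed = obs, expected = eraw, p = p,
                            stringsAsFactors = FALSE)
    n_tested <- n_tested + nrow(cand)
  }
  if (!length(res)) stopf("distance band is empty")
  tab <- do.call(rbind, res)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  sig <- tab[tab$p_adj < alpha & tab$observed >= fold_min * tab$expected, ,
             drop = FALSE]

  calls <- list()
  for (cn in unique(sig$chrom)) {
    s <- sig[sig$chrom == cn, , drop = FALSE]
    # 8-connected components among significant pixels
    comp <- seq_len(nrow(s))
    repeat {
      changed <- FALSE
      for (a in seq_len(nrow(s))) {
        nb <- which(abs(s$i - s$i[a]) <= 1 & abs(s$j - s$j[a]) <= 1 &
                      comp != comp[a])
        if (length(nb)) {
          newc <- min(comp[a], comp[nb])
          comp[c(a, nb)] <- newc
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    rows <- chrom_rows(bins, cn)
    for (g in unique(comp)) {
      grp <- s[comp == g, , drop = FALSE]
      ord <- order(grp$p_adj, -grp$observed, grp$i, grp$j)
      top <- grp[ord[1], ]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = cn, bin_i = top$i - 1L, bin_j = top$j - 1L,
        anchor1_start = bins$start[rows[top$i]],
        anchor1_end = bins$end[rows[top$i]],
        anchor2_start = bins$start[rows[top$j]],
        anchor2_end = bins$end[rows[top$j]],
        observed = top$observed, expected = top$expected,
        p_adj = top$p_adj, n_pixels = nrow(grp), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(chrom = character(), bin_i = integer(),
                         bin_j = integer(), anchor1_start = numeric(),
                         anchor1_end = numeric(), anchor2_start = numeric(),
                         anchor2_end = numeric(), observed = numeric(),
                         expected = numeric(), p_adj = numeric(),
                         n_pixels = integer(), stringsAsFactors = FALSE)
  attr(out, "n_tested") <- n_tested
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Write loop calls as BEDPE
#'
#' @param loops A [call_loops()] result.
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(
    data.frame(loops$chrom,
               format(loops$anchor1_start, scientific = FALSE, trim = TRUE),
               format(loops$anchor1_end, scientific = FALSE, trim = TRUE),
               loops$chrom,
               format(loops$anchor2_start, scientific = FALSE, trim = TRUE),
               format(loops$anchor2_end, scientific = FALSE, trim = TRUE),
               loops$observed,
               sprintf("%.6g", loops$expected),
               sprintf("%.6g", loops$p_adj)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag genes whose promoter falls in a loop anchor and compare expression
#'
#' A gene is in-loop when its promoter (the start coordinate; the end for
#' minus-strand genes when a `strand` column is present) lies inside either
#' anchor interval of any loop. Expression of the two groups is compared with
#' a Wilcoxon rank-sum test.
#'
#' @param loops A [call_loops()] result.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param expression Data frame `gene_id`, `value`.
#' @return List with the annotated `genes` table, group sizes `n_in` /
#'   `n_out`, and the rank-sum `statistic` and `p` (NA when a group is
#'   empty).
#' @export
annotate_loops <- function(loops, genes, expression) {
  if (!nrow(genes)) stopf("empty gene set")
  minus <- if (is.null(genes$strand)) rep(FALSE, nrow(genes))
           else genes$strand == "-"
  prom <- ifelse(minus, genes$end, genes$start)
  inloop <- rep(FALSE, nrow(genes))
  for (r in seq_len(nrow(loops))) {
    same <- genes$chrom == loops$chrom[r]
    inloop <- inloop | (same & prom >= loops$anchor1_start[r] &
                          prom < loops$anchor1_end[r]) |
                       (same & prom >= loops$anchor2_start[r] &
                          prom < loops$anchor2_end[r])
  }
  genes$in_loop <- inloop
  ex <- expression$value[match(genes$gene_id, expression$gene_id)]
  stat <- NA_real_; p <- NA_real_
  if (any(inloop) && any(!inloop)) {
    wt <- stats::wilcox.test(ex[inloop], ex[!inloop], exact = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  list(genes = genes, n_in = sum(inloop), n_out = sum(!inloop),
       statistic = stat, p = p)
}
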