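# Quantile-normalise a list of numeric vectors to their common average
# distribution (rank-based, ties averaged). Vectors of unequal length are
# matched through interpolated quantiles of the averaged sorted profile.
quantile_normalize_values <- function(value_list) {
  lens <- lengths(value_list)
  L <- max(lens)
  grid <- if (L == 1) 0.5 else seq(0, 1, length.out = L)
  profiles <- lapply(value_list, function(v) {
    sv <- sort(v)
    if (length(sv) == L) sv
    else stats::approx(seq(0, 1, length.out = length(sv)), sv, xout = grid,
                       rule = 2)$y
  })
  ref <- Reduce(`+`, profiles) / length(profiles)
  lapply(value_list, function(v) {
    r <- rank(v, ties.method = "average")
    q <- if (length(v) == 1) 0.5 else (r - 1) / (length(v) - 1)
    stats::approx(grid, ref, xout = q, rule = 2)$y
  })
}

#' Quantile-normalised difference of two stage matrices
#'
#' The stored non-zero pixel values of every stage matrix are
#' quantile-normalised to their common average distribution (rank-based,
#' ties averaged); the result is the entry-wise difference
#' `stages[[pair[1]]] - stages[[pair[2]]]`.
#'
#' @param stages List of balanced `contact_matrix` objects on one bin table.
#' @param pair Length-2 index vector selecting the difference pair.
#' @return A `contact_matrix` of kind `"difference"`.
#' @export
deconvolve <- function(stages, pair = c(1, 2)) {
  ref <- stages[[1]]
  for (m in stages) {
    if (!same_bins(m$bins, ref$bins)) stopf("bin tables differ between stages")
    if (m$kind != "balanced") stopf("deconvolve expects balanced matrices")
  }
  up <- upper.tri(ref$mat, diag = TRUE)
  sel <- lapply(stages, function(m) which(up & m$mat != 0 & !is.na(m$mat)))
  vals <- quantile_normalize_values(
    Map(function(m, s) m$mat[s], stages, sel))
  normed <- Map(function(m, s, v) {
    out <- m$mat
    out[!is.na(out)] <- 0
    out[s] <- v
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
    out
  }, stages, sel, vals)
  diffm <- normed[[pair[1]]] - normed[[pair[2]]]
  contact_matrix(diffm, ref$bins, kind = "difference",
                 mask = stages[[pair[1]]]$mask | stages[[pair[2]]]$mask)
}

#' Conserved regions from sliding-window PC1 correlation
#'
#' Slides windows of `window` bp (stepping by `step`) along each chromosome,
#' computes Pearson correlation between the two tracks over co-defined bins,
#' and merges overlapping windows with `r > r_threshold` into maximal
#' regions annotated with the mean r of their contributing windows.
#'
#' A sample correlation over one window of `window / bin_size` bins is noisy,
#' and the r values of overlapping windows are dependent over about two
#' window widths, so single noise excursions above the threshold produce
#' short spurious regions; merged regions must span at least `min_span`
#' (default three window widths) to be reported.
#'
#' @param pc1_a,pc1_b `scalar_track`s on one bin table.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @param r_threshold Minimum correlation for a window to qualify.
#' @param min_span Minimum merged-region span in bp (default `3 * window`).
#' @return Data frame `chrom`, `start`, `end`, `mean_r` of maximal regions.
#' @export
conserved_regions <- function(pc1_a, pc1_b, window = 2e6, step = 4e5,
                              r_threshold = 0.6, min_span = NULL) {
  if (is.null(min_span)) min_span <- 3 * window
  if (nrow(pc1_a) != nrow(pc1_b)) stopf("tracks are on different bin tables")
  bs <- bin_size_of(pc1_a)
  wb <- max(2, round(window / bs))
  sb <- max(1, round(step / bs))
  regions <- list()
  for (cn in unique(pc1_a$chrom)) {
    rows <- which(pc1_a$chrom == cn)
    k <- length(rows)
    if (k < wb) next
    wins <- list()
    for (s in seq(1, k - wb + 1, by = sb)) {
      span <- rows[s:(s + wb - 1)]
      va <- pc1_a$value[span]; vb <- pc1_b$value[span]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) < 3) next
      if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) next
      r <- stats::cor(va[ok], vb[ok])
      if (!is.finite(r) || r <= r_threshold) next
      wins[[length(wins) + 1L]] <- c(pc1_a$start[span[1]],
                                     pc1_a$end[span[wb]], r)
    }
    if (!length(wins)) next
    # merge all overlapping qualifying windows into maximal regions
    cur <- NULL
    for (w in wins) {
      if (is.null(cur)) {
        cur <- list(chrom = cn, start = w[1], end = w[2], rs = w[3])
      } else if (w[1] < cur$end) {
        cur$end <- max(cur$end, w[2])
        cur$rs <- c(cur$rs, w[3])
      } else {
        regions[[length(regions) + 1L]] <- cur
        cur <- list(chrom = cn, start = w[1], end = w[2], rs = w[3])
      }
    }
    regions[[length(regions) + 1L]] <- cur
  }
  regions <- Filter(function(g) g$end - g$start >= min_span, regions)
  if (!length(regions))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mean_r = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(regions, function(g)
    data.frame(chrom = g$chrom, start = g$start, end = g$end,
               mean_r = mean(g$rs), stringsAsFactors = FALSE)))
}

#' Hierarchical clustering of PC1 profiles across samples
#'
#' Distance between samples is `1 - Pearson r` over co-defined bins;
#' agglomeration is average linkage.
#'
#' @param tracks Named list of `scalar_track`s on one bin table.
#' @return An `hclust` tree with sample labels.
#' @export
cluster_profiles <- function(tracks) {
  if (length(tracks) < 2) stopf("need at least two samples")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stopf("tracks must be named by sample")
  V <- vapply(tracks, function(t) t$value, numeric(nrow(tracks[[1]])))
  for (s in names(tracks)) {
    v <- V[, s]
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
      stopf("track '%s' is constant; correlation distance undefined", s)
  }
  D <- 1 - stats::cor(V, use = "pairwise.complete.obs")
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Write a dendrogram in Newick format
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

check_disjoint <- function(regions) {
  for (cn in unique(regions$chrom)) {
    r <- regions[regions$chrom == cn, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stopf("regions overlap within chromosome %s", cn)
  }
  invisible(TRUE)
}

#' Base-pair overlap between two disjoint region sets
#'
#' @param a,b Data frames `chrom`, `start`, `end`; regions must be
#'   non-overlapping within each set.
#' @return Named numeric `only_a_bp`, `shared_bp`, `only_b_bp`.
#' @export
region_overlap <- function(a, b) {
  check_disjoint(a); check_disjoint(b)
  shared <- 0
  for (cn in union(unique(a$chrom), unique(b$chrom))) {
    ra <- a[a$chrom == cn, , drop = FALSE]
    rb <- b[b$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb)))
      shared <- shared + max(0, min(ra$end[i], rb$end[j]) -
                                  max(ra$start[i], rb$start[j]))
  }
  tot_a <- sum(a$end - a$start)
  tot_b <- sum(b$end - b$start)
  c(only_a_bp = tot_a - shared, shared_bp = shared, only_b_bp = tot_b - shared)
}

#' Fisher's exact enrichment of features within regions over a bin universe
#'
#' Classifies each universe bin by whether it overlaps a region and whether
#' it overlaps a feature, and tests the 2x2 table with a two-sided Fisher
#' exact test. With a zero margin the p-value is 1 and the odds ratio
#' undefined.
#'
#' @param regions Data frame `chrom`, `start`, `end`.
#' @param features Data frame `chrom`, `start`, `end`.
#' @param universe A [bin_table()].
#' @return List of class `enrichment_result`: `table`, `odds_ratio`, `p`,
#'   `p_adj` (NA until batch adjustment).
#' @export
fisher_enrichment <- function(regions, features, universe) {
  if (!nrow(universe)) stopf("empty universe")
  overlaps_any <- function(set) {
    hit <- rep(FALSE, nrow(universe))
    for (r in seq_len(NROW(set))) {
      hit <- hit | (universe$chrom == set$chrom[r] &
                      universe$end > set$start[r] &
                      universe$start < set$end[r])
    }
    hit
  }
  in_reg <- overlaps_any(regions)
  has_feat <- overlaps_any(features)
  tab <- matrix(c(sum(in_reg & has_feat), sum(in_reg & !has_feat),
                  sum(!in_reg & has_feat), sum(!in_reg & !has_feat)),
                2, 2, byrow = TRUE,
                dimnames = list(c("in_region", "out_region"),
                                c("feature", "no_feature")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res <- list(table = tab, odds_ratio = NA_real_, p = 1, p_adj = NA_real_)
  } else {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    res <- list(table = tab, odds_ratio = or, p = ft$p.value, p_adj = NA_real_)
  }
  class(res) <- "enrichment_result"
  res
}

#' Benjamini-Hochberg adjustment over a batch of enrichment tests
#'
#' @param regions Data frame of regions shared by the batch.
#' @param feature_sets Named list of feature data frames.
#' @param universe A [bin_table()].
#' @return Named list of `enrichment_result`s with `p_adj` filled in.
#' @export
fisher_enrichment_batch <- function(regions, feature_sets, universe) {
  res <- lapply(feature_sets, fisher_enrichment, regions = regions,
                universe = universe)
  padj <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p"), method = "BH")
  for (i in seq_along(res)) res[[i]]$p_adj <- padj[i]
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> OR = %s, p = %.4g%s\n",
              ifelse(is.na(x$odds_ratio), "NA", sprintf("%.3f", x$odds_ratio)),
              x$p,
              ifelse(is.na(x$p_adj), "", sprintf(", p_adj = %.4g", x$p_adj))))
  print(x$table)
  invisible(x)
}
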