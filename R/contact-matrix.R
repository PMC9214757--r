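#' Construct a contact matrix
#'
#' A symmetric binned contact map over a genome bin table. Values are stored
#' densely; masked bins carry `NA` in balanced and derived kinds. `raw`
#' matrices hold non-negative integer counts; `balanced` and
#' `observed_expected` non-negative reals; `difference` may be negative.
#'
#' @param mat Square symmetric numeric matrix, one row/column per bin.
#' @param bins A [bin_table()].
#' @param kind One of `"raw"`, `"balanced"`, `"observed_expected"`,
#'   `"difference"`.
#' @param mask Logical vector flagging excluded bins (default none).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bins,
                           kind = c("raw", "balanced", "observed_expected", "difference"),
                           mask = NULL) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  n <- nrow(bins)
  if (!is.numeric(mat) || nrow(mat) != n || ncol(mat) != n)
    stopf("matrix must be %d x %d numeric to match the bin table", n, n)
  if (is.null(mask)) mask <- rep(FALSE, n)
  ok <- is.finite(mat)
  if (!isTRUE(all.equal(mat[ok & t(ok)], t(mat)[ok & t(ok)], tolerance = 1e-8)))
    stopf("contact matrix must be symmetric")
  vals <- mat[ok]
  if (kind == "raw") {
    if (any(vals < 0) || any(vals != round(vals)))
      stopf("raw matrices must contain non-negative integer counts")
  } else if (kind != "difference" && any(vals < 0)) {
    stopf("%s matrices must be non-negative", kind)
  }
  structure(list(mat = mat, bins = bins, kind = kind, mask = as.logical(mask)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  bs <- bin_size_of(x$bins)
  cat(sprintf("<contact_matrix> %s, %d bins (%s bp) on %d chromosome(s)\n",
              x$kind, nrow(x$bins),
              format(bs, big.mark = ",", scientific = FALSE),
              length(chrom_names(x$bins))))
  tot <- sum(upper_with_diag(x$mat), na.rm = TRUE)
  cat(sprintf("  total (i<=j): %s | masked bins: %d\n",
              format(tot, big.mark = ","), sum(x$mask)))
  if (!is.null(attr(x, "converged")) && !attr(x, "converged"))
    cat("  warning: balancing did not converge\n")
  invisible(x)
}

#' @export
as.matrix.contact_matrix <- function(x, ...) x$mat

upper_with_diag <- function(m) m[upper.tri(m, diag = TRUE)]

# genome-wide count sum, each unordered pair once, diagonal once
total_count <- function(m) sum(upper_with_diag(m$mat), na.rm = TRUE)

#' Read a contact matrix from sparse triplet text plus a BED4 bin table
#'
#' Triplet rows are whitespace-separated `bin_id_1 bin_id_2 value` with
#' 0-based bin ids. Rows with `i > j` are folded onto `(j, i)`; duplicate
#' pixels are summed.
#'
#' @param triplet_path Path to the triplet file (may be empty).
#' @param bins_path Path to the BED4 bin table.
#' @param kind Matrix kind of the stored values (default `"raw"`).
#' @return A `contact_matrix`.
#' @export
read_matrix <- function(triplet_path, bins_path, kind = "raw") {
  bins <- read_bins(bins_path)
  n <- nrow(bins)
  mat <- matrix(0, n, n)
  info <- file.info(triplet_path)
  if (is.na(info$size)) stopf("triplet file not found: %s", triplet_path)
  if (info$size > 0) {
    df <- utils::read.table(triplet_path, header = FALSE, sep = "",
                            col.names = c("i", "j", "value"))
    bad <- which(df$i < 0 | df$i >= n | df$j < 0 | df$j >= n)
    if (length(bad))
      stopf("bin id out of range [0, %d) at line %d of %s", n, bad[1], triplet_path)
    if (kind == "raw") {
      neg <- which(df$value < 0)
      if (length(neg))
        stopf("negative count at line %d of %s", neg[1], triplet_path)
    }
    i <- pmin(df$i, df$j) + 1L
    j <- pmax(df$i, df$j) + 1L
    agg <- rowsum(df$value, group = paste(i, j))
    ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    mat[ij] <- agg[, 1]
    mat[ij[, c(2, 1), drop = FALSE]] <- agg[, 1]
  }
  contact_matrix(mat, bins, kind = kind)
}

#' Write a contact matrix as sorted upper-triangle triplets
#'
#' Only non-zero (and defined) pixels with `i <= j` are emitted, sorted by
#' `(i, j)`, so output is canonical and reproducible.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  n <- nrow(m$mat)
  idx <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0 & !is.na(m$mat),
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.table(
    data.frame(idx[, 1] - 1L, idx[, 2] - 1L,
               sprintf("%.10g", m$mat[idx])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge replicate contact matrices by entry-wise count summation
#'
#' @param matrices List of raw `contact_matrix` objects on one bin table.
#' @return The merged raw `contact_matrix`.
#' @export
merge_replicates <- function(matrices) {
  if (length(matrices) < 1) stopf("need at least one matrix")
  ref <- matrices[[1]]
  for (m in matrices) {
    if (m$kind != "raw") stopf("merge_replicates expects raw matrices")
    if (!same_bins(m$bins, ref$bins)) stopf("bin tables differ between replicates")
  }
  out <- Reduce(`+`, lapply(matrices, `[[`, "mat"))
  contact_matrix(out, ref$bins, kind = "raw")
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts over `factor` x `factor` blocks within each chromosome,
#' counting each unordered pixel pair once, and rebuilds the bin table at
#' `bin_size * factor`.
#'
#' @param m A raw `contact_matrix`.
#' @param factor Integer coarsening factor (>= 2).
#' @return A raw `contact_matrix` at the coarser resolution.
#' @export
coarsen <- function(m, factor) {
  if (m$kind != "raw") stopf("coarsen expects a raw matrix")
  if (length(factor) != 1 || factor != round(factor) || factor < 2)
    stopf("factor must be a single integer >= 2")
  bins <- m$bins
  bs <- bin_size_of(bins)
  # group fine bins into coarse bins chromosome by chromosome
  grp <- integer(nrow(bins))
  coarse <- list()
  nxt <- 0L
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    local <- floor((bins$start[rows] - min(bins$start[rows])) / (bs * factor))
    grp[rows] <- nxt + as.integer(local)
    for (g in sort(unique(as.integer(local)))) {
      sel <- rows[local == g]
      coarse[[length(coarse) + 1L]] <-
        data.frame(chrom = cn, start = min(bins$start[sel]),
                   end = max(bins$end[sel]), stringsAsFactors = FALSE)
    }
    nxt <- nxt + length(unique(local))
  }
  cb <- do.call(rbind, coarse)
  cb$bin_id <- seq_len(nrow(cb)) - 1L
  attr(cb, "bin_size") <- bs * factor
  class(cb) <- c("bin_table", "data.frame")

  f <- factor(grp, levels = sort(unique(grp)))
  S <- rowsum(m$mat, f)
  C <- t(rowsum(t(S), f))
  # dense block-sum double-counts within-block off-diagonal pairs on the
  # diagonal; correct so each unordered fine pair contributes once
  diag_fine <- rowsum(diag(m$mat), f)[, 1]
  diag(C) <- (diag(C) + diag_fine) / 2
  contact_matrix(C, cb, kind = "raw")
}

#' Pearson correlation between replicates over the short-range band
#'
#' Correlates all intra-chromosomal pixels (shared zeros included) whose
#' genomic separation is at most `max_dist`, the standard reproducibility
#' check for Hi-C replicates.
#'
#' @param a,b `contact_matrix` objects on the same bin table.
#' @param max_dist Maximum genomic separation in bp (default 2 Mb).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(a, b, max_dist = 2e6) {
  if (!same_bins(a$bins, b$bins)) stopf("bin tables differ")
  bins <- a$bins
  va <- numeric(0); vb <- numeric(0)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    k <- length(rows)
    sub_a <- a$mat[rows, rows, drop = FALSE]
    sub_b <- b$mat[rows, rows, drop = FALSE]
    d <- abs(outer(bins$start[rows], bins$start[rows], `-`))
    sel <- upper.tri(d, diag = TRUE) & d <= max_dist
    va <- c(va, sub_a[sel]); vb <- c(vb, sub_b[sel])
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stopf("correlation undefined: zero variance within the distance band")
  stats::cor(va, vb)
}
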