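#' A/B compartment assignment from PC1 of the O/E correlation matrix
#'
#' Per chromosome, computes the Pearson correlation matrix of
#' observed/expected columns over unmasked bins and takes its first principal
#' component. The sign is flipped per chromosome so that the component
#' correlates non-negatively with an orientation track (conventionally gene
#' density or mean expression per bin: the A compartment is the active one).
#' Bins with positive PC1 are labelled `A`, negative `B`.
#'
#' @param oe An [observed_expected()] matrix.
#' @param orientation A `scalar_track` on the same bin table used to fix the
#'   eigenvector sign.
#' @return A list of class `compartment_profile` with `pc1` (scalar_track),
#'   `labels` (per-bin `"A"`/`"B"`/`NA`) and `orientation_evidence` (mean
#'   post-flip correlation with the orientation track).
#' @export
pc1_compartments <- function(oe, orientation) {
  if (oe$kind != "observed_expected")
    stopf("pc1_compartments requires an observed/expected matrix")
  bins <- oe$bins
  if (nrow(orientation) != nrow(bins))
    stopf("orientation track does not match the bin table")
  pc1 <- rep(NA_real_, nrow(bins))
  evid <- c()
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    u <- !oe$mask[rows] & apply(oe$mat[rows, rows, drop = FALSE], 1,
                                function(r) sum(is.finite(r)) > 1)
    if (sum(u) < 10) {
      warnf("chromosome %s has fewer than 10 usable bins; masked", cn)
      next
    }
    sub <- oe$mat[rows[u], rows[u], drop = FALSE]
    C <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    eg <- eigen(C, symmetric = TRUE)
    v <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
    ori <- orientation$value[rows[u]]
    r <- suppressWarnings(stats::cor(v, ori, use = "complete.obs"))
    if (is.finite(r) && r < 0) { v <- -v; r <- -r }
    pc1[rows[u]] <- v
    evid <- c(evid, r)
  }
  labels <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
  structure(list(pc1 = scalar_track(bins, pc1), labels = labels,
                 orientation_evidence = mean(evid, na.rm = TRUE)),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("A", "B")))
  cat(sprintf("<compartment_profile> %d A / %d B / %d masked bins; orientation r = %.3f\n",
              tab[["A"]], tab[["B"]], sum(is.na(x$labels)),
              x$orientation_evidence))
  invisible(x)
}

#' Compartment switch accounting between two stages
#'
#' Joint A/B label counts over bins unmasked in both profiles, and the stable
#' fraction `(AA + BB) / total`.
#'
#' @param a,b `compartment_profile`s on the same bin table.
#' @return List with `counts` (named `AA`, `AB`, `BA`, `BB`) and
#'   `stable_fraction`.
#' @export
switch_table <- function(a, b) {
  la <- a$labels; lb <- b$labels
  if (length(la) != length(lb)) stopf("profiles are on different bin tables")
  ok <- !is.na(la) & !is.na(lb)
  if (!any(ok)) stopf("no co-unmasked bins")
  key <- paste0(la[ok], lb[ok])
  counts <- vapply(c("AA", "AB", "BA", "BB"), function(k) sum(key == k),
                   numeric(1))
  list(counts = counts,
       stable_fraction = (counts[["AA"]] + counts[["BB"]]) / sum(counts))
}

#' Saddle plot and compartment strength
#'
#' Ranks bins by PC1, cuts them into `n_quantiles` groups, and averages O/E
#' over intra-chromosomal pixel pairs per group pair. Compartment strength is
#' the field-standard corner ratio `(AA + BB) / (AB + BA)` over the extreme
#' `corner_frac` of quantile pairs.
#'
#' @param oe An [observed_expected()] matrix.
#' @param pc1 A `scalar_track` of PC1 values on the same bin table.
#' @param n_quantiles Number of PC1 quantile groups.
#' @param corner_frac Fraction of extreme quantiles forming each corner.
#' @return A list of class `saddle_result` with the `saddle` matrix
#'   (quantile 1 = strongest B, `n_quantiles` = strongest A) and `strength`.
#' @export
saddle_strength <- function(oe, pc1, n_quantiles = 5, corner_frac = 0.2) {
  if (oe$kind != "observed_expected")
    stopf("saddle_strength requires an observed/expected matrix")
  bins <- oe$bins
  v <- pc1$value
  use <- !oe$mask & !is.na(v)
  if (!any(use) || stats::sd(v[use]) == 0) stopf("PC1 track is constant or empty")
  Q <- n_quantiles
  q <- rep(NA_integer_, nrow(bins))
  q[use] <- as.integer(cut(rank(v[use], ties.method = "first"), Q,
                           labels = FALSE))
  sad <- matrix(NA_real_, Q, Q)
  acc <- matrix(0, Q, Q); cnt <- matrix(0, Q, Q)
  for (cn in chrom_names(bins)) {
    rows <- chrom_rows(bins, cn)
    sub <- oe$mat[rows, rows, drop = FALSE]
    qq <- q[rows]
    off <- row(sub) != col(sub)
    ok <- is.finite(sub) & off & !is.na(qq[row(sub)]) & !is.na(qq[col(sub)])
    if (!any(ok)) next
    gi <- qq[row(sub)[ok]]; gj <- qq[col(sub)[ok]]
    vals <- sub[ok]
    s <- rowsum(vals, group = paste(gi, gj))
    k <- rowsum(rep(1, length(vals)), group = paste(gi, gj))
    ij <- do.call(rbind, lapply(strsplit(rownames(s), " "), as.integer))
    acc[ij] <- acc[ij] + s[, 1]
    cnt[ij] <- cnt[ij] + k[, 1]
  }
  sad[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  kc <- max(1L, round(Q * corner_frac))
  aa <- mean(sad[(Q - kc + 1):Q, (Q - kc + 1):Q], na.rm = TRUE)
  bb <- mean(sad[1:kc, 1:kc], na.rm = TRUE)
  ab <- mean(sad[1:kc, (Q - kc + 1):Q], na.rm = TRUE)
  ba <- mean(sad[(Q - kc + 1):Q, 1:kc], na.rm = TRUE)
  structure(list(saddle = sad, strength = (aa + bb) / (ab + ba)),
            class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("<saddle_result> %dx%d saddle, compartment strength = %.3f\n",
              nrow(x$saddle), ncol(x$saddle), x$strength))
  invisible(x)
}

#' A/B composition of a chromosome subset
#'
#' Percentages of unmasked bins labelled A and B over the subset, plus the
#' ratio of the number of contiguous A runs to contiguous B runs.
#'
#' @param profile A `compartment_profile`.
#' @param chrom_subset Chromosome names to include (default all).
#' @return Named list `percent_A`, `percent_B`, `count_ratio_AB` (`NA` when
#'   the subset has no B runs).
#' @export
ab_composition <- function(profile, chrom_subset = NULL) {
  bins <- profile$pc1
  sel <- if (is.null(chrom_subset)) rep(TRUE, nrow(bins))
         else bins$chrom %in% chrom_subset
  lab <- profile$labels[sel]
  ok <- !is.na(lab)
  if (!any(ok)) stopf("no unmasked bins in the subset")
  runs_a <- 0L; runs_b <- 0L
  for (cn in unique(bins$chrom[sel])) {
    l <- profile$labels[sel & bins$chrom == cn]
    r <- rle(l[!is.na(l)])
    runs_a <- runs_a + sum(r$values == "A")
    runs_b <- runs_b + sum(r$values == "B")
  }
  list(percent_A = 100 * sum(lab == "A", na.rm = TRUE) / sum(ok),
       percent_B = 100 * sum(lab == "B", na.rm = TRUE) / sum(ok),
       count_ratio_AB = if (runs_b == 0) NA_real_ else runs_a / runs_b)
}
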