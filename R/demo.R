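# helper: chromosome-local bin index (0-based) of planted TAD gap midpoints
planted_boundary_bins <- function(tads, chrom) {
  iv <- tads[tads$chrom == chrom, , drop = FALSE]
  iv <- iv[order(iv$start_bin), , drop = FALSE]
  if (nrow(iv) < 2) return(integer(0))
  round((iv$end_bin[-nrow(iv)] + iv$start_bin[-1] - 1) / 2)
}

# standard planted-structure layout used by the demo: TADs tiling each
# chromosome (20-bin domains, 2-bin gaps) and a sparse diagonal of loops
demo_tads <- function(bins, domain_bins = 20, gap_bins = 2) {
  out <- list()
  for (cn in chrom_names(bins)) {
    k <- length(chrom_rows(bins, cn))
    s <- 0
    while (s + domain_bins <= k) {
      out[[length(out) + 1L]] <- data.frame(chrom = cn, start_bin = s,
                                            end_bin = s + domain_bins,
                                            stringsAsFactors = FALSE)
      s <- s + domain_bins + gap_bins
    }
  }
  do.call(rbind, out)
}

demo_loops <- function(bins, sep = 12, every = 70, offset = 31) {
  out <- list()
  for (cn in chrom_names(bins)) {
    k <- length(chrom_rows(bins, cn))
    for (i in seq(offset, k - sep - 2, by = every))
      out[[length(out) + 1L]] <- data.frame(chrom = cn, bin_i = i,
                                            bin_j = i + sep,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' End-to-end synthetic demonstration run
#'
#' Simulates a two-chromosome genome with planted compartments, TADs, loops
#' and bin biases, runs the full analysis chain (ICE balancing, O/E, contact
#' decay, PC1 compartments, saddle strength, DI + HMM TADs, insulation,
#' loop calling, conserved regions), writes all standard-format outputs into
#' `out_dir`, and returns a machine-readable report comparing every call to
#' the planted truth. Fully deterministic given `seed`.
#'
#' @param seed Master seed for all randomness.
#' @param out_dir Output directory (created if needed).
#' @param compartment_contrast Planted checkerboard contrast `c`
#'   (`g = log(1 + c)`; default 1, i.e. g = ln 2). Set 0 for a null run.
#' @param tad_enrichment Planted TAD enrichment tau (values `<= 1` disable
#'   TADs).
#' @param loop_enrichment Planted loop enrichment lambda (values `<= 1`
#'   disable loops).
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_demo <- function(seed, out_dir, compartment_contrast = 1,
                     tad_enrichment = 3, loop_enrichment = 8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bs <- 4e4
  bins <- bin_table(c(chrA = 600 * bs, chrB = 400 * bs), bs)
  tads <- if (tad_enrichment > 1) demo_tads(bins) else NULL
  loops <- if (loop_enrichment > 1) demo_loops(bins) else NULL
  cfg <- sim_config(
    chrom_lengths = c(chrA = 600 * bs, chrB = 400 * bs), bin_size = bs,
    decay_exponent = 1, compartment_contrast = compartment_contrast,
    compartment_block_bins = 50,
    tads = tads, tad_enrichment = max(tad_enrichment, 1 + 1e-9),
    loops = loops, loop_enrichment = max(loop_enrichment, 1 + 1e-9),
    bias_log_sd = 0.3, trans_background = 1e-3,
    depth_scale = 1500 * bs, seed = seed)
  sim <- simulate_contact_map(cfg)
  write_matrix(sim$matrix, file.path(out_dir, "matrix.triplet.txt"))
  write_bins(bins, file.path(out_dir, "bins.bed"))

  bal <- ice_normalize(sim$matrix)
  u <- !bal$matrix$mask
  # note: on a structured map ICE absorbs genuine coverage structure (TADs,
  # ends) into its factors, so correlation with the planted biases is
  # deliberately reported alongside the balancing quality itself
  bias_r <- stats::cor(bal$biases[u], sim$truth$biases[u])
  rs <- rowSums(bal$matrix$mat[u, u], na.rm = TRUE)
  rowsum_cv <- stats::sd(rs) / mean(rs)
  oe <- observed_expected(bal$matrix)

  ps <- slope_curve(contact_probability(bal$matrix))
  mid <- ps$distance >= 10 * bs & ps$distance <= 100 * bs
  ps_slope <- stats::median(ps$slope[mid])

  orientation <- scalar_track(bins, ifelse(sim$truth$labels == "A", 1, -1))
  prof <- pc1_compartments(oe, orientation)
  acc <- label_accuracy(prof, sim$truth$labels)
  sad <- saddle_strength(oe, prof$pc1)
  write_bedgraph(prof$pc1, file.path(out_dir, "pc1.bedGraph"))

  di <- directionality_index(bal$matrix)
  tadset <- hmm_call_tads(di)
  write_bed(tadset$domains, file.path(out_dir, "tads.bed"))
  write_bedgraph(di, file.path(out_dir, "di.bedGraph"))
  is_track <- insulation_score(bal$matrix)
  minima <- insulation_minima(is_track)

  bf1 <- c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  ins_hit <- NA_real_
  if (!is.null(tads)) {
    per_chrom <- lapply(chrom_names(bins), function(cn) {
      truth_b <- planted_boundary_bins(tads, cn)
      rows <- chrom_rows(bins, cn)
      called <- tadset$boundaries[tadset$boundaries$chrom == cn, , drop = FALSE]
      called_b <- round(((called$start + called$end) / 2) / bs - 0.5)
      min_b <- minima$bin_id[minima$chrom == cn] - (rows[1] - 1L)
      list(truth = truth_b, called = called_b, minima = min_b)
    })
    # evaluate per chromosome to avoid cross-chromosome matches
    prec <- c(); rec <- c(); hits <- c()
    for (p in per_chrom) {
      f <- boundary_f1(p$called, p$truth, tol = 1)
      prec <- c(prec, f[["precision"]]); rec <- c(rec, f[["recall"]])
      hits <- c(hits, vapply(p$truth, function(t)
        any(abs(p$minima - t) <= 1), logical(1)))
    }
    pr <- mean(prec, na.rm = TRUE); rc <- mean(rec, na.rm = TRUE)
    bf1 <- c(precision = pr, recall = rc,
             f1 = if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0)
    ins_hit <- mean(hits)
  }

  calls <- call_loops(sim$matrix, bal$biases)
  write_bedpe(calls, file.path(out_dir, "loops.bedpe"))
  lrec <- if (!is.null(loops)) loop_recovery(calls, loops, tol = 1)
          else c(recall = NA_real_, false_calls = NA_real_,
                 n_calls = nrow(calls))

  cbins <- bin_table(c(chr1 = 1000 * 4e5), 4e5)
  blocks <- data.frame(chrom = "chr1",
                       start = c(40, 320, 640) * 4e5,
                       end = c(160, 440, 800) * 4e5)
  pair <- simulate_pc1_pair(cbins, blocks, r_in = 0.95, r_out = 0,
                            seed = seed)
  cons <- conserved_regions(pair$a, pair$b)
  write_bed(cbind(cons[c("chrom", "start", "end")],
                  data.frame(name = "conserved", score = cons$mean_r)),
            file.path(out_dir, "conserved.bed"))
  jac <- interval_jaccard(cons[c("chrom", "start", "end")], blocks)

  report <- list(
    seed = seed,
    n_bins = nrow(bins),
    ice = list(bias_correlation_planted = bias_r,
               rowsum_cv = rowsum_cv,
               converged = attr(bal$matrix, "converged")),
    decay = list(mid_range_slope = ps_slope),
    compartments = list(label_accuracy = acc,
                        saddle_strength = sad$strength),
    tads = list(n_domains = nrow(tadset$domains),
                boundary_precision = bf1[["precision"]],
                boundary_recall = bf1[["recall"]],
                boundary_f1 = bf1[["f1"]],
                insulation_minima_hit_rate = ins_hit),
    loops = list(n_calls = nrow(calls),
                 n_tested = attr(calls, "n_tested"),
                 recall = lrec[["recall"]],
                 false_calls = lrec[["false_calls"]]),
    conserved = list(n_regions = nrow(cons), jaccard = jac))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
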