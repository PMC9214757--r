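# Validation metrics comparing calls with a planted truth set.

#' Boundary-recovery precision/recall/F1 at a bin tolerance
#'
#' Positions are matched when within `tol` bins; recall is the fraction of
#' true positions with a matching call, precision the fraction of calls with
#' a matching true position.
#'
#' @param called,truth Integer vectors of boundary bin positions (any common
#'   coordinate; one chromosome at a time, or global bin ids).
#' @param tol Matching tolerance in bins.
#' @return Named numeric `precision`, `recall`, `f1`.
#' @export
boundary_f1 <- function(called, truth, tol = 1) {
  if (!length(truth)) return(c(precision = NA, recall = NA, f1 = NA))
  if (!length(called)) return(c(precision = NA, recall = 0, f1 = 0))
  rec <- mean(vapply(truth, function(t) any(abs(called - t) <= tol), logical(1)))
  prec <- mean(vapply(called, function(c) any(abs(truth - c) <= tol), logical(1)))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Base-pair Jaccard index between two disjoint region sets
#'
#' @param a,b Data frames `chrom`, `start`, `end`.
#' @return Jaccard index `shared / union` in bp.
#' @export
interval_jaccard <- function(a, b) {
  ov <- region_overlap(a, b)
  un <- sum(ov)
  if (un == 0) return(NA_real_)
  unname(ov[["shared_bp"]] / un)
}

#' Loop-call recovery against planted pixels
#'
#' A planted pixel is recovered when a call summit on the same chromosome
#' lies within `tol` bins in both coordinates; a call is false when no
#' planted pixel does.
#'
#' @param calls A [call_loops()] result.
#' @param truth Data frame `chrom`, `bin_i`, `bin_j` (chromosome-local,
#'   0-based).
#' @param tol Matching tolerance in bins.
#' @return Named numeric `recall`, `false_calls`, `n_calls`.
#' @export
loop_recovery <- function(calls, truth, tol = 1) {
  hit_truth <- vapply(seq_len(NROW(truth)), function(r) {
    s <- calls[calls$chrom == truth$chrom[r], , drop = FALSE]
    any(abs(s$bin_i - truth$bin_i[r]) <= tol &
          abs(s$bin_j - truth$bin_j[r]) <= tol)
  }, logical(1))
  false_call <- vapply(seq_len(NROW(calls)), function(r) {
    t <- truth[truth$chrom == calls$chrom[r], , drop = FALSE]
    !any(abs(t$bin_i - calls$bin_i[r]) <= tol &
           abs(t$bin_j - calls$bin_j[r]) <= tol)
  }, logical(1))
  c(recall = if (NROW(truth)) mean(hit_truth) else NA_real_,
    false_calls = sum(false_call), n_calls = NROW(calls))
}

#' Compartment-label accuracy against planted labels
#'
#' @param profile A `compartment_profile`.
#' @param truth_labels Character vector of planted `"A"`/`"B"` labels.
#' @return Fraction of co-defined bins with matching labels.
#' @export
label_accuracy <- function(profile, truth_labels) {
  ok <- !is.na(profile$labels) & !is.na(truth_labels)
  if (!any(ok)) return(NA_real_)
  mean(profile$labels[ok] == truth_labels[ok])
}
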