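#' Construct a genome bin table
#'
#' Partitions each chromosome into consecutive fixed-width bins (0-based,
#' half-open BED coordinates). The last bin of a chromosome may be shorter.
#' Bin ids are dense 0-based indices in table order.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @return A `data.frame` of class `bin_table` with columns `chrom`, `start`,
#'   `end`, `bin_id` and a `bin_size` attribute.
#' @examples
#' bin_table(c(chr1 = 1e6, chr2 = 6e5), 2e5)
#' @export
bin_table <- function(chrom_lengths, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stopf("bin_size must be a single positive number")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stopf("chrom_lengths must be a named vector")
  if (any(chrom_lengths < 2 * bin_size))
    stopf("every chromosome must span at least two bins")
  pieces <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin_id <- seq_len(nrow(out)) - 1L
  attr(out, "bin_size") <- bin_size
  class(out) <- c("bin_table", "data.frame")
  out
}

bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- stats::median(bins$end - bins$start)
  bs
}

n_bins <- function(bins) nrow(bins)

chrom_names <- function(bins) unique(bins$chrom)

# 1-based row indices of a chromosome's bins
chrom_rows <- function(bins, chrom) which(bins$chrom == chrom)

same_bins <- function(a, b) {
  isTRUE(all.equal(a$chrom, b$chrom)) &&
    isTRUE(all.equal(a$start, b$start)) &&
    isTRUE(all.equal(a$end, b$end))
}

#' Read a bin table from a BED4 file
#'
#' Expects columns chrom, start, end, bin_id with dense 0-based bin ids in
#' file order.
#'
#' @param path Path to the BED4 file.
#' @return A `bin_table`.
#' @export
read_bins <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "start", "end", "bin_id"),
                          colClasses = c("character", "numeric", "numeric", "integer"))
  if (!identical(df$bin_id, seq_len(nrow(df)) - 1L))
    stopf("bin ids in %s are not dense 0..N-1 in table order", path)
  attr(df, "bin_size") <- stats::median(df$end - df$start)
  class(df) <- c("bin_table", "data.frame")
  df
}

#' Write a bin table as BED4
#'
#' @param bins A `bin_table`.
#' @param path Output path.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(
    data.frame(bins$chrom, format(bins$start, scientific = FALSE, trim = TRUE),
               format(bins$end, scientific = FALSE, trim = TRUE), bins$bin_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-bin scalar track aligned to a bin table
#'
#' @param bins A `bin_table`.
#' @param value Numeric vector, one value per bin (`NA` = undefined/masked).
#' @return A `data.frame` of class `scalar_track`.
#' @export
scalar_track <- function(bins, value) {
  if (length(value) != nrow(bins))
    stopf("track length (%d) does not match bin table (%d bins)",
          length(value), nrow(bins))
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    bin_id = bins$bin_id, value = as.numeric(value),
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bin_size_of(bins)
  class(out) <- c("scalar_track", "data.frame")
  out
}

#' Write a scalar track as bedGraph
#'
#' @param track A `scalar_track`.
#' @param path Output path.
#' @param na How undefined values are rendered (default drops those lines).
#' @export
write_bedgraph <- function(track, path, na = c("drop", "zero")) {
  na <- match.arg(na)
  v <- track$value
  keep <- if (na == "drop") !is.na(v) else rep(TRUE, length(v))
  if (na == "zero") v[is.na(v)] <- 0
  utils::write.table(
    data.frame(track$chrom[keep],
               format(track$start[keep], scientific = FALSE, trim = TRUE),
               format(track$end[keep], scientific = FALSE, trim = TRUE),
               sprintf("%.8g", v[keep])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally a
#'   `name` and `score` column.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- data.frame(intervals$chrom,
                     format(intervals$start, scientific = FALSE, trim = TRUE),
                     format(intervals$end, scientific = FALSE, trim = TRUE))
  if (!is.null(intervals$name)) cols <- cbind(cols, intervals$name)
  if (!is.null(intervals$score))
    cols <- cbind(cols, sprintf("%.6g", intervals$score))
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
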