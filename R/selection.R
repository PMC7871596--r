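## Extreme-window selection.
##
## Per chromosome and focal group, the top-0.1% retention-count threshold is
## the nearest-rank 99.9th percentile of the window counts (the smallest
## order statistic whose cumulative rank reaches the quantile); windows with
## count >= threshold are "high", ties included. Zero-count windows are
## "null" and are classified by cause: no ancestral allele was definable in
## the window (null_no_aa), or AA sites exist but the derived allele has
## taken over at every one of them (null_derived). mean + 3 sd is reported
## as a diagnostic only -- on heavy-tailed count distributions the selected
## thresholds exceed it, but it plays no part in selection.

#' Nearest-rank percentile
#'
#' The smallest order statistic with cumulative rank >= `q`:
#' `sort(x)[ceiling(q * n)]`.
#'
#' @param x numeric vector (non-empty).
#' @param q quantile in (0, 1].
#' @return the percentile value.
#' @export
nearest_rank_quantile <- function(x, q) {
  if (length(x) == 0L) stop("empty vector")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  ## the small slack keeps ceiling() from jumping a rank when q * n lands
  ## a floating-point ulp above an integer
  sort(x)[max(1L, as.integer(ceiling(q * length(x) - 1e-9)))]
}

#' Chromosome-wise top-fraction thresholds
#'
#' @param windows an `aa_windows` table (all windows enumerated).
#' @param top_fraction selected upper tail (default 0.001, i.e. top 0.1%).
#' @return data.table of class `aa_thresholds`: chrom, group, threshold
#'   (nearest-rank `1 - top_fraction` percentile of the window counts),
#'   mean_count, sd_count, mean_plus_3sd, and `exceeds_mean_3sd` -- a QC
#'   flag for whether the threshold lies beyond mean + 3 sd.
#' @export
chromosome_thresholds <- function(windows, top_fraction = 0.001) {
  windows <- as.data.table(windows)
  if (nrow(windows) == 0L) stop("no windows: empty chromosome set")
  th <- windows[, .(
    threshold = nearest_rank_quantile(count, 1 - top_fraction),
    mean_count = mean(count),
    sd_count = sd(count)
  ), by = .(chrom, group)]
  th[is.na(sd_count), sd_count := 0]
  th[, mean_plus_3sd := mean_count + 3 * sd_count]
  th[, exceeds_mean_3sd := threshold > mean_plus_3sd]
  setattr(th, "class", c("aa_thresholds", "data.table", "data.frame"))
  th[]
}

#' Select high-count windows
#'
#' Windows whose retention count reaches their chromosome's threshold
#' (`count >= threshold`, ties included). Zero-count windows are never
#' selected: on a degenerate all-zero chromosome the nearest-rank threshold
#' is 0, and a window with no retained ancestral allele is not evidence of
#' conservation.
#'
#' @param windows an `aa_windows` table.
#' @param thresholds an `aa_thresholds` table.
#' @return the selected subset of `windows`.
#' @export
select_high <- function(windows, thresholds) {
  windows <- as.data.table(windows)
  j <- as.data.table(thresholds)[, .(chrom, group, threshold)][
    windows, on = .(chrom, group)]
  windows[j$count >= j$threshold & j$count > 0L]
}

#' Select null (zero-count) windows
#'
#' @param windows an `aa_windows` table with every window enumerated,
#'   including those containing no sites.
#' @return the subset with count = 0.
#' @export
select_null <- function(windows) {
  as.data.table(windows)[count == 0L]
}

#' Classify a null window by cause
#'
#' @param windows zero-count windows (rows of an `aa_windows` table).
#' @return character vector: `"null_no_aa"` where no ancestral allele was
#'   definable in the window (`n_aa_sites` = 0), `"null_derived"` where AA
#'   sites exist but none is retained. Calling this on a window with
#'   count > 0 is an error.
#' @export
classify_null <- function(windows) {
  windows <- as.data.table(windows)
  if (any(windows$count > 0L))
    stop("classify_null called on a window with count > 0")
  ifelse(windows$n_aa_sites == 0L, "null_no_aa", "null_derived")
}

#' Label every window
#'
#' Partitions the windows of each chromosome and group into exactly one of
#' `high`, `null_no_aa`, `null_derived`, `background`.
#'
#' @param windows an `aa_windows` table.
#' @param thresholds an `aa_thresholds` table from
#'   [chromosome_thresholds()]; computed from `windows` when `NULL`.
#' @param top_fraction passed to [chromosome_thresholds()] when computing.
#' @return `windows` with columns `threshold` and `label` added (class
#'   `aa_classified`).
#' @export
classify_windows <- function(windows, thresholds = NULL, top_fraction = 0.001) {
  windows <- copy(as.data.table(windows))
  if (is.null(thresholds))
    thresholds <- chromosome_thresholds(windows, top_fraction)
  windows <- as.data.table(thresholds)[, .(chrom, group, threshold)][
    windows, on = .(chrom, group)]
  windows[, label := "background"]
  windows[count >= threshold & count > 0L, label := "high"]
  windows[count == 0L, label := ifelse(n_aa_sites == 0L,
                                       "null_no_aa", "null_derived")]
  setattr(windows, "class", c("aa_classified", "data.table", "data.frame"))
  windows[]
}

#' Ratio of null windows to total windows
#'
#' @param windows an `aa_windows` table with all windows enumerated.
#' @return data.table: chrom, group, n_null, n_total, null_ratio in [0, 1].
#' @export
null_ratio <- function(windows) {
  as.data.table(windows)[, .(
    n_null = sum(count == 0L),
    n_total = .N,
    null_ratio = sum(count == 0L) / .N
  ), by = .(chrom, group)]
}

#' Write classified windows as BED
#'
#' 0-based half-open window spans with the label in the name column, for
#' use with genome-arithmetic tools.
#'
#' @param classified an `aa_classified` table.
#' @param path output BED path.
#' @param labels which labels to emit (default all).
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(classified, path,
                              labels = c("high", "null_no_aa",
                                         "null_derived", "background")) {
  cw <- as.data.table(classified)[label %in% labels]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", cw$chrom, cw$start - 1L,
                     cw$end, paste0(cw$group, ":", cw$label), cw$count),
             path, useBytes = TRUE)
  invisible(path)
}
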