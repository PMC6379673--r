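#' Segment a genome into constant-size windows
#'
#' Non-overlapping windows tiled from position 0 of each chromosome;
#' a trailing partial window is dropped.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window window size in bp (the analyses use 250 bp up to 1 Mb).
#' @return `data.table` with chrom, start, end (0-based half-open).
#' @export
segment_genome <- function(chrom_sizes, window) {
  stopifnot(window >= 1)
  window <- as.integer(window)
  out <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]] %/% window
    if (n == 0L) return(NULL)
    s <- (seq_len(n) - 1L) * window
    data.table(chrom = ch, start = s, end = s + window)
  })
  wt <- rbindlist(out)
  attr(wt, "window") <- window
  wt
}

# mean of a per-base signal over 0-based half-open windows, via cumsum
window_means <- function(signal_list, windows) {
  cs <- lapply(signal_list, function(v) c(0, cumsum(v)))
  vapply(seq_len(nrow(windows)), function(i) {
    v <- cs[[windows$chrom[i]]]
    (v[windows$end[i] + 1L] - v[windows$start[i] + 1L]) /
      (windows$end[i] - windows$start[i])
  }, numeric(1))
}

# GC fraction per window over non-N bases; NA for all-N windows
window_gc <- function(genome, windows) {
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    v <- Views(genome[[ch]], start = windows$start[idx] + 1L,
               end = windows$end[idx])
    freq <- letterFrequency(v, c("G", "C", "A", "T"))
    acgt <- rowSums(freq)
    out[idx] <- ifelse(acgt == 0, NA_real_,
                       (freq[, "G"] + freq[, "C"]) / acgt)
  }
  out
}

#' Per-window occupancy, GC and mappability statistics
#'
#' Computes, for each window, the mean low/high occupancy, the GC fraction
#' of the underlying sequence (non-N bases) and the mean mappability, then
#' applies the window filters: windows lacking signal in either condition,
#' with mean mappability below 0.9, or fully N are excluded.
#'
#' @param windows a [segment_genome()] table.
#' @param low_track,high_track `OccupancyTrack`s of the two conditions.
#' @param genome a `DNAStringSet` (names matching chromosome names).
#' @param mappability optional `OccupancyTrack` with per-base mappability in
#'   `[0, 1]`; omitted = fully mappable.
#' @param min_mappability retention threshold (windows >= threshold kept).
#' @return a `WindowTable`: `data.table` with chrom, start, end, mean_low,
#'   mean_high, gc, mappability. Attributes `window`, `n_dropped_signal`,
#'   `n_dropped_mappability`, `n_dropped_N` record the filtering.
#' @export
window_stats <- function(windows, low_track, high_track, genome,
                         mappability = NULL, min_mappability = 0.9) {
  stopifnot(inherits(low_track, "OccupancyTrack"),
            inherits(high_track, "OccupancyTrack"))
  wt <- copy(windows)
  wt[, mean_low := window_means(low_track$signal, wt)]
  wt[, mean_high := window_means(high_track$signal, wt)]
  wt[, gc := window_gc(genome, wt)]
  wt[, mappability := if (is.null(mappability)) 1
     else window_means(mappability$signal, wt)]
  drop_sig <- wt$mean_low == 0 | wt$mean_high == 0
  drop_map <- !drop_sig & wt$mappability < min_mappability
  drop_n <- !drop_sig & !drop_map & is.na(wt$gc)
  out <- wt[!(drop_sig | drop_map | drop_n)]
  attr(out, "window") <- attr(windows, "window")
  attr(out, "n_dropped_signal") <- sum(drop_sig)
  attr(out, "n_dropped_mappability") <- sum(drop_map)
  attr(out, "n_dropped_N") <- sum(drop_n)
  out
}

#' Add log2 fold change (high over low) to a window table
#'
#' @param table a [window_stats()] table (zero-mean rows already excluded).
#' @return the table with a `logfc = log2(mean_high / mean_low)` column.
#' @export
compute_logfc <- function(table) {
  out <- copy(table)
  out[, logfc := log2(mean_high / mean_low)]
  for (a in c("window", "n_dropped_signal", "n_dropped_mappability",
              "n_dropped_N")) {
    attr(out, a) <- attr(table, a)
  }
  out
}

#' Linear regression of window signal on GC with influence filtering
#'
#' Ordinary least squares of the chosen response on the window GC fraction.
#' Observations with Cook's distance above `cooks_threshold` in the initial
#' fit are dropped and the model is refitted once; the adjusted R-squared of
#' the refit is reported. If the influence filter would leave fewer than 3
#' observations it is skipped and the initial fit is reported.
#'
#' @param table a window table with a `gc` column and the response.
#' @param response "logfc", "mean_high" or "mean_low".
#' @param cooks_threshold Cook's distance cutoff (default 0.001).
#' @return a `RegressionResult`: list with slope, intercept, adj_r2
#'   (clamped at 0), r2, n_used, n_dropped_influence, cooks_threshold,
#'   response and the refit `lm` object in `fit`.
#' @export
gc_regression <- function(table, response = c("logfc", "mean_high",
                                              "mean_low"),
                          cooks_threshold = 0.001) {
  response <- match.arg(response)
  if (response == "logfc" && !"logfc" %in% names(table)) {
    table <- compute_logfc(table)
  }
  dat <- data.frame(y = table[[response]], gc = table$gc)
  dat <- dat[complete.cases(dat) & is.finite(dat$y), , drop = FALSE]
  if (nrow(dat) < 3L) stop("fewer than 3 windows available for regression")
  fit1 <- lm(y ~ gc, data = dat)
  cd <- cooks.distance(fit1)
  keep <- cd <= cooks_threshold
  n_dropped <- sum(!keep)
  if (sum(keep) >= 3L) {
    fit <- lm(y ~ gc, data = dat[keep, , drop = FALSE])
    n_used <- sum(keep)
  } else {
    fit <- fit1
    n_used <- nrow(dat)
    n_dropped <- 0L
  }
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 adj_r2 = max(0, sm$adj.r.squared),
                 r2 = sm$r.squared,
                 n_used = n_used,
                 n_dropped_influence = n_dropped,
                 cooks_threshold = cooks_threshold,
                 response = response,
                 fit = fit),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf(
    "gc regression (%s): slope %.4g, intercept %.4g, adj R2 %.4f (n=%d, %d influential dropped)\n",
    x$response, x$slope, x$intercept, x$adj_r2, x$n_used,
    x$n_dropped_influence))
  invisible(x)
}

#' Pearson correlation of log fold change with GC deviation
#'
#' Correlates the per-window log2(high/low) with the deviation of window GC
#' from the genome-wide mean GC, as displayed on domain-scale browser
#' tracks.
#'
#' @param table a window table with logfc (computed if absent).
#' @return list with `r` (Pearson) and `genome_gc` (mean GC used).
#' @export
logfc_gc_correlation <- function(table) {
  if (!"logfc" %in% names(table)) table <- compute_logfc(table)
  ok <- is.finite(table$logfc) & !is.na(table$gc)
  gmean <- mean(table$gc[ok])
  list(r = cor(table$logfc[ok], table$gc[ok] - gmean), genome_gc = gmean)
}

#' Write a window table as TSV (and optionally its logfc as bedGraph)
#'
#' @param table window table.
#' @param path output TSV path.
#' @param bedgraph optional path for a logfc bedGraph.
#' @export
write_window_table <- function(table, path, bedgraph = NULL) {
  fwrite(table, path, sep = "\t")
  if (!is.null(bedgraph) && "logfc" %in% names(table)) {
    dt <- data.table(chrom = table$chrom, start = table$start,
                     end = table$end, value = signif(table$logfc, 6))
    fwrite(dt, bedgraph, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}
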