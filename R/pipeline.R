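#' Default analysis configuration
#'
#' All reference defaults in one place: 20/70 cutting events, 180 bp kept /
#' 30 bp trimmed array fragments, 140-200 bp mono and 250-500 bp di size
#' gates, 70/150 bp midpoint extension, 2e8 depth target, clonal filter
#' p 1e-2, mappability >= 0.9, Cook's distance 0.001, GC gate 30-70%,
#' site width 70 bp, per-base p 1e-2, FDR 0.05.
#'
#' @param ... overrides (name = value).
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_cuts_low = 20L, n_cuts_high = 70L,
    keep_len = 180L, trim = 30L,
    mono_range = c(140L, 200L), di_range = c(250L, 500L),
    extend_mono = 70L, extend_di = 150L,
    depth_target = 2e8,
    clonal_p = 1e-2,
    min_mappability = 0.9,
    cooks_threshold = 0.001,
    gc_bounds = c(0.30, 0.70),
    loess_span = 0.75, loess_degree = 2L,
    loess_window = 250L,
    min_width = 70L, base_p = 1e-2, fdr = 0.05,
    ploidy = 3,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, over)
}

validate_config <- function(cfg) {
  stopifnot(cfg$base_p > 0, cfg$base_p < 1, cfg$fdr > 0, cfg$fdr < 1,
            cfg$min_mappability >= 0, cfg$min_mappability <= 1,
            cfg$gc_bounds[1] < cfg$gc_bounds[2],
            cfg$min_width >= 1, cfg$depth_target > 0,
            cfg$cooks_threshold > 0)
  invisible(cfg)
}

#' Run the differential MNase analysis pipeline
#'
#' Chains the analysis stages on fragment intervals from two digestion
#' conditions: mono-nucleosomal size selection, clonal filtering,
#' midpoint-extended occupancy tracks, depth normalization to a common
#' target, optional CNV correction, 250-bp window statistics, per-condition
#' LOESS GC correction, and differential site calling.
#'
#' @param fragments `data.table` with chrom, start, end, condition
#'   ("low"/"high").
#' @param genome `DNAStringSet`.
#' @param chrom_sizes named chromosome lengths (defaults to the genome's).
#' @param mappability optional mappability `OccupancyTrack`.
#' @param cnv_segments optional CNV `data.table` (chrom, start, end,
#'   copy_number).
#' @param config a [default_config()] list.
#' @param depth_target depth target; `NULL` (default) uses the mean of the
#'   two post-filter fragment totals so normalized values stay on the
#'   count scale of the data (set `config$depth_target`, e.g. 2e8, for
#'   genome-scale cross-sample work).
#' @param window_sizes window sizes (bp) for the GC regression sweep.
#' @return list with tracks (raw), tracks_corrected, window_table_250,
#'   regressions (per window size: low/high/logfc `RegressionResult`s),
#'   loess fits, sites, post_correction_r and config.
#' @export
run_differential_pipeline <- function(fragments, genome,
                                      chrom_sizes = NULL,
                                      mappability = NULL,
                                      cnv_segments = NULL,
                                      config = default_config(),
                                      depth_target = NULL,
                                      window_sizes = c(5e3, 5e4, 5e5)) {
  validate_config(config)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- setNames(
      vapply(seq_along(genome), function(i) length(genome[[i]]),
             integer(1)),
      names(genome))
  }
  prep <- function(cond) {
    fr <- fragments[condition == cond]
    if (nrow(fr) == 0L) stop("no fragments for condition ", cond)
    fr <- size_select(fr, "mono", mono_range = config$mono_range)
    fr <- dedup_clonal(fr, config$clonal_p)
    build_occupancy(fr, chrom_sizes, extend_to = config$extend_mono)
  }
  tr_low <- prep("low")
  tr_high <- prep("high")
  if (is.null(depth_target)) {
    depth_target <- mean(c(tr_low$n_fragments_used,
                           tr_high$n_fragments_used))
  }
  tr_low <- depth_normalize(tr_low, depth_target)
  tr_high <- depth_normalize(tr_high, depth_target)
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    tr_low <- cnv_correct(tr_low, cnv_segments, config$ploidy)
    tr_high <- cnv_correct(tr_high, cnv_segments, config$ploidy)
  }

  # GC regression sweep on the uncorrected tracks; sizes leaving fewer
  # than 3 full windows on this genome are skipped
  n_win <- vapply(window_sizes, function(w) {
    sum(chrom_sizes %/% w)
  }, numeric(1))
  window_sizes <- window_sizes[n_win >= 3]
  if (!length(window_sizes)) stop("no window size fits the genome")
  regressions <- lapply(window_sizes, function(w) {
    wt <- window_stats(segment_genome(chrom_sizes, w), tr_low, tr_high,
                       genome, mappability, config$min_mappability)
    wt <- compute_logfc(wt)
    list(window = w,
         low = gc_regression(wt, "mean_low", config$cooks_threshold),
         high = gc_regression(wt, "mean_high", config$cooks_threshold),
         logfc = gc_regression(wt, "logfc", config$cooks_threshold),
         pearson_logfc_gc = logfc_gc_correlation(wt)$r)
  })
  names(regressions) <- paste0("w", window_sizes)

  # LOESS GC correction at 250-bp windows
  w250 <- segment_genome(chrom_sizes, config$loess_window)
  wt250 <- window_stats(w250, tr_low, tr_high, genome, mappability,
                        config$min_mappability)
  fit_low <- fit_gc_loess(wt250, "low", config$loess_span,
                          config$loess_degree, config$gc_bounds)
  fit_high <- fit_gc_loess(wt250, "high", config$loess_span,
                           config$loess_degree, config$gc_bounds)
  w250all <- copy(w250)
  w250all[, gc := window_gc(genome, w250all)]
  trc_low <- apply_gc_correction(tr_low, fit_low, w250all)
  trc_high <- apply_gc_correction(tr_high, fit_high, w250all)

  # residual GC dependence of the corrected log ratio, 250-bp windows
  post <- copy(w250all)
  post[, mean_low := window_means(trc_low$signal, post)]
  post[, mean_high := window_means(trc_high$signal, post)]
  okp <- post$mean_low > 0 & post$mean_high > 0 & !is.na(post$gc)
  post_r <- cor(log2(post$mean_high[okp] / post$mean_low[okp]),
                post$gc[okp])

  sites <- call_differential_sites(trc_low, trc_high, config$min_width,
                                   config$base_p, config$fdr,
                                   extend_to = config$extend_mono)
  list(tracks = list(low = tr_low, high = tr_high),
       tracks_corrected = list(low = trc_low, high = trc_high),
       window_table_250 = wt250,
       regressions = regressions,
       loess = list(low = fit_low, high = fit_high),
       post_correction_r = post_r,
       sites = sites,
       depth_target = depth_target,
       config = config)
}

#' Compare called differential sites with a planted truth set
#'
#' @param sites [call_differential_sites()] output.
#' @param truth planted intervals (chrom, start, end).
#' @param slack bp added to each truth interval when matching.
#' @param direction site direction counted as a recovery.
#' @return list with n_truth, n_called, n_recovered, recovery,
#'   n_false, empirical_fdr.
#' @export
recovery_report <- function(sites, truth, slack = 200L,
                            direction = "hyper_accessible") {
  called <- sites[sites$direction == direction]
  hit <- logical(nrow(truth))
  false_call <- logical(nrow(called))
  for (ch in unique(truth$chrom)) {
    ti <- which(truth$chrom == ch)
    ci <- which(called$chrom == ch)
    tr <- IRanges(truth$start[ti] + 1L - slack, truth$end[ti] + slack)
    if (length(ci)) {
      cr <- IRanges(called$start[ci] + 1L, called$end[ci])
      hit[ti] <- overlapsAny(tr, cr)
      false_call[ci] <- !overlapsAny(cr, tr)
    }
  }
  for (ch in setdiff(unique(called$chrom), unique(truth$chrom))) {
    false_call[called$chrom == ch] <- TRUE
  }
  list(n_truth = nrow(truth), n_called = nrow(called),
       n_recovered = sum(hit),
       recovery = if (nrow(truth)) sum(hit) / nrow(truth) else NA_real_,
       n_false = sum(false_call),
       empirical_fdr = if (nrow(called)) sum(false_call) / nrow(called)
                       else 0)
}
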