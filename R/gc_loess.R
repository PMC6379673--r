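#' Fit the LOESS model of occupancy on GC content
#'
#' Locally weighted regression of the mean window occupancy (250-bp
#' windows) on the window GC fraction, used to estimate the GC bias of a
#' digestion condition. Windows with extreme GC content (< 30% or > 70%)
#' are removed before fitting, on top of the read/mappability filters
#' already applied by [window_stats()].
#'
#' @param window_table a [window_stats()] table at 250-bp windows.
#' @param condition which condition's means to model ("low"/"high").
#' @param span,degree smoother settings (conventional defaults 0.75 / 2).
#' @param gc_bounds retained GC range (default c(0.30, 0.70)).
#' @param grid_step spacing of the prediction grid on the GC axis.
#' @return a `LoessFit`: list with condition, gc_grid, fitted,
#'   global_mean, span, degree, gc_bounds, n_windows.
#' @export
fit_gc_loess <- function(window_table, condition = c("low", "high"),
                         span = 0.75, degree = 2,
                         gc_bounds = c(0.30, 0.70), grid_step = 0.005) {
  condition <- match.arg(condition)
  ycol <- if (condition == "low") "mean_low" else "mean_high"
  dat <- data.frame(y = window_table[[ycol]], gc = window_table$gc)
  dat <- dat[!is.na(dat$gc) & dat$gc >= gc_bounds[1] &
               dat$gc <= gc_bounds[2], , drop = FALSE]
  if (nrow(dat) < 50L) {
    stop("fewer than 50 windows after GC filtering; LOESS fit unstable")
  }
  fit <- loess(y ~ gc, data = dat, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  gc_grid <- seq(gc_bounds[1], gc_bounds[2], by = grid_step)
  fitted <- as.numeric(predict(fit, newdata = data.frame(gc = gc_grid)))
  if (any(!is.finite(fitted)) || any(fitted <= 0)) {
    stop("LOESS fit produced non-positive expected occupancy")
  }
  structure(list(condition = condition, gc_grid = gc_grid, fitted = fitted,
                 global_mean = mean(dat$y), span = span, degree = degree,
                 gc_bounds = gc_bounds, n_windows = nrow(dat)),
            class = "LoessFit")
}

#' @export
print.LoessFit <- function(x, ...) {
  cat(sprintf(
    "LoessFit (%s): %d windows, GC %.2f-%.2f, span %.2f deg %d, mean %.4g\n",
    x$condition, x$n_windows, x$gc_bounds[1], x$gc_bounds[2], x$span,
    x$degree, x$global_mean))
  invisible(x)
}

#' Predict the GC correction factor from a LOESS fit
#'
#' `global_mean / fitted(gc)`, with gc clamped to the fitted range.
#'
#' @param fit a `LoessFit`.
#' @param gc GC fractions.
#' @return multiplicative correction factors.
#' @export
gc_correction_factor <- function(fit, gc) {
  gcc <- pmin(pmax(gc, fit$gc_bounds[1]), fit$gc_bounds[2])
  f <- stats::approx(fit$gc_grid, fit$fitted, xout = gcc, rule = 2)$y
  if (any(f <= 0, na.rm = TRUE)) stop("fitted occupancy <= 0")
  fit$global_mean / f
}

#' Apply the LOESS GC correction to an occupancy track
#'
#' Multiplies the signal in each 250-bp window by the correction factor
#' `global_mean / fitted(gc)` of that window's GC content. Windows with GC
#' outside the fitted range use the fitted value at the nearest bound
#' (clamped prediction) so the corrected track stays genome-wide; windows
#' with undefined GC (all N) and trailing partial windows are left
#' unchanged.
#'
#' @param track the condition's `OccupancyTrack`.
#' @param fit the condition's `LoessFit`.
#' @param window_table a window table carrying `gc` for every window to be
#'   corrected (unfiltered tiling from [segment_genome()] + gc is fine; a
#'   filtered [window_stats()] table corrects the retained windows only).
#' @return the corrected track (normalization step "gc_loess" recorded).
#' @export
apply_gc_correction <- function(track, fit, window_table) {
  stopifnot(inherits(track, "OccupancyTrack"), inherits(fit, "LoessFit"))
  if ("gc_loess" %in% track$normalization) {
    stop("GC correction already applied to this track")
  }
  wt <- window_table
  ok <- !is.na(wt$gc)
  fac <- rep(NA_real_, nrow(wt))
  fac[ok] <- gc_correction_factor(fit, wt$gc[ok])
  for (ch in unique(wt$chrom)) {
    idx <- which(wt$chrom == ch & ok)
    if (!length(idx)) next
    v <- track$signal[[ch]]
    for (i in idx) {
      v[(wt$start[i] + 1L):wt$end[i]] <-
        v[(wt$start[i] + 1L):wt$end[i]] * fac[i]
    }
    track$signal[[ch]] <- v
  }
  track$normalization <- c(track$normalization, "gc_loess")
  track
}

#' Serialize a LOESS fit to JSON
#'
#' @param fit a `LoessFit`.
#' @param path output path.
#' @export
write_loess_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit)[c("condition", "gc_grid", "fitted",
                                      "global_mean", "span", "degree",
                                      "gc_bounds", "n_windows")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
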