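#' Read aligned fragment intervals
#'
#' Reads sequenced fragments as genomic intervals, one record per fragment.
#' BED input uses columns chrom/start/end (a 4th column, when present, is
#' taken as the condition label). BEDPE input uses the two outermost mate
#' coordinates (columns 1,2,6) to form the fragment.
#'
#' @param path input file.
#' @param format "BED" or "BEDPE".
#' @param condition condition label assigned when the file carries none.
#' @return `data.table` with columns chrom, start, end, condition.
#' @export
read_fragments <- function(path, format = c("BED", "BEDPE"),
                           condition = NA_character_) {
  format <- match.arg(format)
  dt <- tryCatch(fread(path, header = FALSE),
                 error = function(e) data.table())
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), condition = character()))
  }
  if (format == "BED") {
    out <- data.table(chrom = as.character(dt[[1]]),
                      start = suppressWarnings(as.integer(dt[[2]])),
                      end = suppressWarnings(as.integer(dt[[3]])),
                      condition = if (ncol(dt) >= 4L) as.character(dt[[4]])
                                  else condition)
  } else {
    if (ncol(dt) < 6L) stop("BEDPE input needs at least 6 columns")
    if (!all(dt[[1]] == dt[[4]])) {
      stop("BEDPE mates on different chromosomes at line ",
           which(dt[[1]] != dt[[4]])[1])
    }
    out <- data.table(chrom = as.character(dt[[1]]),
                      start = suppressWarnings(
                        as.integer(pmin(dt[[2]], dt[[5]]))),
                      end = suppressWarnings(
                        as.integer(pmax(dt[[3]], dt[[6]]))),
                      condition = if (ncol(dt) >= 7L) as.character(dt[[7]])
                                  else condition)
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$end <= out$start)
  if (length(bad)) {
    stop("malformed fragment record at line ", bad[1],
         " (need 0 <= start < end)")
  }
  out
}

#' Size-select mono- or di-nucleosomal fragments
#'
#' Fragments of 140-200 bp are considered mono-nucleosomal and fragments of
#' 250-500 bp di-nucleosomal; both bounds are inclusive.
#'
#' @param fragments fragment `data.table` (chrom/start/end...).
#' @param cls "mono" or "di".
#' @param mono_range,di_range inclusive length gates in bp.
#' @return the selected fragments.
#' @export
size_select <- function(fragments, cls = c("mono", "di"),
                        mono_range = c(140L, 200L),
                        di_range = c(250L, 500L)) {
  cls <- match.arg(cls)
  rng <- if (cls == "mono") mono_range else di_range
  len <- fragments$end - fragments$start
  fragments[len >= rng[1] & len <= rng[2]]
}

#' Cap clonal (identical-coordinate) fragments
#'
#' Fragments sharing identical (chrom, start, end) coordinates beyond what
#' random sampling explains are treated as clonal amplification artefacts.
#' The multiplicity of each coordinate is capped at the smallest k for which
#' the upper-tail probability P(X >= k) of a Poisson with rate lambda (the
#' genome-wide mean multiplicity per distinct coordinate) falls below
#' `p_threshold`; the cap never goes below 1 copy.
#'
#' @param fragments fragment `data.table`.
#' @param p_threshold tail probability threshold (default 1e-2).
#' @return fragments with per-coordinate multiplicity capped.
#' @export
dedup_clonal <- function(fragments, p_threshold = 1e-2) {
  if (nrow(fragments) == 0L) return(fragments)
  stopifnot(p_threshold > 0)
  counts <- fragments[, .(n_dup = .N), by = .(chrom, start, end)]
  lambda <- nrow(fragments) / nrow(counts)
  cap <- 1L
  while (ppois(cap - 1L, lambda, lower.tail = FALSE) >= p_threshold) {
    cap <- cap + 1L
    if (cap > 1e6L) break
  }
  cap <- max(cap, 1L)
  idx <- fragments[, .I[seq_len(min(.N, cap))], by = .(chrom, start, end)]$V1
  fragments[sort(idx)]
}

#' Build a midpoint-extended nucleosome occupancy track
#'
#' Each fragment is centred on its midpoint `floor((start + end) / 2)` and
#' extended to `extend_to` bp (70 bp for mono-nucleosomes, 150 bp for
#' di-nucleosomes); each extended interval contributes +1 to the per-base
#' signal. Intervals extending beyond chromosome bounds are clipped with a
#' warning.
#'
#' @param fragments fragment `data.table` (chrom/start/end).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param extend_to extension width in bp.
#' @return an `OccupancyTrack` with per-base counts.
#' @export
build_occupancy <- function(fragments, chrom_sizes, extend_to = 70L) {
  stopifnot(extend_to >= 1L)
  extend_to <- as.integer(extend_to)
  clipped <- 0L
  sig <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    v <- numeric(len)
    sub <- fragments[chrom == ch]
    if (nrow(sub) == 0L) return(v)
    m <- (sub$start + sub$end) %/% 2L
    s <- m - extend_to %/% 2L          # 0-based start
    e <- s + extend_to                 # 0-based end (exclusive)
    nclip <- sum(s < 0L | e > len)
    if (nclip > 0L) clipped <<- clipped + nclip
    s <- pmax(s, 0L)
    e <- pmin(e, len)
    ok <- e > s
    # difference-array accumulation, then cumsum
    d <- numeric(len + 1L)
    ds <- tabulate(s[ok] + 1L, nbins = len)
    de <- tabulate(e[ok] + 1L, nbins = len + 1L)
    d[seq_len(len)] <- ds
    d <- d - de
    cumsum(d[seq_len(len)])
  })
  names(sig) <- names(chrom_sizes)
  if (clipped > 0L) {
    warning(clipped, " fragment extension(s) clipped at chromosome bounds")
  }
  tr <- new_track(sig, n_fragments_used = nrow(fragments))
  tr$extend_to <- extend_to
  tr
}

#' Normalize a track to a target fragment depth
#'
#' Scales the signal by `target / n_fragments_used` so that samples become
#' comparable at a common depth (2e8 fragments for genome-scale data).
#'
#' @param track an `OccupancyTrack` built by [build_occupancy()].
#' @param target target fragment count.
#' @return the rescaled track; applying twice is an error.
#' @export
depth_normalize <- function(track, target = 2e8) {
  stopifnot(inherits(track, "OccupancyTrack"))
  if ("depth" %in% track$normalization) {
    stop("depth normalization already applied to this track")
  }
  if (is.na(track$n_fragments_used) || track$n_fragments_used == 0) {
    stop("track has no fragments to normalize")
  }
  f <- target / track$n_fragments_used
  track$signal <- lapply(track$signal, function(v) v * f)
  track$normalization <- c(track$normalization, "depth")
  track$depth_target <- target
  track
}

#' Correct a track for copy-number variation
#'
#' Within each CNV segment the signal is divided by
#' `copy_number / ploidy`; positions outside all segments are assumed to be
#' at ploidy and left unchanged.
#'
#' @param track an `OccupancyTrack`.
#' @param segments `data.table` with chrom, start, end, copy_number
#'   (non-overlapping).
#' @param ploidy assumed ploidy (3 for HeLa-like genomes).
#' @return the corrected track.
#' @export
cnv_correct <- function(track, segments, ploidy = 3) {
  stopifnot(inherits(track, "OccupancyTrack"))
  if ("cnv" %in% track$normalization) {
    stop("CNV correction already applied to this track")
  }
  if (nrow(segments)) {
    if (any(segments$copy_number <= 0)) stop("copy_number must be > 0")
    for (i in seq_len(nrow(segments))) {
      ch <- segments$chrom[i]
      if (!ch %in% names(track$signal)) next
      len <- length(track$signal[[ch]])
      s <- max(segments$start[i], 0L) + 1L
      e <- min(segments$end[i], len)
      if (e >= s) {
        track$signal[[ch]][s:e] <-
          track$signal[[ch]][s:e] / (segments$copy_number[i] / ploidy)
      }
    }
  }
  track$normalization <- c(track$normalization, "cnv")
  track
}

#' Call nucleosome positions from an occupancy track
#'
#' A defined substitute for an external position caller: the track is
#' smoothed with a centred moving average (`smooth_win`, default 73 bp =
#' half a nucleosome), local maxima are extracted (ties broken leftmost),
#' and maxima are retained greedily by height subject to a minimum
#' separation and a minimum height.
#'
#' @param track an `OccupancyTrack`.
#' @param min_distance minimum distance between called dyads, bp.
#' @param min_height minimum smoothed signal at a call (> 0 required).
#' @param smooth_win moving-average window, bp (odd).
#' @return `data.table` with chrom, pos (0-based dyad), height.
#' @export
call_nucleosomes <- function(track, min_distance = 150L, min_height = 0,
                             smooth_win = 73L) {
  stopifnot(inherits(track, "OccupancyTrack"))
  out <- lapply(names(track$signal), function(ch) {
    x <- track$signal[[ch]]
    if (length(x) < smooth_win || all(x == 0)) {
      return(data.table(chrom = character(), pos = integer(),
                        height = numeric()))
    }
    s <- as.numeric(stats::filter(x, rep(1 / smooth_win, smooth_win),
                                  sides = 2))
    s[is.na(s)] <- 0
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nv <- length(r$values)
    left <- c(-Inf, r$values[-nv])
    right <- c(r$values[-1L], -Inf)
    ismax <- r$values > left & r$values > right & r$values > min_height &
      r$values > 0
    if (!any(ismax)) {
      return(data.table(chrom = character(), pos = integer(),
                        height = numeric()))
    }
    cand <- data.table(pos = starts[ismax] - 1L,  # 0-based, leftmost of plateau
                       height = r$values[ismax])
    setorder(cand, -height, pos)
    blocked <- logical(length(x))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      p <- cand$pos[i]
      if (!blocked[p + 1L]) {
        keep[i] <- TRUE
        lo <- max(p - min_distance + 1L, 0L)
        hi <- min(p + min_distance - 1L, length(x) - 1L)
        blocked[(lo + 1L):(hi + 1L)] <- TRUE
      }
    }
    sel <- cand[keep]
    setorder(sel, pos)
    data.table(chrom = ch, pos = sel$pos, height = sel$height)
  })
  rbindlist(out)
}
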