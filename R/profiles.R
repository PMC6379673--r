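#' Per-fragment GC content
#'
#' GC fraction of each fragment's sequence (N bases excluded from the
#' denominator), plus the genome-wide GC for comparison.
#'
#' @param fragments fragment `data.table`.
#' @param genome `DNAStringSet`.
#' @return list with `gc` (per fragment), `mean_gc` and `genome_gc`.
#' @export
fragment_gc <- function(fragments, genome) {
  gc <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    idx <- which(fragments$chrom == ch)
    len <- length(genome[[ch]])
    if (any(fragments$end[idx] > len | fragments$start[idx] < 0)) {
      stop("fragment beyond chromosome end on ", ch)
    }
    v <- Views(genome[[ch]], start = fragments$start[idx] + 1L,
               end = fragments$end[idx])
    freq <- letterFrequency(v, c("G", "C", "A", "T"))
    gc[idx] <- (freq[, "G"] + freq[, "C"]) / pmax(rowSums(freq), 1L)
  }
  gfreq <- colSums(letterFrequency(genome, c("G", "C", "A", "T")))
  list(gc = gc, mean_gc = mean(gc),
       genome_gc = (gfreq[["G"]] + gfreq[["C"]]) / sum(gfreq))
}

dinuc_sets <- list(
  GC = c("GG", "GC", "CG", "CC"),
  AT = c("AA", "AT", "TA", "TT"))

#' Dinucleotide frequency profile around fragment anchors
#'
#' For each offset o in `-flank .. flank - 1`, the fraction of fragments
#' whose dinucleotide at positions (anchor + o, anchor + o + 1) belongs to
#' the chosen set (GC-set: GG/GC/CG/CC; AT-set: AA/AT/TA/TT; the set
#' frequency is the sum over its four dinucleotides). The anchor is the
#' fragment midpoint `floor((start + end) / 2)` or, for `anchor = "ends"`,
#' both fragment borders (5' and 3' reported separately, the 3' border
#' read outward). Dinucleotides containing N are excluded from numerator
#' and denominator; fragments whose window leaves the chromosome are
#' skipped and counted.
#'
#' @param fragments fragment `data.table`.
#' @param genome `DNAStringSet`.
#' @param set "GC" or "AT".
#' @param anchor "midpoint" or "ends".
#' @param flank half-width of the profile in bp.
#' @return a `DinucProfile`: list with offsets, frequency (midpoint) or
#'   frequency_5p/frequency_3p (ends), set, anchor, n_fragments,
#'   n_skipped.
#' @export
dinuc_profile <- function(fragments, genome, set = c("GC", "AT"),
                          anchor = c("midpoint", "ends"), flank = 300L) {
  set <- match.arg(set)
  anchor <- match.arg(anchor)
  if (nrow(fragments) == 0L) stop("no fragments")
  flank <- as.integer(flank)
  offsets <- seq.int(-flank, flank - 1L)
  want <- dinuc_sets[[set]]

  profile_at <- function(centers, chroms) {
    width <- 2L * flank + 1L
    num <- integer(width - 1L)
    den <- integer(width - 1L)
    skipped <- 0L
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      len <- length(genome[[ch]])
      s <- centers[idx] - flank            # 0-based window start
      ok <- s >= 0L & s + width <= len
      skipped <- skipped + sum(!ok)
      if (!any(ok)) next
      seqs <- as.character(Views(genome[[ch]], start = s[ok] + 1L,
                                 width = width))
      for (j in seq_len(width - 1L)) {
        d <- substring(seqs, j, j + 1L)
        valid <- !grepl("N", d, fixed = TRUE)
        num[j] <- num[j] + sum(d[valid] %in% want)
        den[j] <- den[j] + sum(valid)
      }
    }
    list(freq = ifelse(den > 0L, num / den, NA_real_), skipped = skipped)
  }

  if (anchor == "midpoint") {
    ctr <- (fragments$start + fragments$end) %/% 2L
    pr <- profile_at(ctr, fragments$chrom)
    structure(list(offsets = offsets, frequency = pr$freq, set = set,
                   anchor = anchor, n_fragments = nrow(fragments),
                   n_skipped = pr$skipped),
              class = "DinucProfile")
  } else {
    p5 <- profile_at(fragments$start, fragments$chrom)
    p3 <- profile_at(fragments$end - 1L, fragments$chrom)
    structure(list(offsets = offsets, frequency_5p = p5$freq,
                   frequency_3p = rev(p3$freq), set = set, anchor = anchor,
                   n_fragments = nrow(fragments),
                   n_skipped = p5$skipped + p3$skipped),
              class = "DinucProfile")
  }
}

#' @export
print.DinucProfile <- function(x, ...) {
  cat(sprintf("DinucProfile (%s-set, %s): %d fragments, offsets %d..%d\n",
              x$set, x$anchor, x$n_fragments, min(x$offsets),
              max(x$offsets)))
  invisible(x)
}

#' Uniformly placed control fragments
#'
#' Control for dinucleotide profiles: `n` fragments of exactly `length` bp
#' placed uniformly on the genome (the reference analyses use 1e6
#' fragments of 147 bp).
#'
#' @param genome `DNAStringSet`.
#' @param n fragment count.
#' @param length fragment length, bp.
#' @param seed optional seed.
#' @return fragment `data.table` (condition "random").
#' @export
random_fragment_control <- function(genome, n = 1e6, length = 147L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- vapply(seq_along(genome), function(i) length(genome[[i]]),
                 integer(1))
  names(lens) <- names(genome)
  if (all(lens < length)) stop("genome shorter than the fragment length")
  lens <- lens[lens >= length]
  ch <- names(lens)[sample.int(base::length(lens), n, replace = TRUE,
                               prob = as.numeric(lens))]
  s <- integer(n)
  for (cc in unique(ch)) {
    idx <- which(ch == cc)
    s[idx] <- sample.int(lens[[cc]] - length + 1L, base::length(idx),
                         replace = TRUE) - 1L
  }
  out <- data.table(chrom = ch, start = as.integer(s),
                    end = as.integer(s + length), condition = "random")
  setorder(out, chrom, start)
  out
}

#' Spectral power of a dinucleotide profile at a target period
#'
#' Quantifies the ~10-bp phasing of nucleosome-bound DNA: the profile is
#' restricted to the nucleosome footprint (+-73 bp around the anchor),
#' mean-subtracted, discrete-Fourier transformed, and the fraction of
#' non-DC spectral power in the bin nearest `1/period` (and its two
#' neighbours, absorbing leakage from the non-integral cycle count) is
#' returned. A pure sinusoid of the target period scores near 1, a
#' constant profile scores 0.
#'
#' @param profile a midpoint `DinucProfile` with flank >= 73.
#' @param period target period in bp.
#' @return power fraction in `[0, 1]`.
#' @export
periodicity_score <- function(profile, period = 10) {
  stopifnot(inherits(profile, "DinucProfile"))
  if (max(profile$offsets) < 73L) stop("profile flank smaller than 73 bp")
  if (period >= 2 * 73) stop("period exceeds the footprint")
  sel <- profile$offsets >= -73L & profile$offsets <= 73L
  x <- profile$frequency[sel]
  x <- x[!is.na(x)]
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  n <- length(x)
  pw <- Mod(fft(x))^2
  half <- pw[2:(n %/% 2 + 1L)]
  k <- round(n / period)
  k <- max(1L, min(k, length(half)))
  bins <- unique(pmax(1L, pmin(length(half), (k - 1L):(k + 1L))))
  sum(half[bins]) / sum(half)
}

#' Feature-anchored aggregate profile or heatmap of a track
#'
#' Extracts the track signal in a window of +-`flank` bp around each
#' feature midpoint (minus-strand features reversed), dropping features
#' whose window leaves the chromosome. `mean_profile` returns the
#' per-offset mean; `heatmap` returns the per-feature matrix, ordered by
#' `sort_by` descending (features without a score sort last).
#'
#' @param track an `OccupancyTrack`.
#' @param features `data.table` with chrom, start, end, optional strand
#'   and score columns.
#' @param flank half-window in bp.
#' @param mode "mean_profile" or "heatmap".
#' @param sort_by optional numeric vector (or feature column name) used to
#'   order heatmap rows.
#' @return numeric vector (mean_profile, names = offsets) or matrix
#'   (heatmap). Attribute `n_dropped` counts clipped features.
#' @export
aggregate_profile <- function(track, features, flank = 1000L,
                              mode = c("mean_profile", "heatmap"),
                              sort_by = NULL) {
  mode <- match.arg(mode)
  if (nrow(features) == 0L) stop("empty feature set")
  flank <- as.integer(flank)
  ctr <- (features$start + features$end) %/% 2L
  lens <- track_chrom_sizes(track)
  ok <- features$chrom %in% names(lens)
  ok[ok] <- ctr[ok] - flank >= 0L &
    ctr[ok] + flank < lens[features$chrom[ok]]
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("all features clipped at chromosome bounds")
  keep <- which(ok)
  mat <- matrix(NA_real_, length(keep), 2L * flank + 1L)
  for (r in seq_along(keep)) {
    i <- keep[r]
    v <- track$signal[[features$chrom[i]]][(ctr[i] - flank + 1L):
                                             (ctr[i] + flank + 1L)]
    if ("strand" %in% names(features) &&
        identical(features$strand[i], "-")) {
      v <- rev(v)
    }
    mat[r, ] <- v
  }
  colnames(mat) <- as.character(seq.int(-flank, flank))
  if (mode == "mean_profile") {
    out <- colMeans(mat)
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  sb <- if (is.null(sort_by)) {
    NULL
  } else if (is.character(sort_by) && length(sort_by) == 1L) {
    features[[sort_by]][keep]
  } else {
    sort_by[keep]
  }
  if (!is.null(sb)) {
    mat <- mat[order(-xtfrm(sb), na.last = TRUE), , drop = FALSE]
  }
  attr(mat, "n_dropped") <- n_dropped
  mat
}
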