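#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Own implementation of the BH step-up rule (kept independent of
#' `p.adjust` so the two can be cross-checked): q_(i) = min_{j >= i}
#' ( p_(j) * m / j ), capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided equal-rate test of two Poisson counts, conditional on the sum
# (exact binomial with p = 1/2); vectorized over x, y
poisson_rate_p <- function(x, y) {
  n <- x + y
  p <- rep(1, length(x))
  nz <- n > 0
  p[nz] <- pmin(1, 2 * pbinom(pmin(x[nz], y[nz]), n[nz], 0.5))
  p
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact enumeration over the hypergeometric support: the p-value is the
#' sum of the probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table (with the
#' standard relative tolerance). The odds ratio is the sample
#' cross-product ratio.
#'
#' @param tab 2x2 matrix or integer vector (a, b, c, d) by row.
#' @return list with `p_value`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2, byrow = is.null(dim(tab)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("degenerate margin in contingency table; p = 1")
    return(list(p_value = 1,
                odds_ratio = NA_real_, table = tab))
  }
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  list(p_value = p, odds_ratio = or, table = tab)
}

#' Call local differential chromatin accessibility sites
#'
#' A defined substitute for an external differential peak caller, with the
#' reference tunables (minimum width 70 bp, per-base p < 1e-2, FDR < 0.05).
#' Both tracks must be depth-normalized to the same total (and GC-corrected
#' for real use). Per base, the rounded low and high signals are compared
#' with a two-sided Poisson rate test; consecutive bases with p below
#' `base_p` and a consistent sign of (low - high) are merged into candidate
#' intervals (no gap tolerance), intervals shorter than `min_width` are
#' discarded, and each surviving interval is re-tested on its summed signal
#' expressed in fragment units (summed per-base signal divided by the
#' midpoint-extension width, so the counts entering the interval test are
#' approximately independent fragments rather than correlated bases).
#' Benjamini-Hochberg correction is applied across intervals and sites with
#' q below `fdr` are reported. Sites enriched in the low condition are
#' "hyper_accessible", sites enriched in the high condition "inaccessible".
#'
#' @param low_track,high_track normalized `OccupancyTrack`s.
#' @param min_width minimum site width in bp.
#' @param base_p per-base candidate threshold.
#' @param fdr FDR threshold on interval q-values.
#' @param extend_to midpoint-extension width used to build the tracks;
#'   taken from the tracks when present.
#' @details The testing universe for the FDR correction is wider than the
#'   reported candidates: every maximal same-sign run of length >=
#'   `min_width` enters the Benjamini-Hochberg correction with its
#'   interval p-value, whether or not it contains a per-base-significant
#'   core. Correcting only across the few candidates that survive the
#'   per-base gate would be anticonservative, because the same data that
#'   selected a candidate is reused in its interval test; padding the
#'   universe with the (overwhelmingly null) remaining sign-runs restores
#'   calibration, which the null-genome tests verify empirically.
#' @return `data.table` of `DifferentialSite`s: chrom, start, end,
#'   direction, p_value, q_value, low_mean, high_mean. The full tested
#'   universe (pre-FDR) is in attribute `universe`; candidates passing
#'   the per-base gate (pre-FDR) in attribute `candidates`.
#' @export
call_differential_sites <- function(low_track, high_track, min_width = 70L,
                                    base_p = 1e-2, fdr = 0.05,
                                    extend_to = NULL) {
  stopifnot(inherits(low_track, "OccupancyTrack"),
            inherits(high_track, "OccupancyTrack"))
  if (!identical(low_track$normalization, high_track$normalization)) {
    stop("tracks have different normalization states")
  }
  if (is.null(extend_to)) {
    extend_to <- low_track$extend_to
    if (is.null(extend_to)) extend_to <- 70L
  }
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      p_value = numeric(), q_value = numeric(),
                      low_mean = numeric(), high_mean = numeric())
  rows <- list()
  for (ch in names(low_track$signal)) {
    lraw <- low_track$signal[[ch]]
    hraw <- high_track$signal[[ch]]
    l <- round(lraw)
    h <- round(hraw)
    pbase <- poisson_rate_p(l, h)
    sig <- pbase < base_p & (l != h)
    dsign <- sign(l - h)
    r <- rle(dsign)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0 & r$lengths >= min_width)
    if (!length(keep)) next
    cl <- c(0, cumsum(lraw))
    chh <- c(0, cumsum(hraw))
    sigdir <- sig * dsign
    out <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      s0 <- starts[i]; e0 <- ends[i]
      # longest per-base-significant core of matching sign inside the run
      core <- rle(sigdir[s0:e0] == r$values[i])
      cend <- cumsum(core$lengths)
      ok <- which(core$values & core$lengths >= min_width)
      if (length(ok)) {
        b <- ok[which.max(core$lengths[ok])]
        cs <- s0 + cend[b] - core$lengths[b]
        ce <- s0 + cend[b] - 1L
        is_cand <- TRUE
      } else {
        cs <- s0; ce <- e0
        is_cand <- FALSE
      }
      sl <- cl[ce + 1L] - cl[cs]
      sh <- chh[ce + 1L] - chh[cs]
      out[[j]] <- data.table(
        chrom = ch, start = cs - 1L, end = ce,
        direction = if (r$values[i] > 0) "hyper_accessible"
                    else "inaccessible",
        p_value = poisson_rate_p(round(sl / extend_to),
                                 round(sh / extend_to)),
        low_mean = sl / (ce - cs + 1L), high_mean = sh / (ce - cs + 1L),
        candidate = is_cand)
    }
    rows[[ch]] <- rbindlist(out)
  }
  if (!length(rows)) {
    attr(empty, "universe") <- empty
    return(empty)
  }
  universe <- rbindlist(rows)
  universe[, q_value := bh_fdr(p_value)]
  out <- universe[candidate & q_value < fdr,
                  .(chrom, start, end, direction, p_value, q_value,
                    low_mean, high_mean)]
  setorder(out, chrom, start)
  attr(out, "universe") <- universe
  attr(out, "candidates") <- universe[candidate == TRUE]
  out
}

#' Overlap enrichment of differential sites in a feature set
#'
#' Builds the 2x2 table of site direction (hyper-accessible vs
#' inaccessible) against overlap (>= 1 bp) with a feature interval set and
#' applies the two-sided Fisher's exact test.
#'
#' @param sites a [call_differential_sites()] result (both directions
#'   present).
#' @param features `data.table` of intervals (chrom, start, end).
#' @return list with odds_ratio, p_value and the contingency table.
#' @export
overlap_enrichment <- function(sites, features) {
  if (nrow(sites) == 0L || nrow(features) == 0L) {
    stop("empty site or feature set")
  }
  ov <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    fe <- features[chrom == ch]
    if (nrow(fe) == 0L) next
    ov[si] <- overlapsAny(
      IRanges(sites$start[si] + 1L, sites$end[si]),
      IRanges(fe$start + 1L, fe$end))
  }
  hyper <- sites$direction == "hyper_accessible"
  tab <- matrix(c(sum(hyper & ov), sum(hyper & !ov),
                  sum(!hyper & ov), sum(!hyper & !ov)),
                2, 2, byrow = TRUE,
                dimnames = list(c("hyper_accessible", "inaccessible"),
                                c("overlap", "no_overlap")))
  res <- fisher_exact_2x2(tab)
  list(odds_ratio = res$odds_ratio, p_value = res$p_value,
       contingency = tab)
}

#' Write differential sites as BED6+
#'
#' Name field carries the direction; extra columns carry p and q.
#'
#' @param sites site table.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  dt <- data.table(chrom = sites$chrom, start = sites$start,
                   end = sites$end, name = sites$direction,
                   score = pmin(1000L, as.integer(-10 * log10(
                     pmax(sites$q_value, 1e-100)))),
                   strand = ".",
                   p_value = signif(sites$p_value, 4),
                   q_value = signif(sites$q_value, 4))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
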