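#' Specification of a synthetic MNase-seq genome
#'
#' Describes the stated world the generator emulates: chromosomes tiled by
#' GC domains (the large-scale GC variation real genomes show around a
#' ~40% average), regularly spaced nucleosomes with small positional
#' jitter, optional 10-bp W/S dinucleotide phasing at dyads, planted
#' fragile-nucleosome hyper-accessible sites, optional compacted domains,
#' CNV segments and mappability masks.
#'
#' @param chromosomes named integer vector of chromosome lengths.
#' @param domains `data.table` with chrom, start, end, gc, compaction,
#'   label tiling each chromosome; `NULL` builds a default isochore-like
#'   tiling of AT-rich (`gc_mean - gc_amp`) and GC-rich
#'   (`gc_mean + gc_amp`) tiles whose mixing proportion varies
#'   sinusoidally along the chromosome with period `gc_period`.
#' @param gc_mean,gc_amp,gc_period,domain_tile default-domain parameters.
#' @param nucleosome_spacing nucleosome repeat length, bp.
#' @param dyad_jitter max absolute uniform jitter of dyad positions, bp.
#' @param periodic_positioning plant 10-bp phased W/S dinucleotide
#'   composition around dyads.
#' @param periodic_amplitude amplitude of the phased GC modulation.
#' @param n_hyper number of fragile-nucleosome hyper-accessible sites to
#'   plant.
#' @param at_bias apply the AT-dependent nucleosome-fragility rule when
#'   digesting under the high condition (the source of the GC bias);
#'   `FALSE` gives the fully null genome.
#' @param at_threshold local AT fraction (150-bp footprint) above which a
#'   nucleosome's cleavage weight is doubled in the high condition.
#' @param cnv_segments optional `data.table` chrom, start, end,
#'   copy_number.
#' @param masked_intervals optional `data.table` chrom, start, end set to
#'   mappability 0.
#' @param ploidy assumed ploidy for CNV scaling.
#' @param seed RNG seed.
#' @return a `GenomeSpec` list.
#' @export
genome_spec <- function(chromosomes = c(chrS = 5e6),
                        domains = NULL,
                        gc_mean = 0.42, gc_amp = 0.09, gc_period = 2e6,
                        domain_tile = 2.5e4,
                        nucleosome_spacing = 180L,
                        dyad_jitter = 5L,
                        periodic_positioning = FALSE,
                        periodic_amplitude = 0.10,
                        n_hyper = 50L,
                        at_bias = TRUE,
                        at_threshold = 0.6,
                        cnv_segments = NULL,
                        masked_intervals = NULL,
                        ploidy = 3,
                        seed = 1L) {
  chromosomes <- setNames(as.integer(chromosomes), names(chromosomes))
  if (any(chromosomes <= 0L)) stop("zero-length chromosome in spec")
  if (is.null(domains)) {
    # Bimodal, isochore-like domain layout: each tile is either AT-rich
    # (gc ~ gc_mean - gc_amp, local AT fraction clearly above the
    # fragility threshold) or GC-rich (gc ~ gc_mean + gc_amp, clearly
    # below it), with the AT-rich proportion varying sinusoidally along
    # the chromosome. The hard AT-threshold fragility rule then separates
    # cleanly by domain, and the injected high-condition bias is a smooth
    # function of window GC at every window size.
    set.seed(seed + 1000L)
    domains <- rbindlist(lapply(names(chromosomes), function(ch) {
      len <- chromosomes[[ch]]
      s <- seq(0L, len - 1L, by = as.integer(domain_tile))
      e <- pmin(s + as.integer(domain_tile), len)
      mid <- (s + e) / 2
      p_at <- 0.5 - 0.45 * sin(2 * pi * mid / gc_period)
      is_at <- runif(length(s)) < p_at
      gc <- ifelse(is_at, gc_mean - gc_amp, gc_mean + gc_amp) +
        rnorm(length(s), 0, 0.01)
      gc <- pmin(pmax(gc, 0.05), 0.95)
      data.table(chrom = ch, start = s, end = e, gc = gc, compaction = 1,
                 label = sprintf("%s_%s_dom%03d", ch,
                                 ifelse(is_at, "AT", "GC"), seq_along(s)))
    }))
  }
  setDT(domains)
  if (any(domains$gc <= 0 | domains$gc >= 1)) {
    stop("domain gc_fraction must lie strictly in (0, 1)")
  }
  for (ch in names(chromosomes)) {
    d <- domains[chrom == ch][order(start)]
    if (nrow(d) == 0L || d$start[1] != 0L ||
        d$end[nrow(d)] != chromosomes[[ch]] ||
        (nrow(d) > 1L && any(d$start[-1] != d$end[-nrow(d)]))) {
      stop("domains must tile chromosome ", ch, " without gaps or overlap")
    }
  }
  structure(list(chromosomes = chromosomes, domains = domains,
                 nucleosome_spacing = as.integer(nucleosome_spacing),
                 dyad_jitter = as.integer(dyad_jitter),
                 periodic_positioning = isTRUE(periodic_positioning),
                 periodic_amplitude = periodic_amplitude,
                 n_hyper = as.integer(n_hyper),
                 at_bias = isTRUE(at_bias),
                 at_threshold = at_threshold,
                 cnv_segments = cnv_segments,
                 masked_intervals = masked_intervals,
                 ploidy = ploidy,
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

#' Generate a synthetic genome with known nucleosome dyads
#'
#' Bases are drawn i.i.d. at each domain's GC fraction (G and C, A and T
#' equiprobable within their class). Nucleosome dyads are placed every
#' `nucleosome_spacing` bp with uniform jitter. With
#' `periodic_positioning`, the per-base probability of a strong (G/C) base
#' within +-73 bp of each dyad is modulated as
#' `gc + amplitude * cos(2 * pi * offset / 10)`, planting the 10-bp W/S
#' phasing of nucleosome-bound DNA.
#'
#' @param spec a [genome_spec()].
#' @return list with `genome` (`DNAStringSet`), `dyads` (named list of
#'   0-based dyad positions per chromosome) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  seqs <- list()
  dyads <- list()
  for (ch in names(spec$chromosomes)) {
    len <- spec$chromosomes[[ch]]
    dom <- spec$domains[chrom == ch][order(start)]
    p_s <- numeric(len)
    for (i in seq_len(nrow(dom))) {
      p_s[(dom$start[i] + 1L):dom$end[i]] <- dom$gc[i]
    }
    half <- spec$nucleosome_spacing %/% 2L
    dy <- seq(half, len - half, by = spec$nucleosome_spacing)
    if (spec$dyad_jitter > 0L) {
      dy <- dy + sample.int(2L * spec$dyad_jitter + 1L, length(dy),
                            replace = TRUE) - spec$dyad_jitter - 1L
    }
    dy <- dy[dy >= 74L & dy <= len - 75L]
    if (spec$periodic_positioning) {
      off <- -73:73
      modu <- spec$periodic_amplitude * cos(2 * pi * off / 10)
      for (d in dy) {
        idx <- d + off + 1L          # dyad is 0-based
        p_s[idx] <- p_s[idx] + modu
      }
      p_s <- pmin(pmax(p_s, 0.02), 0.98)
    }
    strong <- runif(len) < p_s
    b <- character(len)
    b[strong] <- sample(c("G", "C"), sum(strong), replace = TRUE)
    b[!strong] <- sample(c("A", "T"), sum(!strong), replace = TRUE)
    seqs[[ch]] <- paste(b, collapse = "")
    dyads[[ch]] <- as.integer(dy)
  }
  genome <- DNAStringSet(unlist(seqs))
  names(genome) <- names(spec$chromosomes)
  list(genome = genome, dyads = dyads, spec = spec)
}

# choose n_hyper dyads as planted fragile-nucleosome sites: away from
# chromosome edges, mutually separated by >= min_sep
plant_hyper_sites <- function(dyads, spec, min_sep = 2e4, edge = 5e4) {
  if (spec$n_hyper == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), dyad = integer()))
  }
  per_chrom <- setNames(
    pmax(1L, round(spec$n_hyper * spec$chromosomes /
                     sum(spec$chromosomes))),
    names(spec$chromosomes))
  # adjust rounding to hit the exact total
  while (sum(per_chrom) > spec$n_hyper) {
    i <- which.max(per_chrom); per_chrom[i] <- per_chrom[i] - 1L
  }
  while (sum(per_chrom) < spec$n_hyper) {
    i <- which.max(spec$chromosomes); per_chrom[i] <- per_chrom[i] + 1L
  }
  out <- lapply(names(spec$chromosomes), function(ch) {
    n <- per_chrom[[ch]]
    if (n == 0L) return(NULL)
    dy <- dyads[[ch]]
    edge_ch <- min(edge, spec$chromosomes[[ch]] %/% 10)
    cand <- dy[dy > edge_ch & dy < spec$chromosomes[[ch]] - edge_ch]
    chosen <- integer(0)
    for (d in sample(cand)) {
      if (!length(chosen) || all(abs(chosen - d) >= min_sep)) {
        chosen <- c(chosen, d)
        if (length(chosen) == n) break
      }
    }
    data.table(chrom = ch, start = as.integer(sort(chosen)) - 90L,
               end = as.integer(sort(chosen)) + 90L,
               dyad = as.integer(sort(chosen)))
  })
  rbindlist(out)
}
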