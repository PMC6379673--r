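#' Derive per-site cleavage weights for a digestion condition
#'
#' Builds the genome-wide cleavage-site table the tiled digestion consumes:
#' nucleosome sites at the dyads (weight 1) and linker sites midway between
#' adjacent dyads plus one flanking site on each side (weight 10 times the
#' domain's compaction multiplier). Nucleosome weights are doubled where
#' the local AT fraction over the 150-bp footprint exceeds the spec's
#' threshold, but only when digesting under the high condition - this is
#' what injects the condition-asymmetric GC bias. Planted hyper-accessible
#' sites get nucleosome weight x4 and flanking linker weight x1.2
#' (applied in both conditions; their differential extraction emerges from
#' the cut numbers alone).
#'
#' @param genome `DNAStringSet`.
#' @param dyads named list of 0-based dyad positions.
#' @param spec the [genome_spec()].
#' @param condition "low" or "high".
#' @param hyper_sites `data.table` with chrom, dyad columns (planted
#'   sites), or NULL.
#' @return `data.table` with chrom, pos, kind ("linker"/"nuc"), weight.
#' @export
derive_cleavage_weights <- function(genome, dyads, spec,
                                    condition = c("low", "high"),
                                    hyper_sites = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(spec, "GenomeSpec"))
  out <- lapply(names(spec$chromosomes), function(ch) {
    len <- spec$chromosomes[[ch]]
    dy <- dyads[[ch]]
    if (any(dy < 0L | dy >= len)) stop("dyad outside chromosome ", ch)
    nd <- length(dy)
    link <- as.integer(round(c(
      max(0L, dy[1] - spec$nucleosome_spacing %/% 2L),
      (dy[-nd] + dy[-1]) / 2,
      min(len, dy[nd] + spec$nucleosome_spacing %/% 2L))))
    sites <- data.table(
      chrom = ch,
      pos = c(link, dy),
      kind = c(rep("linker", nd + 1L), rep("nuc", nd)),
      weight = c(rep(10, nd + 1L), rep(1, nd)))
    # compaction multiplier of the domain each linker falls in
    dom <- spec$domains[chrom == ch][order(start)]
    if (any(dom$compaction != 1)) {
      di <- findInterval(sites$pos[sites$kind == "linker"], dom$start)
      sites[kind == "linker", weight := weight * dom$compaction[di]]
    }
    # AT-dependent nucleosome fragility, high condition only
    if (spec$at_bias && condition == "high") {
      v <- Views(genome[[ch]], start = dy - 74L + 1L, end = dy + 75L)
      freq <- letterFrequency(v, c("A", "T", "G", "C"))
      at <- (freq[, "A"] + freq[, "T"]) / pmax(rowSums(freq), 1L)
      fragile <- which(at > spec$at_threshold)
      if (length(fragile)) {
        nuc_rows <- nd + 1L + fragile
        sites[nuc_rows, weight := weight * 2]
      }
    }
    # planted hyper-accessible fragile nucleosomes
    if (!is.null(hyper_sites) && nrow(hyper_sites)) {
      hs <- hyper_sites[chrom == ch]
      if (nrow(hs)) {
        k <- match(hs$dyad, dy)
        if (anyNA(k)) stop("hyper site dyad not in dyad list")
        sites[nd + 1L + k, weight := weight * 4]        # nucleosome x4
        sites[k, weight := weight * 1.2]                # left linker
        sites[k + 1L, weight := weight * 1.2]           # right linker
      }
    }
    setorder(sites, pos)
    sites
  })
  rbindlist(out)
}

#' Simulate sequenced fragments by tiled genome digestion
#'
#' Digests the genome tile by tile (9-kb tiles, reusing the validated
#' array digestion with cut numbers scaled to the tile's site count:
#' 20 per 101 sites for the low condition, 70 per 101 for high). Two tile
#' grids offset by half a tile are digested and each tile only contributes
#' fragments whose midpoint lies in its central half, so every position is
#' sampled by exactly one tile per grid and boundary artefacts cancel.
#' Fragments spanning exactly one uncut nucleosome site are
#' mono-nucleosomal, fragments spanning an uncut nucleosome-linker-
#' nucleosome triple are di-nucleosomal; reported lengths are re-drawn
#' uniformly within 145-195 bp (mono) and 260-480 bp (di) around the
#' fragment midpoint so the downstream size gates are exercised.
#'
#' @param weights a [derive_cleavage_weights()] table.
#' @param chrom_sizes named chromosome lengths.
#' @param condition "low" or "high" (sets the cut number and the label).
#' @param n_fragments fragments of the requested class to return.
#' @param cls "mono", "di" or "both".
#' @param seed optional seed.
#' @param tile tile size in bp.
#' @param cnv_segments optional CNV table (chrom, start, end,
#'   copy_number); fragment sampling probability scales with
#'   copy_number / ploidy.
#' @param ploidy assumed ploidy.
#' @return `data.table` with chrom, start, end, condition.
#' @export
simulate_fragments <- function(weights, chrom_sizes,
                               condition = c("low", "high"),
                               n_fragments = 1e5, cls = c("mono", "di",
                                                          "both"),
                               seed = NULL, tile = 9000L,
                               cnv_segments = NULL, ploidy = 3) {
  condition <- match.arg(condition)
  cls <- match.arg(cls)
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rate <- (if (condition == "low") 20 else 70) / 101
  half <- tile %/% 2L
  quarter <- tile %/% 4L

  # tile table: both grids, with accepted midpoint range per tile
  tiles <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    tA <- seq(0L, max(0L, len - 1L), by = tile)
    tB <- seq(half, max(half, len - 1L), by = tile)
    dtA <- data.table(chrom = ch, t0 = tA,
                      lo = tA + quarter, hi = tA + 3L * quarter)
    dtA[1, lo := 0L]
    dtA[.N, hi := len]
    dtB <- data.table(chrom = ch, t0 = tB,
                      lo = tB + quarter, hi = tB + 3L * quarter)
    rbind(dtA, dtB)
  }))
  tiles[, hi := pmin(hi, chrom_sizes[chrom])]

  wsplit <- split(weights, weights$chrom)
  digest_pass <- function(n_templates) {
    res <- vector("list", nrow(tiles))
    for (i in seq_len(nrow(tiles))) {
      ch <- tiles$chrom[i]
      w <- wsplit[[ch]]
      sel <- which(w$pos >= tiles$t0[i] & w$pos < tiles$t0[i] + tile)
      if (length(sel) < 6L) next
      pos <- w$pos[sel]
      kindv <- w$kind[sel]
      n_cuts <- max(2L, as.integer(round(rate * length(sel))))
      fr <- cpp_digest_fragments(pos, w$weight[sel], n_cuts, n_templates)
      if (!length(fr$from_idx)) next
      from <- fr$from_idx
      to <- fr$to_idx
      internal <- to - from - 1L
      span <- pos[to] - pos[from]
      mono <- internal == 1L & kindv[from + 1L] == "nuc" &
        span >= 140L & span <= 220L
      di <- internal == 3L & kindv[pmin(from + 1L, length(kindv))] == "nuc" &
        span >= 300L & span <= 430L
      keepv <- if (cls == "mono") mono else if (cls == "di") di else mono | di
      if (!any(keepv)) next
      midp <- (pos[from[keepv]] + pos[to[keepv]]) %/% 2L
      inwin <- midp >= tiles$lo[i] & midp < tiles$hi[i]
      if (!any(inwin)) next
      res[[i]] <- data.table(chrom = ch, mid = midp[inwin],
                             mono = mono[keepv][inwin])
    }
    rbindlist(res)
  }

  # pilot to estimate yield, then batches until the target is reached
  pilot <- digest_pass(2L)
  got <- list(pilot)
  n_got <- nrow(pilot)
  yield <- max(n_got / 2, 1)
  guard <- 0L
  while (n_got < n_fragments * 1.05 && guard < 50L) {
    guard <- guard + 1L
    need <- n_fragments * 1.05 - n_got
    nt <- max(1L, min(500L, as.integer(ceiling(need / yield))))
    batch <- digest_pass(nt)
    got[[length(got) + 1L]] <- batch
    n_got <- n_got + nrow(batch)
  }
  frags <- rbindlist(got)
  if (nrow(frags) < n_fragments) {
    stop("fragment simulation could not reach the requested count (got ",
         nrow(frags), " of ", n_fragments, ")")
  }
  # exact-count subsample; CNV segments scale the inclusion probability
  pr <- rep(1, nrow(frags))
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    for (j in seq_len(nrow(cnv_segments))) {
      inseg <- frags$chrom == cnv_segments$chrom[j] &
        frags$mid >= cnv_segments$start[j] &
        frags$mid < cnv_segments$end[j]
      pr[inseg] <- cnv_segments$copy_number[j] / ploidy
    }
  }
  take <- if (all(pr == pr[1])) {
    sample.int(nrow(frags), n_fragments)
  } else {
    # weighted sampling without replacement via exponential keys
    order(rexp(nrow(frags)) / pr)[seq_len(n_fragments)]
  }
  frags <- frags[take]
  # draw reported lengths within the class gates, centred on the midpoint
  L <- integer(nrow(frags))
  ismono <- frags$mono
  L[ismono] <- 145L + sample.int(51L, sum(ismono), replace = TRUE) - 1L
  L[!ismono] <- 260L + sample.int(221L, sum(!ismono), replace = TRUE) - 1L
  s <- frags$mid - L %/% 2L
  lenv <- chrom_sizes[frags$chrom]
  s <- pmax(0L, pmin(s, lenv - L))
  out <- data.table(chrom = frags$chrom, start = as.integer(s),
                    end = as.integer(s + L), condition = condition)
  setorder(out, chrom, start)
  out
}

#' Simulate a complete differential MNase-seq experiment
#'
#' Orchestrates the generator: genome + dyads, planted hyper-accessible
#' sites, per-condition cleavage weights, and low/high fragment sets.
#'
#' @param spec a [genome_spec()].
#' @param n_low,n_high mono-nucleosomal fragments per condition.
#' @param seed master seed (defaults to the spec's).
#' @return list with genome, dyads, hyper_sites, weights_low,
#'   weights_high, fragments (one `data.table`, condition column), spec.
#' @export
simulate_mnase_experiment <- function(spec, n_low = 2e5, n_high = 2e5,
                                      seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  gen <- generate_genome(spec)
  set.seed(seed + 1L)
  hyper <- plant_hyper_sites(gen$dyads, spec)
  w_low <- derive_cleavage_weights(gen$genome, gen$dyads, spec, "low",
                                   hyper)
  w_high <- derive_cleavage_weights(gen$genome, gen$dyads, spec, "high",
                                    hyper)
  fl <- simulate_fragments(w_low, spec$chromosomes, "low", n_low,
                           seed = seed + 2L,
                           cnv_segments = spec$cnv_segments,
                           ploidy = spec$ploidy)
  fh <- simulate_fragments(w_high, spec$chromosomes, "high", n_high,
                           seed = seed + 3L,
                           cnv_segments = spec$cnv_segments,
                           ploidy = spec$ploidy)
  list(genome = gen$genome, dyads = gen$dyads, hyper_sites = hyper,
       weights_low = w_low, weights_high = w_high,
       fragments = rbind(fl, fh), spec = spec, seed = seed)
}

#' Write a synthetic experiment and its ground truth to disk
#'
#' Emits the genome FASTA, per-condition fragment BEDs, a chrom.sizes
#' file, a mappability bedGraph (1 everywhere, 0 over masked intervals),
#' CNV segments as BED+copy number, planted hyper sites and dyads as BED,
#' and a machine-readable JSON manifest describing every planted feature.
#'
#' @param experiment a [simulate_mnase_experiment()] result.
#' @param outdir output directory (created if missing).
#' @return invisible named vector of written paths.
#' @export
emit_truth_bundle <- function(experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- experiment$spec
  paths <- c(genome = file.path(outdir, "genome.fa"),
             chrom_sizes = file.path(outdir, "genome.chrom.sizes"),
             fragments_low = file.path(outdir, "fragments_low.bed"),
             fragments_high = file.path(outdir, "fragments_high.bed"),
             mappability = file.path(outdir, "mappability.bedGraph"),
             cnv = file.path(outdir, "cnv_segments.bed"),
             hyper = file.path(outdir, "hyper_sites.bed"),
             dyads = file.path(outdir, "dyads.bed"),
             manifest = file.path(outdir, "manifest.json"))
  writeXStringSet(experiment$genome, paths["genome"])
  fwrite(data.table(chrom = names(spec$chromosomes),
                    size = spec$chromosomes),
         paths["chrom_sizes"], sep = "\t", col.names = FALSE)
  for (co in c("low", "high")) {
    fwrite(experiment$fragments[condition == co,
                                .(chrom, start, end, condition)],
           paths[paste0("fragments_", co)], sep = "\t", col.names = FALSE)
  }
  # mappability: 1 everywhere, masked intervals 0
  map <- rbindlist(list(
    data.table(chrom = names(spec$chromosomes), start = 0L,
               end = spec$chromosomes, value = 1),
    if (!is.null(spec$masked_intervals) && nrow(spec$masked_intervals)) {
      data.table(chrom = spec$masked_intervals$chrom,
                 start = spec$masked_intervals$start,
                 end = spec$masked_intervals$end, value = 0)
    }))
  fwrite(map, paths["mappability"], sep = "\t", col.names = FALSE)
  cnv <- if (!is.null(spec$cnv_segments) && nrow(spec$cnv_segments)) {
    spec$cnv_segments[, .(chrom, start, end, copy_number)]
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               copy_number = numeric())
  }
  fwrite(cnv, paths["cnv"], sep = "\t", col.names = FALSE)
  fwrite(experiment$hyper_sites[, .(chrom, start, end)], paths["hyper"],
         sep = "\t", col.names = FALSE)
  dyad_bed <- rbindlist(lapply(names(experiment$dyads), function(ch) {
    data.table(chrom = ch, start = experiment$dyads[[ch]],
               end = experiment$dyads[[ch]] + 1L)
  }))
  fwrite(dyad_bed, paths["dyads"], sep = "\t", col.names = FALSE)
  manifest <- list(
    chromosomes = as.list(spec$chromosomes),
    seed = experiment$seed,
    nucleosome_spacing = spec$nucleosome_spacing,
    periodic_positioning = spec$periodic_positioning,
    at_bias = spec$at_bias,
    at_threshold = spec$at_threshold,
    ploidy = spec$ploidy,
    n_hyper = nrow(experiment$hyper_sites),
    hyper_sites = experiment$hyper_sites,
    cnv_segments = cnv,
    n_fragments = as.list(table(experiment$fragments$condition)),
    files = as.list(paths))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
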