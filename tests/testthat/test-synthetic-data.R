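# synthetic_data: genome generation, cleavage weights, fragments, truth

test_that("genome_spec validates domains and GC bounds", {
  expect_error(genome_spec(chromosomes = c(a = 0L)), "zero-length")
  bad <- data.table::data.table(chrom = "a", start = 0L, end = 500L,
                                gc = 1.0, compaction = 1, label = "d")
  expect_error(genome_spec(chromosomes = c(a = 1000L), domains = bad),
               "strictly")
  gap <- data.table::data.table(chrom = "a", start = c(0L, 600L),
                                end = c(500L, 1000L), gc = 0.5,
                                compaction = 1, label = c("d1", "d2"))
  expect_error(genome_spec(chromosomes = c(a = 1000L), domains = gap),
               "tile")
})

test_that("generate_genome hits domain GC and is deterministic by seed", {
  dom <- data.table::data.table(chrom = "a", start = 0L, end = 1000000L,
                                gc = 0.5, compaction = 1, label = "d")
  spec <- genome_spec(chromosomes = c(a = 1000000L), domains = dom,
                      seed = 71L)
  gen <- generate_genome(spec)
  f <- Biostrings::letterFrequency(gen$genome[[1]], c("G", "C"))
  expect_equal(sum(f) / 1e6, 0.5, tolerance = 0.005)
  gen2 <- generate_genome(spec)
  expect_equal(as.character(gen$genome), as.character(gen2$genome))
  expect_equal(gen$dyads, gen2$dyads)
  spec2 <- genome_spec(chromosomes = c(a = 1000000L), domains = dom,
                       seed = 72L)
  expect_false(identical(as.character(generate_genome(spec2)$genome[[1]]),
                         as.character(gen$genome[[1]])))
  # dyads near the stated spacing
  expect_equal(mean(diff(gen$dyads$a)), 180, tolerance = 0.5)
  expect_true(all(abs(diff(gen$dyads$a) - 180) <= 10))
})

test_that("periodic positioning plants a lag-10 autocorrelation", {
  dom <- data.table::data.table(chrom = "a", start = 0L, end = 300000L,
                                gc = 0.5, compaction = 1, label = "d")
  spec <- genome_spec(chromosomes = c(a = 300000L), domains = dom,
                      periodic_positioning = TRUE, seed = 73L)
  gen <- generate_genome(spec)
  # W/W dinucleotide indicator around dyads, averaged over dyads
  s <- as.character(gen$genome[[1]])
  isW <- strsplit(s, "")[[1]] %in% c("A", "T")
  ww <- isW[-length(isW)] & isW[-1]
  prof <- rowMeans(vapply(gen$dyads$a, function(d) {
    ww[(d - 73):(d + 73)]
  }, numeric(147)))
  ac <- stats::acf(prof - mean(prof), lag.max = 15, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[5:15]) + 4L, 10L)
})

test_that("derive_cleavage_weights implements the weighting rules", {
  # neutral 50 % GC genome: (10, 1) everywhere in both conditions
  dom <- data.table::data.table(chrom = "a", start = 0L, end = 50000L,
                                gc = 0.5, compaction = 1, label = "d")
  spec <- genome_spec(chromosomes = c(a = 50000L), domains = dom,
                      seed = 74L)
  gen <- generate_genome(spec)
  for (cond in c("low", "high")) {
    w <- derive_cleavage_weights(gen$genome, gen$dyads, spec, cond)
    expect_true(all(w[kind == "linker", weight] == 10))
    if (cond == "low") {
      expect_true(all(w[kind == "nuc", weight] == 1))
    } else {
      # at GC 0.5 a small binomial tail of 150-bp footprints still
      # crosses the AT > 0.6 fragility threshold
      expect_gt(mean(w[kind == "nuc", weight] == 1), 0.95)
      expect_true(all(w[kind == "nuc", weight] %in% c(1, 2)))
    }
  }

  # AT-rich genome: nucleosome weight 2 in the high condition only
  domat <- data.table::data.table(chrom = "a", start = 0L, end = 50000L,
                                  gc = 0.2, compaction = 1, label = "d")
  specat <- genome_spec(chromosomes = c(a = 50000L), domains = domat,
                        seed = 75L)
  genat <- generate_genome(specat)
  whi <- derive_cleavage_weights(genat$genome, genat$dyads, specat, "high")
  wlo <- derive_cleavage_weights(genat$genome, genat$dyads, specat, "low")
  expect_gt(mean(whi[kind == "nuc", weight] == 2), 0.99)
  expect_true(all(wlo[kind == "nuc", weight] == 1))

  # planted hyper site: nucleosome x4, flanking linkers x1.2
  hyper <- data.table::data.table(chrom = "a",
                                  dyad = gen$dyads$a[10])
  wh <- derive_cleavage_weights(gen$genome, gen$dyads, spec, "low", hyper)
  nuc <- wh[kind == "nuc"]
  expect_equal(nuc$weight[10], 4)
  lk <- wh[kind == "linker"]
  expect_equal(lk$weight[10:11], c(12, 12))
  expect_equal(sum(wh$weight == 12), 2L)

  # compaction multiplies linker weights
  domc <- data.table::copy(dom)
  domc[, compaction := 0.8]
  specc <- genome_spec(chromosomes = c(a = 50000L), domains = domc,
                       seed = 74L)
  wc <- derive_cleavage_weights(gen$genome, gen$dyads, specc, "low")
  expect_true(all(wc[kind == "linker", weight] == 8))

  bad_dyads <- list(a = c(gen$dyads$a, 50010L))
  expect_error(derive_cleavage_weights(gen$genome, bad_dyads, spec,
                                       "low"), "outside")
})

test_that("simulate_fragments returns the requested class and count", {
  exp <- small_experiment(len = 2e5, n = 2e4, n_hyper = 0L, seed = 76L)
  mono <- exp$fragments[condition == "low"]
  expect_equal(nrow(mono), 2e4)
  lens <- mono$end - mono$start
  expect_true(all(lens >= 145 & lens <= 195))

  # di fragments exercise the di gate
  di <- simulate_fragments(exp$weights_low, exp$spec$chromosomes, "low",
                           2000, cls = "di", seed = 77L)
  dl <- di$end - di$start
  expect_equal(nrow(di), 2000L)
  expect_true(all(dl >= 260 & dl <= 480))
  expect_error(simulate_fragments(exp$weights_low, exp$spec$chromosomes,
                                  "low", 0), ">= 1")
})

test_that("fragment sampling is deterministic under seed", {
  exp <- small_experiment(len = 2e5, n = 5e3, n_hyper = 2L, seed = 78L)
  exp2 <- small_experiment(len = 2e5, n = 5e3, n_hyper = 2L, seed = 78L)
  expect_equal(exp$fragments, exp2$fragments)
  expect_equal(exp$hyper_sites, exp2$hyper_sites)
})

test_that("null genome has no condition asymmetry; plants create one", {
  # null: no plants, no AT bias -> per-10 kb counts correlate like
  # replicates
  spec <- genome_spec(chromosomes = c(chrS = 4e5), n_hyper = 0L,
                      at_bias = FALSE, seed = 79L)
  exp <- simulate_mnase_experiment(spec, n_low = 6e4, n_high = 6e4,
                                   seed = 79L)
  rep2 <- simulate_fragments(exp$weights_low, spec$chromosomes, "low",
                             6e4, seed = 790L)
  bins <- seq(0L, 4e5, by = 1e4)
  cnt <- function(fr) {
    tabulate(findInterval(((fr$start + fr$end) %/% 2L), bins),
             nbins = length(bins) - 1L)
  }
  lo <- cnt(exp$fragments[condition == "low"])
  hi <- cnt(exp$fragments[condition == "high"])
  r2 <- cnt(rep2)
  cond_gap <- sd(log2((lo + 1) / (hi + 1)))
  rep_gap <- sd(log2((lo + 1) / (r2 + 1)))
  expect_lt(cond_gap, 2 * rep_gap)

  # planted hyper site: local low:high ratio exceeds the flanking ratio
  expb <- small_experiment(len = 4e5, n = 8e4, n_hyper = 3L, seed = 80L)
  h <- expb$hyper_sites[1]
  near <- function(fr, a, b) sum(fr$start < b & fr$end > a)
  lo <- expb$fragments[condition == "low"]
  hi <- expb$fragments[condition == "high"]
  site_ratio <- (near(lo, h$start, h$end) + 1) /
    (near(hi, h$start, h$end) + 1)
  flank_ratio <- (near(lo, h$start + 3000L, h$end + 3000L) + 1) /
    (near(hi, h$start + 3000L, h$end + 3000L) + 1)
  expect_gt(site_ratio, flank_ratio)
})

test_that("emit_truth_bundle writes a consistent bundle", {
  spec <- genome_spec(
    chromosomes = c(chrS = 1e5), n_hyper = 2L, seed = 81L,
    cnv_segments = data.table::data.table(chrom = "chrS", start = 2e4L,
                                          end = 4e4L, copy_number = 6),
    masked_intervals = data.table::data.table(chrom = "chrS",
                                              start = 5e4L, end = 6e4L))
  exp <- simulate_mnase_experiment(spec, n_low = 3e3, n_high = 3e3,
                                   seed = 81L)
  out <- tempfile()
  paths <- emit_truth_bundle(exp, out)
  expect_true(all(file.exists(paths)))
  g <- Biostrings::readDNAStringSet(paths["genome"])
  expect_equal(unname(Biostrings::width(g)), 1e5L)
  man <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
  expect_equal(man$n_hyper, 2L)
  expect_equal(nrow(man$hyper_sites), 2L)
  expect_equal(man$cnv_segments$copy_number, 6)
  map <- read_bedgraph(paths["mappability"], c(chrS = 1e5L), fill = 1)
  expect_equal(unique(map$signal$chrS[50001:60000]), 0)
  expect_equal(unique(map$signal$chrS[1:50000]), 1)
  fr <- read_fragments(paths["fragments_low"])
  expect_equal(nrow(fr), 3e3)
  expect_equal(unique(fr$condition), "low")
})
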