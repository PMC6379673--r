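# profiles: fragment GC, dinucleotide profiles, periodicity, aggregates

test_that("fragment_gc computes per-fragment and genome GC", {
  genome <- Biostrings::DNAStringSet(c(c1 = "GGCCAATTGGCC"))
  fr <- data.table::data.table(chrom = "c1",
                               start = c(0L, 4L), end = c(4L, 8L))
  r <- fragment_gc(fr, genome)
  expect_equal(r$gc, c(1, 0))
  expect_equal(unname(r$genome_gc), 8 / 12)
  bad <- data.table::data.table(chrom = "c1", start = 8L, end = 20L)
  expect_error(fragment_gc(bad, genome), "beyond")
})

test_that("fragment GC reflects the condition asymmetry of the generator", {
  exp <- small_experiment(len = 3e5, n = 3e4, n_hyper = 0L, seed = 61L)
  glow <- fragment_gc(exp$fragments[condition == "low"], exp$genome)
  ghigh <- fragment_gc(exp$fragments[condition == "high"], exp$genome)
  # low tracks the genome mean within half a percentage point of GC;
  # high exceeds it (AT-rich nucleosomes lost under full digestion)
  expect_lt(abs(glow$mean_gc - glow$genome_gc), 0.005)
  expect_gt(ghigh$mean_gc, glow$mean_gc + 0.005)
})

test_that("dinuc_profile matches closed forms on degenerate genomes", {
  gall <- Biostrings::DNAStringSet(c(c1 = strrep("G", 3000)))
  fr <- data.table::data.table(chrom = "c1",
                               start = seq(800L, 1800L, by = 100L))
  fr[, end := start + 147L]
  pr <- dinuc_profile(fr, gall, "GC", flank = 100L)
  expect_equal(pr$frequency, rep(1, 200))
  expect_equal(pr$offsets, -100:99)

  # i.i.d. genome at GC 0.5: set frequency (p_G + p_C)^2 = 0.25
  giid <- make_iid_genome(c(c1 = 60000L), gc = 0.5, seed = 62)
  set.seed(63)
  fr2 <- data.table::data.table(chrom = "c1",
                                start = sample(1000:58000, 3000, TRUE))
  fr2[, end := start + 147L]
  pr2 <- dinuc_profile(fr2, giid, "GC", flank = 100L)
  expect_equal(mean(pr2$frequency), 0.25, tolerance = 0.01)
  expect_lt(max(abs(pr2$frequency - 0.25)), 0.05)
  # GC-set + AT-set + mixed = 1 on N-free genomes
  pr2at <- dinuc_profile(fr2, giid, "AT", flank = 100L)
  mixed <- 1 - pr2$frequency - pr2at$frequency
  expect_true(all(mixed > 0 & mixed < 1))
  expect_equal(mean(mixed), 0.5, tolerance = 0.01)
})

test_that("random_fragment_control is exact-length, seeded and flat", {
  g <- make_iid_genome(c(c1 = 30000L), 0.5, seed = 64)
  fr <- random_fragment_control(g, 10, 147L, seed = 65)
  expect_equal(nrow(fr), 10L)
  expect_true(all(fr$end - fr$start == 147L))
  fr2 <- random_fragment_control(g, 10, 147L, seed = 65)
  expect_equal(fr, fr2)
  # profile of the control on an i.i.d. genome is flat within a
  # per-offset binomial band
  frn <- random_fragment_control(g, 2000, 147L, seed = 66)
  pr <- dinuc_profile(frn, g, "GC", flank = 80L)
  band <- 4 * sqrt(0.25 * 0.75 / 2000)
  expect_lt(mean(abs(pr$frequency - mean(pr$frequency)) > band), 0.01)
})

test_that("periodicity_score separates sinusoid, constant and noise", {
  mk <- function(freqs) {
    structure(list(offsets = -300:299, frequency = freqs, set = "GC",
                   anchor = "midpoint", n_fragments = 1000L,
                   n_skipped = 0L), class = "DinucProfile")
  }
  sine <- mk(0.25 + 0.05 * cos(2 * pi * (-300:299) / 10))
  expect_gt(periodicity_score(sine, 10), 0.9)
  expect_equal(periodicity_score(mk(rep(0.3, 600)), 10), 0)
  set.seed(67)
  noise <- mk(0.25 + rnorm(600, 0, 0.01))
  expect_gt(periodicity_score(sine, 10) /
              max(periodicity_score(noise, 10), 1e-6), 10)
  expect_error(periodicity_score(sine, 200), "period")
})

test_that("planted 10-bp phasing shows up in dyad-anchored profiles", {
  spec <- genome_spec(chromosomes = c(chrS = 3e5), n_hyper = 0L,
                      periodic_positioning = TRUE, seed = 68L)
  gen <- generate_genome(spec)
  dy <- gen$dyads$chrS
  fr <- data.table::data.table(chrom = "chrS", start = dy - 73L,
                               end = dy + 74L)
  pr <- dinuc_profile(fr, gen$genome, "GC", flank = 100L)
  # autocorrelation of the footprint profile peaks at lag 10
  x <- pr$frequency[pr$offsets >= -73 & pr$offsets <= 73]
  ac <- stats::acf(x, lag.max = 15, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[5:15]) + 4L, 10L)
  expect_gt(periodicity_score(pr, 10), 0.5)
})

test_that("aggregate_profile averages, reverses strands and sorts heatmaps", {
  tr <- make_track(list(c1 = rep(2, 5000)))
  fe <- data.table::data.table(chrom = "c1", start = c(1000L, 3000L),
                               end = c(1100L, 3100L))
  pr <- aggregate_profile(tr, fe, flank = 200L)
  expect_equal(as.numeric(pr), rep(2, 401))

  x <- numeric(5000); x[2000:2100] <- 1:101
  tr2 <- make_track(list(c1 = x))
  one <- data.table::data.table(chrom = "c1", start = 2000L, end = 2100L)
  pr2 <- aggregate_profile(tr2, one, flank = 50L)
  expect_equal(as.numeric(pr2), x[2001:2101]) # single feature = slice
  # minus strand reversed
  onem <- data.table::data.table(chrom = "c1", start = 2000L,
                                 end = 2100L, strand = "-")
  expect_equal(as.numeric(aggregate_profile(tr2, onem, flank = 50L)),
               rev(x[2001:2101]))

  hm <- aggregate_profile(tr2, rbind(one, one, one), flank = 10L,
                          mode = "heatmap", sort_by = c(1, 3, 2))
  expect_equal(nrow(hm), 3L)
  expect_error(aggregate_profile(tr, fe[0]), "empty")
  # clipped features dropped and counted
  edge <- data.table::data.table(chrom = "c1", start = 0L, end = 10L)
  expect_error(aggregate_profile(tr, edge, flank = 200L), "clipped")
  both <- rbind(fe, edge)
  pr3 <- aggregate_profile(tr, both, flank = 200L)
  expect_equal(attr(pr3, "n_dropped"), 1L)
})

test_that("hyper sites are enriched in low and depleted in high tracks", {
  exp <- small_experiment(len = 4e5, n = 1.2e5, n_hyper = 5L, seed = 69L)
  cs <- exp$spec$chromosomes
  mk <- function(cond) {
    build_occupancy(size_select(exp$fragments[condition == cond], "mono"),
                    cs, 70L)
  }
  lo <- mk("low"); hi <- mk("high")
  plo <- aggregate_profile(lo, exp$hyper_sites, flank = 800L)
  phi <- aggregate_profile(hi, exp$hyper_sites, flank = 800L)
  centre <- 740:862   # +-60 bp around the planted dyad
  flankidx <- c(1:300, 1300:1601)
  # low condition: centred fragment peak clearly exceeds the flank mean
  expect_gt(max(plo[centre]), 1.5 * mean(plo[flankidx]))
  # high condition: centred dip (fragile nucleosome lost)
  expect_lt(mean(phi[centre]) / mean(phi[flankidx]), 0.7)
  # the low/high contrast is concentrated at the site
  ctr_ratio <- mean(plo[centre]) / mean(phi[centre])
  fl_ratio <- mean(plo[flankidx]) / mean(phi[flankidx])
  expect_gt(ctr_ratio, 2 * fl_ratio)
})
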