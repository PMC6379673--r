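# fragment_processing: IO, size selection, clonal filter, occupancy,
# normalization, nucleosome calling

test_that("read_fragments parses BED/BEDPE and rejects malformed records", {
  tf <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t250", "chr1\t500\t700"), tf)
  fr <- read_fragments(tf)
  expect_equal(fr$end - fr$start, c(150L, 200L))
  tf4 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t250\tlow", "chr1\t500\t700\tlow"), tf4)
  expect_equal(read_fragments(tf4)$condition, c("low", "low"))

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_fragments(empty)), 0L)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t250", "chr1\t300\t200"), bad)
  expect_error(read_fragments(bad), "line 2")

  pe <- tempfile(fileext = ".bedpe")
  writeLines("chr1\t100\t150\tchr1\t260\t310\tfragA", pe)
  fp <- read_fragments(pe, "BEDPE")
  expect_equal(fp$start, 100L)
  expect_equal(fp$end, 310L)
})

test_that("size_select applies inclusive gates and is idempotent", {
  fr <- data.table::data.table(
    chrom = "c", start = 0L,
    end = c(139L, 140L, 200L, 201L, 249L, 250L, 500L, 501L, 210L))
  mono <- size_select(fr, "mono")
  expect_equal(sort(mono$end), c(140L, 200L))
  di <- size_select(fr, "di")
  expect_equal(sort(di$end), c(250L, 500L))
  expect_equal(size_select(mono, "mono"), mono)
  expect_equal(nrow(size_select(fr[end == 210L], "mono")), 0L)
})

test_that("dedup_clonal caps multiplicity at the Poisson-tail oracle", {
  # duplicate-free background
  set.seed(2)
  bg <- data.table::data.table(chrom = "c",
                               start = seq(0L, by = 300L,
                                           length.out = 1000L))
  bg[, end := start + 150L]
  expect_equal(nrow(dedup_clonal(bg)), 1000L)

  # one coordinate duplicated 1000x on that background
  clonal <- rbind(bg, bg[rep(1L, 1000L)])
  out <- dedup_clonal(clonal, 1e-2)
  # oracle: lambda = 2000/1000; smallest k with P(X >= k) < 1e-2 by
  # direct summation of the Poisson density
  lambda <- nrow(clonal) / 1000
  k <- 1L
  tail_ge <- function(k) 1 - sum(dpois(0:(k - 1L), lambda))
  while (tail_ge(k) >= 1e-2) k <- k + 1L
  expect_equal(nrow(out), 999L + k)
  expect_equal(max(out[, .N, by = start]$N), k)

  # degenerate p_threshold: floor the cap at one copy
  one <- dedup_clonal(clonal, 0.9999999)
  expect_equal(max(one[, .N, by = start]$N), 1L)
})

test_that("build_occupancy extends around midpoints and conserves mass", {
  cs <- c(c1 = 1000L)
  fr <- data.table::data.table(chrom = "c1", start = 100L, end = 250L)
  tr <- build_occupancy(fr, cs, 70L)
  # midpoint 175 -> covers [140, 210)
  expect_equal(which(tr$signal$c1 > 0), 141:210)
  expect_equal(sum(tr$signal$c1), 70)

  di <- data.table::data.table(chrom = "c1", start = 0L, end = 340L)
  tr2 <- build_occupancy(di, cs, 150L)
  # midpoint 170 -> covers [95, 245)
  expect_equal(which(tr2$signal$c1 > 0), 96:245)

  set.seed(3)
  n <- 200L
  fr3 <- data.table::data.table(chrom = "c1",
                                start = sample(100:700, n, TRUE))
  fr3[, end := start + 150L]
  tr3 <- build_occupancy(fr3, cs, 70L)
  expect_equal(sum(tr3$signal$c1), 70 * n)

  # clipping warns and clips
  edge <- data.table::data.table(chrom = "c1", start = 0L, end = 20L)
  expect_warning(tre <- build_occupancy(edge, cs, 70L), "clipped")
  expect_lt(sum(tre$signal$c1), 70)
})

test_that("depth_normalize scales exactly and refuses reapplication", {
  cs <- c(c1 = 500L)
  fr <- data.table::data.table(chrom = "c1", start = c(100L, 200L))
  fr[, end := start + 150L]
  tr <- build_occupancy(fr, cs, 70L)
  same <- depth_normalize(tr, 2)
  expect_equal(same$signal$c1, tr$signal$c1)
  tr2 <- depth_normalize(tr, 400)
  expect_equal(tr2$signal$c1, tr$signal$c1 * 200)
  expect_equal(tr2$normalization, "depth")
  expect_error(depth_normalize(tr2, 400), "already applied")
})

test_that("cnv_correct divides by copy/ploidy inside segments only", {
  tr <- make_track(list(c1 = rep(6, 100)), 10)
  seg <- data.table::data.table(chrom = "c1", start = 20L, end = 40L,
                                copy_number = 6)
  out <- cnv_correct(tr, seg, ploidy = 3)
  expect_equal(out$signal$c1[21:40], rep(3, 20))   # halved
  expect_equal(out$signal$c1[c(1:20, 41:100)], rep(6, 80)) # untouched
  tr2 <- make_track(list(c1 = rep(6, 100)), 10)
  neutral <- cnv_correct(tr2, data.table::data.table(
    chrom = "c1", start = 0L, end = 100L, copy_number = 3), 3)
  expect_equal(neutral$signal$c1, rep(6, 100))
  expect_error(cnv_correct(make_track(list(c1 = rep(1, 10))),
                           data.table::data.table(chrom = "c1",
                                                  start = 0L, end = 5L,
                                                  copy_number = 0)),
               "> 0")
})

test_that("call_nucleosomes finds separated smoothed maxima", {
  x <- numeric(2000)
  x[301:370] <- 5                      # rectangular peak width 70
  x[1001:1070] <- 3
  calls <- call_nucleosomes(make_track(list(c1 = x)), min_distance = 150)
  expect_equal(nrow(calls), 2L)
  # smoothed plateau of a symmetric rectangle is centred on the peak
  expect_lt(abs(calls$pos[1] - 335), 5)
  expect_lt(abs(calls$pos[2] - 1035), 5)
  # two peaks 100 bp apart merge under the 150-bp separation rule
  y <- numeric(1000)
  y[301:340] <- 5
  y[431:470] <- 4
  expect_equal(nrow(call_nucleosomes(make_track(list(c1 = y)),
                                     min_distance = 150)), 1L)
  expect_equal(nrow(call_nucleosomes(make_track(list(c1 = numeric(500))))),
               0L)
})

test_that("called dyads recover planted dyads in the low condition", {
  exp <- small_experiment(len = 3e5, n = 6e4, n_hyper = 0L, seed = 21L)
  fr <- exp$fragments[condition == "low"]
  tr <- build_occupancy(size_select(fr, "mono"), exp$spec$chromosomes, 70L)
  calls <- call_nucleosomes(tr, min_distance = 150L,
                            min_height = mean(tr$signal$chrS) / 4)
  dy <- exp$dyads$chrS
  hit <- vapply(dy, function(d) any(abs(calls$pos - d) <= 20L), logical(1))
  expect_gt(mean(hit), 0.9)
})
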