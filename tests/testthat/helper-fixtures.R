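# shared fixtures and independent oracles for the test-suite

# small i.i.d. genome at a given GC fraction
make_iid_genome <- function(lens = c(chrA = 20000L), gc = 0.5, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(lens, function(n) {
    s <- ifelse(runif(n) < gc, sample(c("G", "C"), n, TRUE),
                sample(c("A", "T"), n, TRUE))
    paste(s, collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(lens)
  g
}

# track with given per-chromosome signal vectors
make_track <- function(signal, n_fragments = NA_real_,
                       normalization = character(), extend_to = NULL) {
  tr <- structure(list(signal = signal, n_fragments_used = n_fragments,
                       normalization = normalization),
                  class = "OccupancyTrack")
  if (!is.null(extend_to)) tr$extend_to <- extend_to
  tr
}

# closed-form OLS oracle via normal equations (independent of lm)
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- 2L
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  s2 <- ss_res / (n - p)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  h <- diag(H)
  cooks <- as.vector(res)^2 * h / (p * s2 * (1 - h)^2)
  list(intercept = beta[1], slope = beta[2], r2 = r2, adj_r2 = adj,
       cooks = cooks)
}

# BH step-up reference (independent path: stats::p.adjust)
bh_reference <- function(p) stats::p.adjust(p, method = "BH")

# digestion of the default 50-nucleosome array, small fragment counts
quick_profile <- function(scenario, n_cuts, n_frag = 2e4, seed = 1) {
  tpl <- build_template()
  run_digestion(apply_scenario(tpl, scenario),
                digest_params(n_cuts, n_frag, seed = seed))
}

# tiny synthetic experiment shared by pipeline-level tests
small_experiment <- function(len = 4e5, n = 8e4, n_hyper = 4L, seed = 11L,
                             ...) {
  spec <- genome_spec(chromosomes = c(chrS = len), n_hyper = n_hyper,
                      seed = seed, ...)
  simulate_mnase_experiment(spec, n_low = n, n_high = n, seed = seed)
}
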