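#' Digestion parameters
#'
#' @param n_cuts double-strand cutting events per template instance
#'   (20 for the low-MNase condition, 70 for high).
#' @param target_fragments kept fragments to accumulate (the reference
#'   simulations collect 1e6).
#' @param keep_len fragment length retained, bp (exact match).
#' @param trim bp trimmed from both fragment ends before coverage.
#' @param seed optional RNG seed recorded in the output.
#' @param max_templates iteration cap on template instances.
#' @return a `DigestParams` list.
#' @export
digest_params <- function(n_cuts, target_fragments = 1e6, keep_len = 180L,
                          trim = 30L, seed = NULL, max_templates = 1e7) {
  stopifnot(n_cuts >= 2, target_fragments >= 1, keep_len > 2 * trim, trim >= 0)
  structure(list(n_cuts = as.integer(n_cuts),
                 target_fragments = target_fragments,
                 keep_len = as.integer(keep_len), trim = as.integer(trim),
                 seed = seed, max_templates = max_templates),
            class = "DigestParams")
}

#' Run a stochastic MNase digestion of a nucleosome array
#'
#' Repeatedly digests template instances: each instance receives
#' `params$n_cuts` cutting events (weighted sampling of cleavage sites
#' without replacement), neighbouring cuts are assembled into fragments, and
#' fragments of exactly `params$keep_len` bp are kept. Iteration continues
#' until `params$target_fragments` fragments have been accumulated. Kept
#' fragments are trimmed by `params$trim` bp on both sides (centring the
#' nucleosome) and summed into a per-base coverage profile.
#'
#' @param template an `ArrayTemplate` with scenario weights applied.
#' @param params a [digest_params()] object.
#' @param condition label stored in the profile ("low"/"high"/other).
#' @return a `CoverageProfile`: list with `values` (per-base counts over the
#'   template), `n_fragments`, `templates` used, `condition`, `keep_len`,
#'   `trim` and `seed`.
#' @examples
#' tpl <- apply_scenario(build_template(), "uniform")
#' prof <- run_digestion(tpl, digest_params(70, 1000, seed = 1), "high")
#' sum(prof$values) == 1000 * 120
#' @export
run_digestion <- function(template, params, condition = "unlabelled") {
  stopifnot(inherits(template, "ArrayTemplate"), inherits(params, "DigestParams"))
  if (params$n_cuts > nrow(template$sites)) {
    stop("n_cuts exceeds the number of cleavage sites")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_digest_coverage(template$sites$position, template$sites$weight,
                             params$n_cuts, params$keep_len, params$trim,
                             params$target_fragments, params$max_templates,
                             template$length)
  if (res$n_fragments < params$target_fragments) {
    stop(sprintf(paste0("digestion exhausted the iteration cap (%g templates)",
                        " with %g/%g fragments of %d bp"),
                 params$max_templates, res$n_fragments,
                 params$target_fragments, params$keep_len))
  }
  structure(list(values = res$values, n_fragments = res$n_fragments,
                 templates = res$templates, condition = condition,
                 keep_len = params$keep_len, trim = params$trim,
                 seed = params$seed),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile (%s): %g fragments over %d bp, mass %g\n",
              x$condition, x$n_fragments, length(x$values), sum(x$values)))
  invisible(x)
}

#' Per-nucleosome coverage summary of an array digestion
#'
#' Averages a coverage profile over each nucleosome footprint. Footprint k
#' is the trimmed mono-nucleosome fragment between linker sites k and k+1 on
#' the unshifted grid, i.e. `[(k-1)*repeat_len + trim, k*repeat_len - trim)`.
#'
#' @param profile a `CoverageProfile`.
#' @param template the `ArrayTemplate` the profile was generated from.
#' @return numeric vector of length `n_nucleosomes` with mean per-base
#'   coverage per nucleosome.
#' @export
per_nucleosome_coverage <- function(profile, template) {
  stopifnot(inherits(profile, "CoverageProfile"),
            inherits(template, "ArrayTemplate"))
  rep_len <- template$nuc_len + template$linker_len
  trim <- profile$trim
  vapply(seq_len(template$n_nucleosomes), function(k) {
    s <- (k - 1L) * rep_len + trim     # 0-based start
    e <- k * rep_len - trim            # 0-based end (exclusive)
    mean(profile$values[(s + 1L):e])
  }, numeric(1))
}

#' Signed log2 ratio of two digestion conditions
#'
#' Computes `log2((low + eps) / (high + eps))` after scaling both profiles
#' to equal total mass, per base or averaged per nucleosome footprint.
#' Positive values mean enrichment in the low condition.
#'
#' @param low,high `CoverageProfile`s over the same template.
#' @param per "base" or "nucleosome".
#' @param template required for `per = "nucleosome"`.
#' @param eps pseudo-count added before scaling.
#' @return numeric vector of log2 ratios.
#' @export
condition_log_ratio <- function(low, high, per = c("base", "nucleosome"),
                                template = NULL, eps = 1) {
  per <- match.arg(per)
  if (length(low$values) != length(high$values)) {
    stop("profiles have different template lengths")
  }
  if (sum(low$values) == 0 || sum(high$values) == 0) {
    stop("empty coverage profile")
  }
  l <- low$values + eps
  h <- high$values + eps
  target <- (sum(l) + sum(h)) / 2
  l <- l * (target / sum(l))
  h <- h * (target / sum(h))
  lr <- log2(l / h)
  if (per == "base") return(lr)
  stopifnot(inherits(template, "ArrayTemplate"))
  rep_len <- template$nuc_len + template$linker_len
  trim <- low$trim
  vapply(seq_len(template$n_nucleosomes), function(k) {
    s <- (k - 1L) * rep_len + trim
    e <- k * rep_len - trim
    mean(lr[(s + 1L):e])
  }, numeric(1))
}
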