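#' Build a nucleosome-array template with candidate MNase cleavage sites
#'
#' Constructs the in silico nucleosome array used by the digestion
#' simulator: `n_nucleosomes` nucleosomes of `nuc_len` bp separated by
#' `linker_len` bp linkers on one DNA strand. One candidate cleavage site is
#' assigned to each linker and each nucleosome, laid out on a base grid at
#' multiples of `(nuc_len + linker_len) / 2`. Even grid indices are linker
#' sites, odd indices are nucleosome sites, and every odd-numbered nucleosome
#' site (the 1st, 3rd, ...) is displaced by `-shift` bp so that consecutive
#' nucleosome sites alternate between `repeat_len - shift` and
#' `repeat_len + shift` spacings while linker sites stay exactly
#' `repeat_len` apart. With the defaults (50 nucleosomes, 150/30 bp,
#' shift 5) the site index starts 0, 85, 180, 270, ... and ends 8910, 9000.
#'
#' @param n_nucleosomes number of nucleosomes in the array (>= 1).
#' @param nuc_len nucleosomal DNA length in bp.
#' @param linker_len linker DNA length in bp.
#' @param shift displacement in bp applied to every second nucleosome site.
#' @return An object of class `ArrayTemplate`: a list with `length`,
#'   `n_nucleosomes`, `nuc_len`, `linker_len`, `shift` and `sites`, a
#'   `data.table` with columns `position`, `kind` ("linker"/"nuc") and
#'   `weight` (all 1 until a scenario is applied).
#' @examples
#' tpl <- build_template(50, 150, 30, 5)
#' nrow(tpl$sites)            # 101 candidate cleavage sites
#' head(tpl$sites$position)   # 0 85 180 270 360 445
#' @export
build_template <- function(n_nucleosomes = 50L, nuc_len = 150L,
                           linker_len = 30L, shift = 5L) {
  stopifnot(n_nucleosomes >= 1L, nuc_len > 0L, linker_len > 0L, shift >= 0L)
  spacing <- (nuc_len + linker_len) / 2
  if (spacing != floor(spacing)) {
    stop("grid spacing (nuc_len + linker_len)/2 is not an integral number of bp")
  }
  spacing <- as.integer(spacing)
  if (shift >= spacing) stop("shift makes site positions non-monotone")
  idx <- 0:(2L * n_nucleosomes)
  pos <- idx * spacing
  kind <- ifelse(idx %% 2L == 0L, "linker", "nuc")
  nuc_no <- (idx + 1L) %/% 2L          # 1-based nucleosome number, 0 for linkers
  shifted <- kind == "nuc" & nuc_no %% 2L == 1L
  pos[shifted] <- pos[shifted] - shift
  if (any(diff(pos) <= 0)) stop("shift makes site positions non-monotone")
  sites <- data.table(position = as.integer(pos), kind = kind, weight = 1)
  structure(list(length = as.integer(2L * n_nucleosomes * spacing),
                 n_nucleosomes = as.integer(n_nucleosomes),
                 nuc_len = as.integer(nuc_len),
                 linker_len = as.integer(linker_len),
                 shift = as.integer(shift),
                 sites = sites),
            class = "ArrayTemplate")
}

#' @export
print.ArrayTemplate <- function(x, ...) {
  cat(sprintf("ArrayTemplate: %d nucleosomes (%d bp) / %d bp linkers, %d bp, %d sites\n",
              x$n_nucleosomes, x$nuc_len, x$linker_len, x$length, nrow(x$sites)))
  invisible(x)
}

# 1-based indices of the k-th linker / nucleosome site in template$sites
linker_site_idx <- function(template, k) {
  stopifnot(all(k >= 1L), all(k <= template$n_nucleosomes + 1L))
  2L * k - 1L
}
nuc_site_idx <- function(template, k) {
  stopifnot(all(k >= 1L), all(k <= template$n_nucleosomes))
  2L * k
}

#' Named digestion scenarios for the array simulator
#'
#' Each scenario is expressed as weight multipliers on site ranges, applied
#' on top of the base cleavage probabilities p_cut(linker) = 10 * p_cut(nuc)
#' (linker weight 10, nucleosome weight 1):
#'
#' * `uniform`: no modification; equally accessible linkers throughout.
#' * `compact_center`: a compacted chromatin domain; the linkers flanking the
#'   central 25 nucleosomes get 0.8 * p_cut(linker) (weight 8).
#' * `at_rich_center`: MNase-sensitive nucleosomes in an AT-rich central
#'   stretch; the central 25 nucleosome sites get 2 * p_cut(nuc) (weight 2).
#' * `fragile_site`: one fragile nucleosome at the array centre with
#'   4 * p_cut(nuc) (weight 4) flanked by two hyper-accessible linkers at
#'   1.2 * p_cut(linker) (weight 12).
#'
#' @param name scenario name.
#' @param n_nucleosomes array size the ranges refer to.
#' @return list of multiplier specs `list(kind =, index =, mult =)`.
#' @export
scenario_weights <- function(name = c("uniform", "compact_center",
                                      "at_rich_center", "fragile_site"),
                             n_nucleosomes = 50L) {
  name <- match.arg(name)
  n <- as.integer(n_nucleosomes)
  central25 <- function() {
    lo <- (n - 25L) %/% 2L + 1L
    seq.int(lo, lo + 24L)
  }
  switch(name,
    uniform = list(),
    compact_center = {
      nucs <- central25()
      list(list(kind = "linker", index = c(nucs, max(nucs) + 1L), mult = 0.8))
    },
    at_rich_center = list(list(kind = "nuc", index = central25(), mult = 2)),
    fragile_site = {
      k <- (n + 1L) %/% 2L
      list(list(kind = "nuc", index = k, mult = 4),
           list(kind = "linker", index = c(k, k + 1L), mult = 1.2))
    })
}

#' Apply a digestion scenario to a template
#'
#' Sets the base cleavage weights p_cut(linker) = 10, p_cut(nuc) = 1 and then
#' multiplies site weights by the scenario's multipliers. A scenario is
#' either a name understood by [scenario_weights()] or a list of specs
#' `list(kind = "linker"|"nuc", index = <nucleosome/linker numbers>,
#' mult = <positive multiplier>)`, where linker k and k+1 flank nucleosome k.
#'
#' @param template an [build_template()] result.
#' @param scenario scenario name or list of multiplier specs.
#' @param p_linker,p_nuc base weights of linker and nucleosome sites.
#' @return a new `ArrayTemplate` with scenario weights applied.
#' @examples
#' tpl <- apply_scenario(build_template(), "fragile_site")
#' tpl$sites[weight != c(10, 1)[1 + (kind == "nuc")]]
#' @export
apply_scenario <- function(template, scenario = "uniform",
                           p_linker = 10, p_nuc = 1) {
  stopifnot(inherits(template, "ArrayTemplate"))
  if (is.character(scenario)) {
    scenario <- scenario_weights(scenario, template$n_nucleosomes)
  }
  sites <- copy(template$sites)
  sites[, weight := ifelse(kind == "linker", p_linker, p_nuc)]
  for (sp in scenario) {
    if (!all(c("kind", "index", "mult") %in% names(sp))) {
      stop("scenario spec needs fields kind, index, mult")
    }
    if (any(sp$mult <= 0)) stop("scenario multiplier must be > 0")
    idx <- if (sp$kind == "linker") {
      linker_site_idx(template, as.integer(sp$index))
    } else if (sp$kind == "nuc") {
      nuc_site_idx(template, as.integer(sp$index))
    } else {
      stop("scenario kind must be 'linker' or 'nuc'")
    }
    sites[idx, weight := weight * sp$mult]
  }
  out <- template
  out$sites <- sites
  out
}

#' Draw cut positions from a template
#'
#' Simulates `n_cuts` double-strand cutting events on one template instance:
#' site positions are drawn without replacement by successive weighted draws
#' (each draw proportional to the remaining site weights) and returned sorted
#' in ascending order.
#'
#' @param template an `ArrayTemplate` (weights set, e.g. by
#'   [apply_scenario()]).
#' @param n_cuts number of cutting events, at most the number of sites.
#' @return sorted integer vector of cut positions.
#' @export
sample_cuts <- function(template, n_cuts) {
  stopifnot(inherits(template, "ArrayTemplate"))
  m <- nrow(template$sites)
  if (n_cuts > m) stop("n_cuts exceeds the number of cleavage sites")
  w <- template$sites$weight
  picked <- integer(n_cuts)
  for (j in seq_len(n_cuts)) {
    i <- sample.int(m, 1L, prob = w)
    picked[j] <- i
    w[i] <- 0
  }
  sort(template$sites$position[picked])
}

#' Assemble fragments from sorted cut positions
#'
#' Neighbouring cut positions are assembled into fragments and only those of
#' exactly `keep_len` bp are returned (they represent the simulated
#' mono-nucleosomes when `keep_len` equals the nucleosome repeat length).
#'
#' @param positions sorted cut positions (>= 2).
#' @param keep_len retained fragment length in bp (exact match).
#' @return a two-column matrix of (start, end) pairs; zero rows if no
#'   fragment matches.
#' @examples
#' fragments_from_cuts(c(0, 85, 180, 360), 180)  # one fragment: 180-360
#' @export
fragments_from_cuts <- function(positions, keep_len = 180L) {
  if (length(positions) < 2L) stop("need at least two cut positions")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("cut positions must be strictly increasing")
  }
  gaps <- diff(positions)
  keep <- which(gaps == keep_len)
  cbind(start = positions[keep], end = positions[keep + 1L])
}
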