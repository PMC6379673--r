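#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.integer(dt$size), dt$chrom)
}

# internal constructor for per-chromosome 1-bp signal containers
new_track <- function(signal, n_fragments_used = NA_real_,
                      normalization = character()) {
  stopifnot(is.list(signal), !is.null(names(signal)))
  structure(list(signal = signal, n_fragments_used = n_fragments_used,
                 normalization = normalization),
            class = "OccupancyTrack")
}

#' @export
print.OccupancyTrack <- function(x, ...) {
  cat(sprintf("OccupancyTrack: %d chromosome(s), %g fragments used\n",
              length(x$signal), x$n_fragments_used))
  if (length(x$normalization)) {
    cat("  normalization:", paste(x$normalization, collapse = " -> "), "\n")
  }
  invisible(x)
}

track_chrom_sizes <- function(track) {
  vapply(track$signal, length, integer(1))
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal value are collapsed; zero-valued runs are omitted (bedGraph
#' convention). Coordinates are 0-based half-open.
#'
#' @param track an `OccupancyTrack`.
#' @param path output file.
#' @param name track name written in the header line.
#' @param provenance optional named list echoed as `#` comment lines.
#' @export
write_bedgraph <- function(track, path, name = "track", provenance = NULL) {
  header <- c(
    if (!is.null(provenance)) {
      vapply(names(provenance), function(k) {
        sprintf("# %s=%s", k, format(provenance[[k]]))
      }, character(1))
    },
    sprintf("track type=bedGraph name=%s", name))
  writeLines(header, path)
  body <- rbindlist(lapply(names(track$signal), function(chrom) {
    r <- rle(track$signal[[chrom]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table(chrom = chrom, start = s[keep], end = e[keep],
               value = signif(r$values[keep], 8))
  }))
  if (nrow(body)) {
    fwrite(body, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read a bedGraph (or 4-column bed+score) file into a track
#'
#' @param path bedGraph file; `track` and `#` lines are skipped.
#' @param chrom_sizes named vector of chromosome lengths; positions not
#'   covered by a record are set to `fill`.
#' @param fill value for uncovered positions (default 0; use 1 for
#'   mappability tracks where absence means fully mappable).
#' @return an `OccupancyTrack` (n_fragments_used is NA).
#' @export
read_bedgraph <- function(path, chrom_sizes, fill = 0) {
  lines <- readLines(path)
  keep <- !grepl("^(track|#|browser)", lines) & nzchar(lines)
  dt <- if (any(keep)) {
    fread(text = lines[keep], header = FALSE,
          col.names = c("chrom", "start", "end", "value"))
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  }
  sig <- lapply(names(chrom_sizes), function(ch) {
    v <- rep(fill, chrom_sizes[[ch]])
    sub <- dt[chrom == ch]
    if (nrow(sub)) {
      if (any(sub$end > chrom_sizes[[ch]] | sub$start < 0)) {
        stop("bedGraph record outside chromosome bounds on ", ch)
      }
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
      }
    }
    v
  })
  names(sig) <- names(chrom_sizes)
  new_track(sig)
}

#' Write a per-base track as fixedStep wiggle
#'
#' @param track an `OccupancyTrack`.
#' @param path output file.
#' @export
write_wiggle <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$signal)) {
    cat(sprintf("fixedStep chrom=%s start=1 step=1\n", chrom), file = con)
    writeLines(format(signif(track$signal[[chrom]], 6), trim = TRUE), con)
  }
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Columns beyond the first three are kept when present
#' (name, score, strand).
#'
#' @param path BED file (0-based half-open).
#' @return `data.table` with at least chrom/start/end.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  if (nrow(dt) && any(dt$end <= dt$start)) {
    stop("BED interval with end <= start at line ",
         which(dt$end <= dt$start)[1])
  }
  dt
}
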