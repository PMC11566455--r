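#' Build a sliding-window genome layout
#'
#' Tiles each chromosome with overlapping windows of `window_size` bp starting
#' every `step` bp (default half a window, so each position is covered by two
#' windows). All coordinates are 0-based half-open. Windows at a chromosome end
#' are truncated to the chromosome length; downstream masking treats truncated
#' windows as unusable because their read counts are not comparable to full
#' windows.
#'
#' @param chrom_lengths Named numeric vector: chromosome name -> length in bp.
#' @param window_size Window width in bp (default 800).
#' @param step Distance between successive window starts in bp
#'   (default `window_size / 2`).
#' @param placed_chroms Optional character vector of placed-chromosome names.
#'   When supplied, chromosomes not in this whitelist (unplaced scaffolds) are
#'   excluded from the layout.
#' @return An object of class `genome_layout`: a list with `chroms` (named
#'   lengths), `window_size`, `step`, and `windows`, a `data.table` with
#'   columns `chrom`, `start`, `end` and integer key `widx` (1-based row id).
#' @export
#' @examples
#' gl <- genome_layout(c(chr1 = 4000), window_size = 800)
#' gl$windows
genome_layout <- function(chrom_lengths, window_size = 800L,
                          step = window_size %/% 2L, placed_chroms = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector (chromosome name -> bp)")
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size <= 0L || step <= 0L || step > window_size)
    stop("need 0 < step <= window_size")
  if (!is.null(placed_chroms)) {
    chrom_lengths <- chrom_lengths[names(chrom_lengths) %in% placed_chroms]
    if (!length(chrom_lengths)) stop("no chromosomes left after placed-chromosome filter")
  }
  win <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, len - 1L, by = step)
    data.table(chrom = ch, start = starts, end = pmin(starts + window_size, len))
  }))
  win[, widx := seq_len(.N)]
  structure(
    list(chroms = chrom_lengths, window_size = window_size, step = step,
         windows = win),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %d windows (w=%d bp, step=%d bp)\n",
              length(x$chroms), nrow(x$windows), x$window_size, x$step))
  invisible(x)
}

n_windows <- function(layout) nrow(layout$windows)
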