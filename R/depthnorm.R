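#' Count reads per window (raw depth layer)
#'
#' Assigns each read to every window containing its midpoint
#' (`start + length %/% 2`, 0-based half-open: a midpoint exactly at a window
#' start belongs to that window). With overlapping windows a read is counted
#' once per window layer it touches, which keeps per-window counts Poisson
#' under a uniform-start read model.
#'
#' @param reads Named list of per-sample read placements, each a data.frame
#'   with columns `chrom`, `start`, `length` (0-based starts).
#' @param layout A [genome_layout()].
#' @return A `depth_matrix` object: list with `layout`, `samples`, `raw`
#'   (windows x samples integer matrix) and `dropped` (named count of reads on
#'   chromosomes absent from the layout, reported per sample).
#' @export
compute_window_depth <- function(reads, layout) {
  stopifnot(inherits(layout, "genome_layout"), is.list(reads))
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be a named list (one element per sample)")
  win <- layout$windows
  w <- layout$window_size
  step <- layout$step
  nw <- nrow(win)
  # first global window index (0-based within chrom) per chromosome
  chrom_first <- setNames(win[, min(widx), by = chrom]$V1,
                          win[, min(widx), by = chrom]$chrom)
  chrom_nwin <- setNames(win[, .N, by = chrom]$N, win[, .N, by = chrom]$chrom)

  raw <- matrix(0L, nrow = nw, ncol = length(reads),
                dimnames = list(NULL, names(reads)))
  dropped <- setNames(integer(length(reads)), names(reads))
  for (s in names(reads)) {
    rd <- as.data.table(reads[[s]])
    if (!nrow(rd) && length(reads[[s]]) == 0)
      stop(sprintf("empty read input for sample '%s'", s))
    if (!all(c("chrom", "start", "length") %in% names(rd)))
      stop(sprintf("read table for sample '%s' lacks chrom/start/length columns", s))
    if (!nrow(rd)) { next }  # zero reads is allowed; an absent table is not
    known <- rd$chrom %in% names(chrom_first)
    dropped[s] <- sum(!known)
    rd <- rd[known]
    if (!nrow(rd)) next
    mid <- rd$start + rd$length %/% 2L
    k_hi <- mid %/% step
    k_lo <- pmax(0L, (mid - w) %/% step + 1L)
    k_hi <- pmin(k_hi, chrom_nwin[rd$chrom] - 1L)
    nrep <- k_hi - k_lo + 1L
    keep <- nrep > 0L
    idx <- rep.int(k_lo[keep], nrep[keep]) + sequence(nrep[keep]) - 1L +
      rep.int(chrom_first[rd$chrom[keep]], nrep[keep])
    raw[, s] <- tabulate(idx, nbins = nw)
  }
  if (any(dropped > 0))
    warning(sprintf("dropped %d read(s) on chromosomes absent from the layout",
                    sum(dropped)))
  structure(list(layout = layout, samples = names(reads), raw = raw,
                 gc = NULL, gc_corrected = NULL, normalized = NULL,
                 window_mask = NULL, dropped = dropped),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  layers <- c("raw", if (!is.null(x$gc_corrected)) "gc_corrected",
              if (!is.null(x$normalized)) "normalized")
  cat(sprintf("depth_matrix: %d windows x %d samples; layers: %s\n",
              nrow(x$raw), length(x$samples), paste(layers, collapse = ", ")))
  invisible(x)
}

#' Correct GC bias by bin-median rescaling (gc_corrected layer)
#'
#' Windows are binned by GC fraction into `n_bins` equal-width bins over
#' `[0,1]`. Per sample, each bin's counts are rescaled by
#' `reference / bin median`, where the reference level is the median of the
#' per-bin medians (over bins holding at least `min_bin_windows` windows).
#' Using the median-of-bin-medians as the reference makes the correction
#' exactly idempotent: after one pass every bin median equals the reference,
#' so a second pass multiplies by 1. Bins with fewer than `min_bin_windows`
#' windows, or with a zero median, are left uncorrected.
#'
#' @param dm A `depth_matrix` with a raw layer.
#' @param gc_track data.frame with `chrom`, `window_start`, `gc_fraction`
#'   aligned to the layout's window grid.
#' @param n_bins Number of equal-width GC bins (default 20).
#' @param min_bin_windows Minimum windows for a bin to be corrected.
#' @return The `depth_matrix` with `gc` and `gc_corrected` filled in.
#' @export
gc_normalize <- function(dm, gc_track, n_bins = 20L, min_bin_windows = 20L) {
  stopifnot(inherits(dm, "depth_matrix"))
  gt <- as.data.table(gc_track)
  win <- dm$layout$windows
  m <- merge(win, gt, by.x = c("chrom", "start"),
             by.y = c("chrom", "window_start"), all.x = TRUE, sort = FALSE)
  setorder(m, widx)
  if (anyNA(m$gc_fraction))
    stop("gc_track does not cover every layout window")
  if (any(m$gc_fraction < 0 | m$gc_fraction > 1))
    stop("GC fractions must lie in [0,1]")
  gc <- m$gc_fraction
  bin <- pmin(pmax(ceiling(gc * n_bins), 1L), n_bins)
  bin_n <- tabulate(bin, n_bins)

  mat <- dm$raw
  corrected <- matrix(0, nrow = nrow(mat), ncol = ncol(mat),
                      dimnames = dimnames(mat))
  for (s in seq_len(ncol(mat))) {
    med_b <- vapply(seq_len(n_bins), function(b)
      if (bin_n[b] > 0L) median(mat[bin == b, s]) else NA_real_, numeric(1))
    eligible <- !is.na(med_b) & bin_n >= min_bin_windows & med_b > 0
    if (!any(eligible)) {
      if (all(mat[, s] == 0))
        warning(sprintf("sample '%s' has all-zero counts; no GC correction applied",
                        colnames(mat)[s]))
      corrected[, s] <- mat[, s]
      next
    }
    ref <- median(med_b[eligible])
    factor_b <- rep(1, n_bins)
    factor_b[eligible] <- ref / med_b[eligible]
    corrected[, s] <- mat[, s] * factor_b[bin]
  }
  dm$gc <- gc
  dm$gc_bin <- bin
  dm$gc_corrected <- corrected
  dm
}

#' Scale each sample to a diploid baseline of 1.0 (normalized layer)
#'
#' First derives the window usability mask, then divides each sample's
#' GC-corrected depth by its median over usable windows, so a diploid window
#' sits at normalized depth 1.0 and copy number is `2 x` normalized depth.
#'
#' A window is masked (unusable) if any of:
#' * its GC fraction lies outside `[gc_min, gc_max]`;
#' * it is truncated at a chromosome end (width < window size);
#' * fewer than `usability_min_fraction` of samples have a nonzero raw count
#'   in it;
#' * its across-sample median relative depth (each sample first divided by a
#'   provisional baseline, so the check is library-size free) falls outside
#'   `depth_rel_bounds` — gross outliers such as collapsed repeats or
#'   unmappable stretches. The median across samples is used so a CNV carried
#'   by a minority of samples cannot mask its own windows, and the bounds are
#'   absolute rather than rank-based so high-frequency CNV windows are never
#'   trimmed merely for being the most extreme windows of a small genome.
#'
#' @param dm A `depth_matrix` with a gc_corrected layer.
#' @param gc_min,gc_max Usable GC range (defaults 0.2 and 0.8).
#' @param usability_min_fraction Minimum fraction of samples with nonzero raw
#'   depth for a window to be usable (default 0.5).
#' @param depth_rel_bounds Usable range of the across-sample median relative
#'   depth (default `c(0.05, 3)`, i.e. windows collapsed below 5% of or
#'   amplified beyond 3x the diploid level in the cohort consensus).
#' @return The `depth_matrix` with `window_mask` (TRUE = usable) and
#'   `normalized` filled in; per-sample baselines in `baseline`.
#' @export
sample_normalize <- function(dm, gc_min = 0.2, gc_max = 0.8,
                             usability_min_fraction = 0.5,
                             depth_rel_bounds = c(0.05, 3)) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (is.null(dm$gc_corrected))
    stop("gc_corrected layer missing; run gc_normalize() first")
  win <- dm$layout$windows
  full <- (win$end - win$start) == dm$layout$window_size
  gc_ok <- dm$gc >= gc_min & dm$gc <= gc_max
  nonzero_frac <- rowMeans(dm$raw > 0)
  usable <- full & gc_ok & nonzero_frac >= usability_min_fraction
  if (any(usable)) {
    # screen on scale-free relative depth (each sample divided by a
    # provisional baseline) so that rescaling one library cannot move the mask
    prov <- apply(dm$gc_corrected[usable, , drop = FALSE], 2, median)
    prov[prov == 0] <- 1
    rel <- sweep(dm$gc_corrected, 2, prov, "/")
    med_depth <- apply(rel, 1, median)
    usable <- usable &
      med_depth >= depth_rel_bounds[1] & med_depth <= depth_rel_bounds[2]
  }
  if (!any(usable)) stop("no usable windows left after masking")

  baseline <- apply(dm$gc_corrected[usable, , drop = FALSE], 2, median)
  zero <- baseline == 0
  if (any(zero))
    stop(sprintf("sample(s) unusable (median corrected depth is 0): %s",
                 paste(dm$samples[zero], collapse = ", ")))
  normalized <- sweep(dm$gc_corrected, 2, baseline, "/")
  dm$window_mask <- usable
  dm$baseline <- baseline
  dm$normalized <- normalized
  dm
}
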