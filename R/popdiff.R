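#' Per-sample copy numbers over a CNVR
#'
#' Continuous copy number of each sample over a region:
#' `2 x` mean normalized depth across the region's unmasked windows.
#'
#' @param region One CNVR (a one-row table or list with `chrom`, `start`,
#'   `end`).
#' @param dm A `depth_matrix` with a normalized layer.
#' @return Named numeric vector, one copy number per sample.
#' @export
copy_number_vector <- function(region, dm) {
  rows <- region_window_rows(dm, region$chrom, region$start, region$end)
  if (!length(rows))
    stop(sprintf("all windows masked in region %s:%d-%d",
                 region$chrom, region$start, region$end))
  2 * colMeans(dm$normalized[rows, , drop = FALSE])
}

# Variance with a selectable estimator: "population" = ddof 0 (mean squared
# deviation, the Redon-style V_ST convention), "sample" = ddof 1.
variance_ddof <- function(x, estimator) {
  m <- mean(x)
  ss <- sum((x - m)^2)
  if (estimator == "population") ss / length(x) else ss / (length(x) - 1)
}

#' Compute V_ST between two groups of copy numbers
#'
#' `V_ST = (V_T - V_S) / V_T`, where `V_T` is the variance of copy numbers
#' over the two groups pooled and `V_S` is the mean within-group variance
#' weighted by group size: `(n1*v1 + n2*v2) / (n1 + n2)`. A fixed difference
#' between groups gives 1; identical groups give 0; slightly negative values
#' are possible and are retained. When `V_T = 0` (the region is invariant) the
#' statistic is undefined and the record is flagged.
#'
#' @param cn Numeric copy numbers, one per sample.
#' @param groups Group label per sample (exactly two distinct labels, each
#'   with at least 2 samples).
#' @param estimator `"population"` (ddof 0, default) or `"sample"` (ddof 1).
#' @return List `v_t`, `v_s`, `v_st` (NA when undefined), `defined`,
#'   `group_sizes`.
#' @export
compute_vst <- function(cn, groups, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  g <- as.character(groups)
  lv <- unique(g)
  if (length(lv) != 2) stop("compute_vst needs exactly two groups")
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  if (n1 < 2 || n2 < 2)
    stop(sprintf("each group needs >= 2 samples (got %d and %d)", n1, n2))
  v_t <- variance_ddof(cn, estimator)
  v1 <- variance_ddof(cn[g == lv[1]], estimator)
  v2 <- variance_ddof(cn[g == lv[2]], estimator)
  v_s <- (n1 * v1 + n2 * v2) / (n1 + n2)
  defined <- v_t > 0
  list(v_t = v_t, v_s = v_s,
       v_st = if (defined) (v_t - v_s) / v_t else NA_real_,
       defined = defined, group_sizes = setNames(c(n1, n2), lv))
}

#' V_ST scan over a CNVR set
#'
#' Computes per-CNVR copy numbers ([copy_number_vector()]) and V_ST between a
#' focal population and the pooled remaining populations.
#'
#' @param regions CNVR table.
#' @param dm `depth_matrix` with a normalized layer.
#' @param sample_map data.frame `sample`, `population`.
#' @param focal_pop Focal population name; all other populations are pooled
#'   into one comparison group.
#' @param estimator Variance estimator, see [compute_vst()].
#' @return data.table `id`, `chrom`, `midpoint`, `v_t`, `v_s`, `v_st`,
#'   `defined`.
#' @export
vst_scan <- function(regions, dm, sample_map, focal_pop,
                     estimator = "population") {
  smap <- as.data.table(sample_map)
  if (!focal_pop %in% smap$population)
    stop(sprintf("focal population '%s' not in sample map", focal_pop))
  grp <- ifelse(smap$population[match(dm$samples, smap$sample)] == focal_pop,
                focal_pop, "other")
  rbindlist(lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i]
    v <- compute_vst(copy_number_vector(r, dm), grp, estimator)
    data.table(id = r$id, chrom = r$chrom,
               midpoint = (r$start + r$end) %/% 2L,
               v_t = v$v_t, v_s = v$v_s, v_st = v$v_st, defined = v$defined)
  }))
}

#' Select the top fraction of V_ST records
#'
#' Returns the records whose V_ST is at least the empirical
#' `(1 - fraction)`-tail threshold: with `n` defined records the threshold is
#' the `max(1, floor(fraction * n))`-th largest value, and ties at the
#' threshold are all included. Undefined records (V_T = 0) carry no
#' differentiation signal and are excluded before ranking.
#'
#' @param records Table from [vst_scan()].
#' @param fraction Tail fraction (default 0.05, the top 5%).
#' @return List `selected` (record subset), `threshold`.
#' @export
select_top_fraction <- function(records, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  def <- records[defined == TRUE & !is.na(v_st)]
  if (!nrow(def)) stop("no defined V_ST records to rank")
  k <- max(1L, floor(fraction * nrow(def)))
  thr <- sort(def$v_st, decreasing = TRUE)[k]
  list(selected = def[v_st >= thr], threshold = thr)
}
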