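#' Classify each window of each sample by normalized depth
#'
#' Applies the read-depth thresholds per unmasked window: normalized depth
#' below `lower` is a homozygous deletion, `[lower, del_ceiling)` a
#' heterozygous deletion (the lower boundary is half-open: exactly `lower` is
#' het), above `dup_floor` a duplication, anything else neutral. The deletion
#' thresholds default to 0.2 and 0.7; the duplication floor defaults to
#' `2 - 0.7 = 1.3` by symmetry around the diploid level. Masked windows are
#' `NA` and never produce calls.
#'
#' @param dm A `depth_matrix` with a normalized layer.
#' @param lower Homozygous-deletion ceiling (default 0.2).
#' @param del_ceiling Heterozygous-deletion ceiling (default 0.7).
#' @param dup_floor Duplication floor (default 1.3).
#' @return Character matrix (windows x samples) with values `hom_del`,
#'   `het_del`, `dup`, `neutral`, or `NA` for masked windows.
#' @export
call_window_states <- function(dm, lower = 0.2, del_ceiling = 0.7,
                               dup_floor = 1.3) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (is.null(dm$normalized)) stop("normalized layer missing; run sample_normalize() first")
  if (!(0 < lower && lower < del_ceiling && del_ceiling < 1 && 1 < dup_floor))
    stop("thresholds must satisfy 0 < lower < del_ceiling < 1 < dup_floor")
  nd <- dm$normalized
  st <- matrix("neutral", nrow = nrow(nd), ncol = ncol(nd),
               dimnames = dimnames(nd))
  st[nd < lower] <- "hom_del"
  st[nd >= lower & nd < del_ceiling] <- "het_del"
  st[nd > dup_floor] <- "dup"
  st[!dm$window_mask, ] <- NA_character_
  st
}

#' Segment per-sample window states into CNV calls
#'
#' Collects, per sample and chromosome, maximal runs of same-direction
#' non-neutral windows (heterozygous and homozygous deletion states may mix
#' within one deletion run; deletion and duplication runs never join), allowing
#' up to `max_gap_windows` neutral or masked windows inside a run. Runs with
#' fewer than `min_windows` CNV-state windows are discarded. Call coordinates
#' span from the first to the last member window; the call state is re-derived
#' from the segment mean depth on the deletion side (`hom_del` if the mean is
#' below `lower`).
#'
#' @param states State matrix from [call_window_states()].
#' @param dm The `depth_matrix` the states came from.
#' @param min_windows Minimum CNV-state windows per call (default 2).
#' @param max_gap_windows Maximum neutral windows bridged inside a run.
#' @param lower Homozygous-deletion ceiling used to restate the segment.
#' @return data.table of calls: `sample`, `chrom`, `start`, `end`, `state`,
#'   `mean_norm_depth`, `n_windows`.
#' @export
segment_sample_cnvs <- function(states, dm, min_windows = 2L,
                                max_gap_windows = 1L, lower = 0.2) {
  win <- dm$layout$windows
  nd <- dm$normalized
  out <- list()
  for (s in colnames(states)) {
    sv <- states[, s]
    dir <- integer(length(sv))
    dir[!is.na(sv) & (sv == "hom_del" | sv == "het_del")] <- -1L
    dir[!is.na(sv) & sv == "dup"] <- 1L
    for (ch in names(dm$layout$chroms)) {
      rows <- win[chrom == ch, widx]
      d <- dir[rows]
      nz <- which(d != 0L)
      if (!length(nz)) next
      new_run <- c(TRUE, diff(nz) > max_gap_windows + 1L |
                     d[nz[-1]] != d[nz[-length(nz)]])
      grp <- cumsum(new_run)
      for (g in unique(grp)) {
        mem <- nz[grp == g]
        if (length(mem) < min_windows) next
        gwin <- rows[mem]
        mean_nd <- mean(nd[gwin, s])
        state <- if (d[mem[1]] > 0L) "dup" else
          if (mean_nd < lower) "hom_del" else "het_del"
        out[[length(out) + 1L]] <- data.table(
          sample = s, chrom = ch,
          start = win$start[rows[mem[1]]], end = win$end[rows[mem[length(mem)]]],
          state = state, mean_norm_depth = mean_nd,
          n_windows = length(mem))
      }
    }
  }
  if (!length(out))
    return(data.table(sample = character(), chrom = character(),
                      start = integer(), end = integer(), state = character(),
                      mean_norm_depth = numeric(), n_windows = integer()))
  res <- rbindlist(out)
  setorder(res, chrom, start, sample)
  res
}

# Unmasked window row indices inside [start, end); falls back to overlapping
# windows when none is fully contained.
region_window_rows <- function(dm, ch, s0, e0) {
  win <- dm$layout$windows
  rows <- win[chrom == ch & start >= s0 & end <= e0, widx]
  rows <- rows[dm$window_mask[rows]]
  if (!length(rows)) {
    rows <- win[chrom == ch & start < e0 & end > s0, widx]
    rows <- rows[dm$window_mask[rows]]
  }
  rows
}

# Two-sided p-value of Pearson r via the t statistic with df = n - 2
pearson_p <- function(v1, v2) {
  n <- length(v1)
  r <- suppressWarnings(cor(v1, v2))
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Merge per-sample CNV calls into CNVRs
#'
#' Iterative agglomeration per chromosome, left to right by start coordinate,
#' repeated until a fixed point: two candidate regions merge iff (a) the gap
#' between them is less than `max_gap_fraction` of their combined length
#' (overlapping regions have gap <= 0 and always satisfy this), and (b) the
#' Pearson correlation of the two regions' per-sample mean normalized depth
#' vectors (across all samples) is significant at `corr_alpha` (two-sided t
#' test, df = n - 2). With fewer than 4 samples the correlation is untestable
#' and merging falls back to the gap rule alone, with a warning.
#'
#' Accepts either the call table from [segment_sample_cnvs()] or an existing
#' CNVR table (so the fixed-point property can be verified by re-merging).
#'
#' @param calls data.table of calls (or CNVRs with a `carriers` list-column).
#' @param dm The `depth_matrix` (normalized layer) behind the calls.
#' @param max_gap_fraction Gap threshold as a fraction of combined length.
#' @param corr_alpha Significance level for the correlation test.
#' @return data.table of CNVRs: `id`, `chrom`, `start`, `end`, `type`,
#'   `n_carriers`, and list-columns `carriers` (sample names) and `states`
#'   (carrier states, aligned with `carriers`).
#' @export
merge_to_cnvrs <- function(calls, dm, max_gap_fraction = 0.2,
                           corr_alpha = 0.01) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (!nrow(calls)) stop("merge_to_cnvrs needs at least one call")
  n_samp <- length(dm$samples)
  gap_only <- n_samp < 4L
  if (gap_only)
    warning("fewer than 4 samples: correlation untestable, merging on the gap rule only")

  if ("carriers" %in% names(calls)) {
    regs <- lapply(seq_len(nrow(calls)), function(i)
      list(chrom = calls$chrom[i], start = calls$start[i], end = calls$end[i],
           car = data.table(sample = calls$carriers[[i]],
                            state = calls$states[[i]],
                            weight = 1L)))
  } else {
    regs <- lapply(seq_len(nrow(calls)), function(i)
      list(chrom = calls$chrom[i], start = calls$start[i], end = calls$end[i],
           car = data.table(sample = calls$sample[i], state = calls$state[i],
                            weight = calls$n_windows[i])))
  }

  region_vec <- function(r) {
    rows <- region_window_rows(dm, r$chrom, r$start, r$end)
    if (!length(rows)) return(rep(NA_real_, n_samp))
    colMeans(dm$normalized[rows, , drop = FALSE])
  }

  out <- list()
  for (ch in unique(vapply(regs, `[[`, "", "chrom"))) {
    rl <- Filter(function(r) r$chrom == ch, regs)
    vecs <- lapply(rl, region_vec)
    repeat {
      ord <- order(vapply(rl, `[[`, 0, "start"), vapply(rl, `[[`, 0, "end"))
      rl <- rl[ord]; vecs <- vecs[ord]
      merged_any <- FALSE
      max_len <- max(vapply(rl, function(r) r$end - r$start, 0))
      i <- 1L
      while (i < length(rl)) {
        j <- i + 1L
        while (j <= length(rl)) {
          ri <- rl[[i]]; rj <- rl[[j]]
          gap <- rj$start - ri$end
          if (gap >= max_gap_fraction * ((ri$end - ri$start) + max_len)) break
          ok_gap <- gap < max_gap_fraction *
            ((ri$end - ri$start) + (rj$end - rj$start))
          ok <- FALSE
          if (ok_gap) {
            if (gap_only) ok <- TRUE
            else {
              p <- pearson_p(vecs[[i]], vecs[[j]])
              ok <- if (is.na(p)) isTRUE(all.equal(vecs[[i]], vecs[[j]]))
                    else p < corr_alpha
            }
          }
          if (ok) {
            car <- rbind(ri$car, rj$car)
            car <- car[, .(state = state[which.max(weight)],
                           weight = sum(weight)), by = sample]
            rl[[i]] <- list(chrom = ch, start = min(ri$start, rj$start),
                            end = max(ri$end, rj$end), car = car)
            vecs[[i]] <- region_vec(rl[[i]])
            rl[[j]] <- NULL; vecs[[j]] <- NULL
            merged_any <- TRUE
          } else j <- j + 1L
        }
        i <- i + 1L
      }
      if (!merged_any) break
    }
    out <- c(out, rl)
  }

  res <- rbindlist(lapply(out, function(r) {
    car <- r$car[order(sample)]
    data.table(chrom = r$chrom, start = r$start, end = r$end,
               type = classify_cnvr_type(car$state),
               n_carriers = nrow(car),
               carriers = list(car$sample), states = list(car$state))
  }))
  setorder(res, chrom, start, end)
  res[, id := sprintf("cnvr%04d", seq_len(.N))]
  setcolorder(res, c("id", "chrom", "start", "end", "type", "n_carriers",
                     "carriers", "states"))
  res[]
}

#' Classify a CNVR as deletion, duplication or mixed
#'
#' @param states Character vector of carrier states (`hom_del`, `het_del`,
#'   `dup`).
#' @return `"deletion"` if all carriers are deletion-state, `"duplication"` if
#'   all are duplication-state, `"mixed"` if both occur.
#' @export
classify_cnvr_type <- function(states) {
  if (!length(states)) stop("classify_cnvr_type: region has no carriers")
  if (any(!states %in% c("hom_del", "het_del", "dup")))
    stop("classify_cnvr_type: carrier with non-CNV state")
  has_del <- any(states %in% c("hom_del", "het_del"))
  has_dup <- any(states == "dup")
  if (has_del && has_dup) "mixed" else if (has_del) "deletion" else "duplication"
}

#' Filter CNVRs by carrier count and chromosome placement
#'
#' Drops CNVRs carried by fewer than `min_samples` samples and CNVRs on
#' chromosomes outside the placed-chromosome whitelist (unplaced scaffolds).
#'
#' @param regions CNVR table from [merge_to_cnvrs()].
#' @param min_samples Minimum carrier count (default 2, "at least two
#'   animals"; use 3 for a strict "more than two samples" reading).
#' @param placed_chroms Optional character whitelist of placed chromosomes.
#' @return Filtered CNVR table, ids reassigned in genome order.
#' @export
filter_cnvrs <- function(regions, min_samples = 2L, placed_chroms = NULL) {
  res <- regions[n_carriers >= min_samples]
  if (!is.null(placed_chroms)) res <- res[chrom %in% placed_chroms]
  if (nrow(res)) {
    res <- copy(res)
    res[, id := sprintf("cnvr%04d", seq_len(.N))]
  }
  res[]
}
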