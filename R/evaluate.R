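#' Compare called CNVRs against planted truth
#'
#' A truth event is *eligible* if it has at least `min_carriers` carrier
#' samples (events below the pipeline's carrier-frequency filter are
#' unrecoverable by construction and excluded from the recall denominator).
#' An eligible event is *recovered* if some called CNVR on the same chromosome
#' has a compatible type (a deletion matches `deletion` or `mixed`, a
#' duplication matches `duplication` or `mixed`) and both boundaries within
#' `boundary_tol` bp. Precision is the fraction of called CNVRs matching any
#' planted event under the same rule.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param regions Called CNVR table.
#' @param boundary_tol Boundary tolerance in bp (default: one window step).
#' @param min_carriers Carrier threshold defining eligible events (default 2).
#' @return List `recall`, `precision`, `n_eligible`, `n_called`, `events`
#'   (truth table with `eligible`, `recovered`, `matched_id`).
#' @export
evaluate_recovery <- function(truth, regions, boundary_tol = 400L,
                              min_carriers = 2L) {
  ev <- copy(truth$events)
  if (!nrow(ev))
    return(list(recall = NA_real_, precision = if (nrow(regions)) 0 else NA_real_,
                n_eligible = 0L, n_called = nrow(regions), events = ev))
  ev[, n_carriers := rowSums(truth$cn != 2L)]
  ev[, eligible := n_carriers >= min_carriers]
  compat <- function(kind, type) type == "mixed" |
    (kind == "deletion" & type == "deletion") |
    (kind == "duplication" & type == "duplication")
  ev[, c("recovered", "matched_id") := {
    res <- lapply(seq_len(.N), function(i) {
      if (!nrow(regions)) return(list(FALSE, NA_character_))
      cand <- regions[chrom == ev$chrom[i] &
                        abs(start - ev$start[i]) <= boundary_tol &
                        abs(end - ev$end[i]) <= boundary_tol]
      cand <- cand[compat(ev$kind[i], type)]
      if (nrow(cand)) list(TRUE, cand$id[1]) else list(FALSE, NA_character_)
    })
    list(vapply(res, function(x) x[[1]], logical(1)),
         vapply(res, function(x) x[[2]], character(1)))
  }]
  n_eligible <- sum(ev$eligible)
  recall <- if (n_eligible) sum(ev$recovered & ev$eligible) / n_eligible else NA_real_
  if (nrow(regions)) {
    called_ok <- vapply(seq_len(nrow(regions)), function(j) {
      cand <- ev[chrom == regions$chrom[j] &
                   abs(start - regions$start[j]) <= boundary_tol &
                   abs(end - regions$end[j]) <= boundary_tol]
      nrow(cand[compat(kind, regions$type[j])]) > 0
    }, logical(1))
    precision <- mean(called_ok)
  } else precision <- NA_real_
  list(recall = recall, precision = precision, n_eligible = n_eligible,
       n_called = nrow(regions), events = ev[])
}

#' Per-population CNVR summary table
#'
#' One row per population plus a merged row: number of CNVRs with at least one
#' carrier in the population, their total length, the number unique to the
#' population, type counts (duplication, deletion, mixed) and the percentage
#' of the genome covered.
#'
#' @param regions CNVR table with `carriers`/`states` list-columns.
#' @param sample_map data.frame `sample`, `population`.
#' @param genome_size Total genome length in bp.
#' @return data.table with columns `population`, `n_samples`, `n_cnvrs`,
#'   `length_bp`, `n_unique`, `dup`, `del`, `mixed`, `pct_genome`.
#' @export
breed_summary_table <- function(regions, sample_map, genome_size) {
  smap <- as.data.table(sample_map)
  sh <- breed_sharing(regions, smap)
  pops <- sort(unique(smap$population))
  pop_of <- setNames(smap$population, smap$sample)
  row_for <- function(p) {
    idx <- which(vapply(regions$carriers, function(car)
      is.null(p) || any(pop_of[car] == p), logical(1)))
    sub <- regions[idx]
    # type within the population: classify from this population's carriers only
    types <- if (is.null(p)) sub$type else
      vapply(idx, function(i) {
        keep <- pop_of[regions$carriers[[i]]] == p
        classify_cnvr_type(regions$states[[i]][keep])
      }, character(1))
    data.table(
      population = if (is.null(p)) "merged" else p,
      n_samples = if (is.null(p)) nrow(smap) else sum(smap$population == p),
      n_cnvrs = nrow(sub),
      length_bp = sum(sub$end - sub$start),
      n_unique = if (is.null(p)) 0L else unname(sh$unique_counts[p]),
      dup = sum(types == "duplication"),
      del = sum(types == "deletion"),
      mixed = sum(types == "mixed"),
      pct_genome = pct_of(sum(sub$end - sub$start), genome_size)
    )
  }
  rbindlist(c(lapply(pops, row_for), list(row_for(NULL))))
}
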