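#' Copy number from qPCR Ct values (2 x 2^-ddCt)
#'
#' Relative quantification against a reference gene and a diploid calibrator
#' ("standard") sample: per sample, `dCt = mean(Ct_target) -
#' mean(Ct_reference)`; `ddCt = dCt_sample - dCt_calibrator`; copy number
#' `CN = 2 x 2^-ddCt` (amplification efficiency assumed exactly 2). Replicates
#' are summarized by their arithmetic mean. `ddCt = 0` therefore gives CN = 2,
#' the diploid state.
#'
#' @param measurements Long-format table with columns `cnvr_id`, `sample`,
#'   `role` (`target`/`reference`), `ct`, `is_calibrator` — the layout
#'   produced by [simulate_qpcr()] or read from a Ct TSV.
#' @return data.table `cnvr_id`, `sample`, `d_ct`, `dd_ct`, `copy_number`,
#'   `is_calibrator`.
#' @export
copy_number_ddct <- function(measurements) {
  m <- as.data.table(measurements)
  need <- c("cnvr_id", "sample", "role", "ct", "is_calibrator")
  if (!all(need %in% names(m)))
    stop(sprintf("measurement table needs columns: %s", paste(need, collapse = ", ")))
  if (any(!is.finite(m$ct) | m$ct <= 0)) stop("Ct values must be finite and > 0")
  wide <- m[, .(ct = mean(ct)), by = .(cnvr_id, sample, role, is_calibrator)]
  dct <- data.table::dcast(wide, cnvr_id + sample + is_calibrator ~ role,
                           value.var = "ct")
  if (!all(c("target", "reference") %in% names(dct)) ||
      anyNA(dct$target) || anyNA(dct$reference))
    stop("every sample needs both target and reference-gene replicates")
  dct[, d_ct := target - reference]
  res <- rbindlist(lapply(split(dct, by = "cnvr_id"), function(b) {
    cal <- b[is_calibrator == TRUE]
    if (nrow(cal) != 1L)
      stop(sprintf("CNVR batch '%s' needs exactly one calibrator sample (found %d)",
                   b$cnvr_id[1], nrow(cal)))
    b[, dd_ct := d_ct - cal$d_ct]
    b[, copy_number := 2 * 2^(-dd_ct)]
    b[, .(cnvr_id, sample, d_ct, dd_ct, copy_number, is_calibrator)]
  }))
  setorder(res, cnvr_id, sample)
  res[]
}

#' Classify a qPCR copy-number estimate and call concordance with sequencing
#'
#' qPCR class: `loss` when the estimate is at or below `loss_max` (ratios
#' around 0 or 1), `gain` at or above `gain_min` (values around 3 or higher),
#' otherwise `normal` (a value of 2). The call is concordant iff the class
#' direction matches the sequencing-derived state (`deletion`/`hom_del`/
#' `het_del` expect loss, `duplication`/`dup` expect gain, `neutral`/`normal`
#' expect normal).
#'
#' @param cn_estimate Numeric copy-number estimate(s), >= 0.
#' @param sequencing_state Matching sequencing state label(s).
#' @param loss_max Upper bound of the loss class (default 1.5).
#' @param gain_min Lower bound of the gain class (default 3.0).
#' @return data.table `copy_number`, `qpcr_class`, `sequencing_state`,
#'   `concordant`.
#' @export
concordance_call <- function(cn_estimate, sequencing_state,
                             loss_max = 1.5, gain_min = 3.0) {
  stopifnot(all(cn_estimate >= 0), loss_max < gain_min)
  cls <- ifelse(cn_estimate <= loss_max, "loss",
                ifelse(cn_estimate >= gain_min, "gain", "normal"))
  expected <- vapply(as.character(sequencing_state), function(st)
    switch(st,
           deletion = , hom_del = , het_del = , loss = "loss",
           duplication = , dup = , gain = "gain",
           neutral = , normal = "normal",
           stop(sprintf("unknown sequencing state '%s'", st))),
    character(1), USE.NAMES = FALSE)
  data.table(copy_number = cn_estimate, qpcr_class = cls,
             sequencing_state = as.character(sequencing_state),
             concordant = cls == expected)
}

#' Per-CNVR qPCR validation verdict
#'
#' Runs [copy_number_ddct()] and [concordance_call()] over a measurement table
#' and summarizes, per CNVR, whether the non-calibrator samples' qPCR classes
#' agree with the sequencing-derived region type.
#'
#' @param measurements Measurement table (see [copy_number_ddct()]).
#' @param sequencing_types Named character vector CNVR id -> sequencing type
#'   (`deletion`, `duplication`, `neutral`).
#' @param loss_max,gain_min Class boundaries, see [concordance_call()].
#' @return List `per_sample` (joined estimates + calls), `per_cnvr`
#'   (data.table `cnvr_id`, `n_samples`, `n_concordant`, `validated` — TRUE
#'   iff a majority of assayed carrier samples is concordant),
#'   `validation_rate_pct`.
#' @export
qpcr_validate <- function(measurements, sequencing_types,
                          loss_max = 1.5, gain_min = 3.0) {
  est <- copy_number_ddct(measurements)
  est <- est[is_calibrator == FALSE]
  if (any(!est$cnvr_id %in% names(sequencing_types)))
    stop("sequencing_types must name every assayed CNVR")
  calls <- concordance_call(est$copy_number,
                            sequencing_types[est$cnvr_id],
                            loss_max, gain_min)
  per_sample <- cbind(est[, .(cnvr_id, sample)], calls)
  per_cnvr <- per_sample[, .(n_samples = .N, n_concordant = sum(concordant),
                             validated = mean(concordant) > 0.5),
                         by = cnvr_id]
  list(per_sample = per_sample, per_cnvr = per_cnvr,
       validation_rate_pct = pct_of(sum(per_cnvr$validated), nrow(per_cnvr)))
}
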