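#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end run. Defaults mirror the
#' calling conventions the pipeline is built around: 800 bp windows stepping
#' by 400 bp, deletion thresholds 0.2/0.7 with a symmetric duplication floor
#' of 1.3, CNVR merging at gap < 20% of combined length with depth
#' correlation significant at 0.01, carrier filter of 2 samples, and a top-5%
#' V(ST) tail.
#'
#' @param sim A [sim_config()] describing the cohort to simulate, or `NULL`
#'   when read placements are supplied directly to [run_pipeline()].
#' @param window_size,step Window grid (bp).
#' @param lower,del_ceiling,dup_floor Depth thresholds for window states.
#' @param gc_bins,min_bin_windows GC-correction binning.
#' @param min_windows,max_gap_windows Per-sample segmentation parameters.
#' @param merge_gap_fraction,corr_alpha CNVR merge rule.
#' @param min_samples Carrier filter for CNVRs.
#' @param placed_chroms Optional placed-chromosome whitelist.
#' @param vst_top_fraction Tail fraction for the V(ST) scan.
#' @param focal_pop Focal population of the V(ST) comparison; `NULL` picks the
#'   last population in the sample map.
#' @param size_bin_edges_kb Size-distribution bin edges (kb).
#' @param n_genes,n_qtls Number of simulated annotation features.
#' @param seed Seed for annotation simulation (the cohort has its own seed in
#'   `sim`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window_size = 800L, step = window_size %/% 2L,
                            lower = 0.2, del_ceiling = 0.7, dup_floor = 1.3,
                            gc_bins = 20L, min_bin_windows = 20L,
                            min_windows = 2L, max_gap_windows = 1L,
                            merge_gap_fraction = 0.2, corr_alpha = 0.01,
                            min_samples = 2L, placed_chroms = NULL,
                            vst_top_fraction = 0.05, focal_pop = NULL,
                            size_bin_edges_kb = c(1, 2, 5, 10, Inf),
                            n_genes = 40L, n_qtls = 30L, seed = 1L) {
  cfg <- as.list(environment())
  if (!(0 < lower && lower < del_ceiling && del_ceiling < 1 && 1 < dup_floor))
    stop("thresholds must satisfy 0 < lower < del_ceiling < 1 < dup_floor")
  if (merge_gap_fraction < 0 || merge_gap_fraction >= 1)
    stop("merge_gap_fraction must be in [0, 1)")
  if (vst_top_fraction <= 0 || vst_top_fraction > 1)
    stop("vst_top_fraction must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the whole read-depth CNV pipeline
#'
#' Executes simulate (unless a cohort is supplied) -> window depth -> GC
#' correction -> sample normalization -> window states -> per-sample segments
#' -> CNVR merge -> carrier/placement filter -> annotation -> V(ST) scan, and
#' returns a report bundle. Identical config + seed gives identical results.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built [simulate_cohort()] result (or a
#'   compatible list with `layout`, `gc`, `reads`, `sample_map`, and
#'   optionally `truth`) to use instead of simulating.
#' @param outdir Optional directory; when set, every stage's table is written
#'   as TSV together with a JSON manifest of all parameters.
#' @return List of class `cnv_report`: `dm` (depth matrix), `calls`, `cnvrs`
#'   (filtered CNVR table), `breed_summary`, `annotation`, `vst` (scan table),
#'   `vst_top` (selected records + threshold), `recovery` (truth comparison,
#'   when truth is available), `params`.
#' @export
run_pipeline <- function(config, cohort = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$sim)) stop("no cohort supplied and config$sim is NULL")
    cohort <- simulate_cohort(config$sim)
  }
  dm <- compute_window_depth(cohort$reads, cohort$layout)
  dm <- gc_normalize(dm, cohort$gc, n_bins = config$gc_bins,
                     min_bin_windows = config$min_bin_windows)
  dm <- sample_normalize(dm)
  states <- call_window_states(dm, config$lower, config$del_ceiling,
                               config$dup_floor)
  calls <- segment_sample_cnvs(states, dm, config$min_windows,
                               config$max_gap_windows, config$lower)
  if (nrow(calls)) {
    cnvrs <- merge_to_cnvrs(calls, dm, config$merge_gap_fraction,
                            config$corr_alpha)
    cnvrs <- filter_cnvrs(cnvrs, config$min_samples, config$placed_chroms)
  } else {
    cnvrs <- data.table(id = character(), chrom = character(),
                        start = integer(), end = integer(), type = character(),
                        n_carriers = integer(), carriers = list(),
                        states = list())
  }

  ann_feats <- simulate_annotations(cohort$layout, config$n_genes,
                                    config$n_qtls, seed = config$seed)
  annotation <- annotate_cnvrs(cnvrs, ann_feats[c("genes", "exons")],
                               ann_feats$qtls, cohort$sample_map)

  focal <- config$focal_pop %||% tail(sort(unique(cohort$sample_map$population)), 1)
  vst <- if (nrow(cnvrs) >= 1) vst_scan(cnvrs, dm, cohort$sample_map, focal)
         else data.table(id = character(), chrom = character(),
                         midpoint = integer(), v_t = numeric(),
                         v_s = numeric(), v_st = numeric(), defined = logical())
  vst_top <- if (any(vst$defined)) select_top_fraction(vst, config$vst_top_fraction)
             else list(selected = vst[0], threshold = NA_real_)

  genome_size <- sum(cohort$layout$chroms)
  breed_summary <- if (nrow(cnvrs))
    breed_summary_table(cnvrs, cohort$sample_map, genome_size)
  else data.table()
  recovery <- if (!is.null(cohort$truth))
    evaluate_recovery(cohort$truth, cnvrs,
                      boundary_tol = cohort$layout$step,
                      min_carriers = config$min_samples)
  else NULL

  params <- config[setdiff(names(config), "sim")]
  params$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  report <- structure(
    list(dm = dm, calls = calls, cnvrs = cnvrs, breed_summary = breed_summary,
         annotation = annotation, vst = vst, vst_top = vst_top,
         recovery = recovery, features = ann_feats, params = params,
         focal_pop = focal),
    class = "cnv_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fwrite(calls, file.path(outdir, "cnv_calls.tsv"), sep = "\t")
    write_cnvr_bed(cnvrs, file.path(outdir, "cnvrs.bed.tsv"), dm)
    fwrite(breed_summary, file.path(outdir, "breed_summary.tsv"), sep = "\t")
    fwrite(annotation$genic, file.path(outdir, "genic_context.tsv"), sep = "\t")
    fwrite(annotation$sizes, file.path(outdir, "size_distribution.tsv"), sep = "\t")
    fwrite(annotation$sharing$venn, file.path(outdir, "venn_cells.tsv"), sep = "\t")
    fwrite(annotation$qtl$by_category, file.path(outdir, "qtl_categories.tsv"), sep = "\t")
    fwrite(vst, file.path(outdir, "vst_scan.tsv"), sep = "\t")
    fwrite(vst_top$selected, file.path(outdir, "vst_top.tsv"), sep = "\t")
    man <- params
    man$sim$window_gc_profile <- NULL
    man$vst_threshold <- vst_top$threshold
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}

#' @export
print.cnv_report <- function(x, ...) {
  cat(sprintf("cnv_report: %d CNVRs (%d del / %d dup / %d mixed) from %d calls\n",
              nrow(x$cnvrs), sum(x$cnvrs$type == "deletion"),
              sum(x$cnvrs$type == "duplication"), sum(x$cnvrs$type == "mixed"),
              nrow(x$calls)))
  if (!is.null(x$recovery) && !is.na(x$recovery$recall))
    cat(sprintf("  planted-CNV recovery: recall %.3f, precision %.3f (%d eligible events)\n",
                x$recovery$recall, x$recovery$precision, x$recovery$n_eligible))
  if (nrow(x$vst) && any(x$vst$defined))
    cat(sprintf("  V_ST scan vs '%s': top threshold %.3f (%d selected)\n",
                x$focal_pop, x$vst_top$threshold, nrow(x$vst_top$selected)))
  invisible(x)
}
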