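# Shared configuration for the analysis scripts.
#
# The synthetic cohort emulates the study design the pipeline is built for:
# 3 cattle populations (two lowland, one highland as the focal group) x 10
# animals at 15X mean depth on a 5 Mb toy genome (2 chromosomes), with 45
# planted CNVs of 1.6-8 kb, two of which are population-differentiated in the
# focal group (carrier frequency 0.9 vs 0.02) for the V_ST scan to recover.

suppressMessages(library(rdcnv))
suppressMessages(library(data.table))

RESULTS <- "results"
SCRATCH <- "scratch/analysis"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH, showWarnings = FALSE, recursive = TRUE)

COHORT_SEED <- 2024L

study_config <- function() pipeline_config(sim = sim_config(seed = COHORT_SEED))

# Heavy intermediates are cached under scratch/ so each numbered script can be
# rerun on its own without repeating earlier stages.
cached_rds <- function(name, builder) {
  p <- file.path(SCRATCH, paste0(name, ".rds"))
  if (file.exists(p)) return(readRDS(p))
  x <- builder()
  saveRDS(x, p)
  x
}

get_cohort <- function() cached_rds("cohort", function() {
  simulate_cohort(study_config()$sim)
})

get_dm <- function() cached_rds("depth_matrix", function() {
  cfg <- study_config()
  co <- get_cohort()
  dm <- compute_window_depth(co$reads, co$layout)
  dm <- gc_normalize(dm, co$gc, cfg$gc_bins, cfg$min_bin_windows)
  sample_normalize(dm)
})

get_cnvrs <- function() cached_rds("cnvrs", function() {
  cfg <- study_config()
  co <- get_cohort()
  dm <- get_dm()
  states <- call_window_states(dm, cfg$lower, cfg$del_ceiling, cfg$dup_floor)
  calls <- segment_sample_cnvs(states, dm, cfg$min_windows,
                               cfg$max_gap_windows, cfg$lower)
  cnvrs <- merge_to_cnvrs(calls, dm, cfg$merge_gap_fraction, cfg$corr_alpha)
  list(calls = calls, cnvrs = filter_cnvrs(cnvrs, cfg$min_samples))
})
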