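# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Hand-built depth matrix around an explicit normalized layer.
make_dm <- function(normalized, layout, mask = rep(TRUE, nrow(normalized))) {
  structure(list(layout = layout, samples = colnames(normalized),
                 raw = normalized, gc_corrected = normalized,
                 normalized = normalized, window_mask = mask),
            class = "depth_matrix")
}

# Noise-free cohort on which depth identities are exact:
# integer expected counts, no GC bias, no library-size variation, all-het
# deletions (CN=1) and CN=3 duplications.
zero_noise_config <- function(seed = 42L, n_cnvs = 8L) {
  sim_config(n_chroms = 1L, chrom_length = 1e6, noise = "none",
             gc_bias_strength = 0, sample_scale_sd = 0,
             n_populations = 2L, samples_per_pop = 3L,
             mean_depth = 15, read_length = 100L,
             n_cnvs = n_cnvs, cnv_length_range = c(1600L, 4800L),
             hom_del_fraction = 0, hom_dup_fraction = 0,
             freq_range = c(0.4, 0.6), n_differentiated = 0L,
             min_separation = 8000L, seed = seed)
}

zero_noise_cohort <- function() cached("zero_noise", function() {
  simulate_cohort(zero_noise_config())
})

zero_noise_dm <- function() cached("zero_noise_dm", function() {
  co <- zero_noise_cohort()
  dm <- compute_window_depth(co$reads, co$layout)
  dm <- gc_normalize(dm, co$gc)
  sample_normalize(dm)
})

# Expected copy number per (window, sample) from planted truth; windows
# fully inside an event get the carrier CN, windows clear of all events get 2.
truth_cn_by_window <- function(cohort) {
  win <- cohort$layout$windows
  ev <- cohort$truth$events
  cn <- matrix(2L, nrow = nrow(win), ncol = ncol(cohort$truth$cn),
               dimnames = list(NULL, colnames(cohort$truth$cn)))
  boundary <- rep(FALSE, nrow(win))
  for (i in seq_len(nrow(ev))) {
    inside <- win$chrom == ev$chrom[i] & win$start >= ev$start[i] &
      win$end <= ev$end[i]
    touch <- win$chrom == ev$chrom[i] & win$start < ev$end[i] &
      win$end > ev$start[i]
    boundary <- boundary | (touch & !inside)
    cn[inside, ] <- matrix(cohort$truth$cn[i, ], nrow = sum(inside),
                           ncol = ncol(cn), byrow = TRUE)
  }
  list(cn = cn, boundary = boundary)
}

# The study-scale cohort of the recovery and V_ST suites: 5 Mb genome,
# 3 populations x 10 samples at 15X Poisson noise, 45 planted CNVs.
study_report <- function() cached("study_report", function() {
  run_pipeline(pipeline_config(sim = sim_config(seed = 2024L)))
})

# Independent brute-force interval overlap: O(n*m) pairwise scan on
# 0-based half-open intervals.
brute_overlaps <- function(a, b, min_bp = 1L) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_bp) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) matrix(integer(), ncol = 2)
  else do.call(rbind, hits)
}

# Textbook V_ST oracle, written independently of compute_vst().
vst_oracle <- function(cn, groups, ddof = 0) {
  v <- function(x) sum((x - sum(x) / length(x))^2) / (length(x) - ddof)
  gs <- split(cn, groups)
  stopifnot(length(gs) == 2)
  n1 <- length(gs[[1]]); n2 <- length(gs[[2]])
  v_t <- v(cn)
  v_s <- (n1 * v(gs[[1]]) + n2 * v(gs[[2]])) / (n1 + n2)
  if (v_t == 0) NA_real_ else (v_t - v_s) / v_t
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                           min_len = 500, max_len = 20000) {
  start <- floor(runif(n, 0, max_pos - max_len))
  data.table::data.table(
    id = sprintf("r%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = as.integer(start),
    end = as.integer(start + runif(n, min_len, max_len)))
}

# Synthetic long-format Ct table with a calibrator and given per-sample ddCt.
ct_table <- function(dd_ct_by_sample, calibrator = "cal", n_rep = 3L,
                     ref_ct = 20, base_ct = 25) {
  samples <- c(calibrator, names(dd_ct_by_sample))
  dd <- c(0, unname(dd_ct_by_sample))
  data.table::data.table(
    cnvr_id = "cnvr_test",
    sample = rep(samples, each = n_rep, times = 2),
    role = rep(c("target", "reference"), each = length(samples) * n_rep),
    ct = c(rep(base_ct + dd, each = n_rep), rep(ref_ct, length(samples) * n_rep)),
    is_calibrator = rep(samples == calibrator, each = n_rep, times = 2))
}
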