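#' Simulation configuration for a synthetic WGS cohort
#'
#' Describes a toy multi-chromosome genome, a cohort of samples split into
#' populations, a sequencing-depth model, and a set of CNVs to plant with
#' population-stratified carrier frequencies. The generator's read model is
#' deliberately simple — uniform-start, fixed-length reads with Poisson counts
#' per bin — so that read-depth CNV calling is exact in expectation and every
#' downstream stage can be validated against planted truth.
#'
#' Planted events are aligned to the window step grid and separated by at least
#' `min_separation` bp so that distinct events never satisfy the CNVR merge
#' gap rule. Deletion carriers are heterozygous (CN=1) or homozygous (CN=0)
#' with `hom_del_fraction` homozygous; duplication carriers get CN=3 or CN=4
#' (CN=4 with probability `hom_dup_fraction`).
#'
#' The last `n_differentiated` events are population-differentiated: carrier
#' frequency `diff_focal_freq` in the focal (last) population and
#' `diff_other_freq` elsewhere, emulating the high-altitude-specific CNVRs a
#' V(ST) scan should recover.
#'
#' @param n_chroms Number of chromosomes (named chr1, chr2, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param window_size,step Window grid passed to [genome_layout()].
#' @param window_gc_profile Optional numeric vector of per-window GC fractions
#'   in `[0,1]`, recycled across the window grid; `NULL` draws a smooth profile.
#' @param n_populations,samples_per_pop Cohort structure.
#' @param mean_depth Mean fold-coverage of a diploid genome (e.g. 15).
#' @param read_length Read length in bp.
#' @param gc_bias_strength Strength of the unimodal multiplicative GC bias
#'   curve peaking at GC = 0.5; 0 disables the bias.
#' @param sample_scale_sd SD of the per-sample log-normal depth scale factor;
#'   0 gives every sample the same library size.
#' @param noise `"poisson"` for Poisson read counts, `"none"` for deterministic
#'   rounded expectations (used to verify exact-recovery identities).
#' @param n_cnvs Number of CNVs to plant.
#' @param cnv_length_range Length range in bp (min must be >= `window_size` so
#'   every event spans at least two windows).
#' @param del_fraction Proportion of planted CNVs that are deletions.
#' @param hom_del_fraction Fraction of deletion carriers that are homozygous.
#' @param hom_dup_fraction Fraction of duplication carriers with CN=4.
#' @param pop_freq_spec Optional `n_cnvs x n_populations` matrix of carrier
#'   frequencies; `NULL` draws each event's frequency uniformly from
#'   `freq_range` (shared across populations) before applying differentiation.
#' @param freq_range Range carrier frequencies are drawn from when
#'   `pop_freq_spec` is `NULL`.
#' @param n_differentiated Number of planted population-differentiated events.
#' @param diff_focal_freq,diff_other_freq Carrier frequencies of differentiated
#'   events in the focal (last) population and in the remaining populations.
#' @param min_separation Minimum distance in bp between planted events.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 2.5e6,
                       window_size = 800L, step = window_size %/% 2L,
                       window_gc_profile = NULL,
                       n_populations = 3L, samples_per_pop = 10L,
                       mean_depth = 15, read_length = 100L,
                       gc_bias_strength = 0.5, sample_scale_sd = 0.1,
                       noise = c("poisson", "none"),
                       n_cnvs = 45L, cnv_length_range = c(1600L, 8000L),
                       del_fraction = 0.5, hom_del_fraction = 0.2,
                       hom_dup_fraction = 0.2,
                       pop_freq_spec = NULL, freq_range = c(0.15, 0.4),
                       n_differentiated = 2L,
                       diff_focal_freq = 0.9, diff_other_freq = 0.02,
                       min_separation = 10000L, seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    window_size = as.integer(window_size), step = as.integer(step),
    window_gc_profile = window_gc_profile,
    n_populations = as.integer(n_populations),
    samples_per_pop = as.integer(samples_per_pop),
    mean_depth = mean_depth, read_length = as.integer(read_length),
    gc_bias_strength = gc_bias_strength, sample_scale_sd = sample_scale_sd,
    noise = noise, n_cnvs = as.integer(n_cnvs),
    cnv_length_range = as.integer(cnv_length_range),
    del_fraction = del_fraction, hom_del_fraction = hom_del_fraction,
    hom_dup_fraction = hom_dup_fraction,
    pop_freq_spec = pop_freq_spec, freq_range = freq_range,
    n_differentiated = as.integer(n_differentiated),
    diff_focal_freq = diff_focal_freq, diff_other_freq = diff_other_freq,
    min_separation = as.integer(min_separation), seed = as.integer(seed)
  )
  chk <- function(ok, field, why) if (!ok) stop(sprintf("sim_config: %s %s", field, why))
  chk(cfg$n_chroms >= 1L, "n_chroms", "must be >= 1")
  chk(cfg$chrom_length > 0, "chrom_length", "must be > 0")
  chk(cfg$mean_depth > 0, "mean_depth", "must be > 0")
  chk(cfg$read_length > 0, "read_length", "must be > 0")
  chk(cfg$n_populations >= 1L, "n_populations", "must be >= 1")
  chk(cfg$samples_per_pop >= 1L, "samples_per_pop", "must be >= 1")
  chk(cfg$n_cnvs >= 0L, "n_cnvs", "must be >= 0")
  chk(all(cfg$cnv_length_range > 0) && cfg$cnv_length_range[1] <= cfg$cnv_length_range[2],
      "cnv_length_range", "must be an increasing positive pair")
  chk(cfg$n_cnvs == 0L || cfg$cnv_length_range[1] >= cfg$window_size,
      "cnv_length_range", "minimum must be >= window_size (events must span >= 2 windows)")
  for (f in c("del_fraction", "hom_del_fraction", "hom_dup_fraction",
              "diff_focal_freq", "diff_other_freq"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0,1]")
  chk(all(cfg$freq_range >= 0 & cfg$freq_range <= 1), "freq_range", "must be in [0,1]")
  if (!is.null(cfg$pop_freq_spec)) {
    chk(is.matrix(cfg$pop_freq_spec) &&
          nrow(cfg$pop_freq_spec) == cfg$n_cnvs &&
          ncol(cfg$pop_freq_spec) == cfg$n_populations,
        "pop_freq_spec", "must be an n_cnvs x n_populations matrix")
    chk(all(cfg$pop_freq_spec >= 0 & cfg$pop_freq_spec <= 1),
        "pop_freq_spec", "frequencies must be in [0,1]")
  }
  cfg$n_differentiated <- min(cfg$n_differentiated, cfg$n_cnvs)
  if (!is.null(cfg$window_gc_profile))
    chk(all(cfg$window_gc_profile >= 0 & cfg$window_gc_profile <= 1),
        "window_gc_profile", "GC fractions must be in [0,1]")
  structure(cfg, class = "sim_config")
}

# Unimodal multiplicative GC bias, peak 1 at GC = 0.5.
gc_bias_curve <- function(gc, strength) exp(-strength * (gc - 0.5)^2 / 0.125)

sample_names_for <- function(cfg) {
  pops <- paste0("pop", seq_len(cfg$n_populations))
  data.table(
    sample = paste0(rep(pops, each = cfg$samples_per_pop), "_s",
                    rep(seq_len(cfg$samples_per_pop), cfg$n_populations)),
    population = rep(pops, each = cfg$samples_per_pop)
  )
}

# Greedy placement of non-overlapping step-aligned intervals.
place_intervals <- function(layout, n, len_range, min_sep, what = "event") {
  if (n == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  step <- layout$step
  chroms <- layout$chroms
  placed <- vector("list", n)
  occupied <- lapply(chroms, function(...) data.table(start = integer(), end = integer()))
  k <- 0L; tries <- 0L; max_tries <- 200L * n
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    ch <- sample(names(chroms), 1L, prob = as.numeric(chroms))
    len <- step * max(2L, round(runif(1, len_range[1], len_range[2]) / step))
    max_start_k <- floor((chroms[[ch]] - len) / step)
    if (max_start_k < 0) next
    start <- step * sample.int(max_start_k + 1L, 1L) - step
    end <- start + len
    occ <- occupied[[ch]]
    if (nrow(occ) && any(start < occ$end + min_sep & end > occ$start - min_sep)) next
    k <- k + 1L
    placed[[k]] <- data.table(chrom = ch, start = as.integer(start), end = as.integer(end))
    occupied[[ch]] <- rbind(occ, placed[[k]][, .(start, end)])
  }
  if (k < n)
    stop(sprintf("could not place %d non-overlapping %ss (genome too small for the requested number/separation)", n, what))
  out <- rbindlist(placed)
  setorder(out, chrom, start)
  out
}

#' Simulate a synthetic cohort with planted CNVs
#'
#' Generates, deterministically under `config$seed`: a window GC track, a set
#' of planted truth CNVs with per-sample integer copy numbers, per-sample read
#' placements, and a sample-to-population map. Per sample, the read count of a
#' step-bin is drawn around
#' `mean_depth * bin_width / read_length * (CN/2) * gc_bias(GC) * sample_scale`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `layout`
#'   ([genome_layout()]), `gc` (data.table chrom/window_start/gc_fraction),
#'   `reads` (named list of data.tables chrom/start/length, one per sample),
#'   `truth` (list: `events` data.table with cnv_id/chrom/start/end/kind/
#'   differentiated, `cn` events x samples integer matrix, `freq` events x
#'   populations carrier-frequency matrix), `sample_map` (data.table
#'   sample/population) and `sample_scales`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chroms <- setNames(rep(config$chrom_length, config$n_chroms),
                       paste0("chr", seq_len(config$n_chroms)))
    layout <- genome_layout(chroms, config$window_size, config$step)
    win <- layout$windows
    nw <- nrow(win)

    # GC track aligned to the window grid
    if (is.null(config$window_gc_profile)) {
      wave <- 0.45 + 0.12 * sin(2 * pi * win$start / 3e5) +
        rnorm(nw, 0, 0.02)
      gc <- pmin(pmax(wave, 0.25), 0.68)
    } else {
      gc <- rep_len(config$window_gc_profile, nw)
    }
    gc_track <- data.table(chrom = win$chrom, window_start = win$start,
                           gc_fraction = gc)

    smap <- sample_names_for(config)
    ns <- nrow(smap)
    pops <- unique(smap$population)

    # Plant truth events
    ev <- place_intervals(layout, config$n_cnvs, config$cnv_length_range,
                          config$min_separation, "CNV")
    n_ev <- nrow(ev)
    if (n_ev) {
      ev[, cnv_id := sprintf("cnv%03d", seq_len(n_ev))]
      ev[, kind := ifelse(runif(n_ev) < config$del_fraction, "deletion", "duplication")]
      ev[, differentiated := FALSE]
      if (config$n_differentiated > 0L)
        ev[sample.int(n_ev, config$n_differentiated), differentiated := TRUE]

      freq <- config$pop_freq_spec
      if (is.null(freq)) {
        base <- runif(n_ev, config$freq_range[1], config$freq_range[2])
        freq <- matrix(rep(base, length(pops)), ncol = length(pops))
      }
      colnames(freq) <- pops
      rownames(freq) <- ev$cnv_id
      focal <- pops[length(pops)]
      freq[ev$differentiated, ] <- config$diff_other_freq
      freq[ev$differentiated, focal] <- config$diff_focal_freq

      cn <- matrix(2L, nrow = n_ev, ncol = ns,
                   dimnames = list(ev$cnv_id, smap$sample))
      for (i in seq_len(n_ev)) {
        carrier <- rbinom(ns, 1L, freq[i, smap$population]) == 1L
        if (ev$kind[i] == "deletion") {
          hom <- runif(ns) < config$hom_del_fraction
          cn[i, carrier] <- ifelse(hom[carrier], 0L, 1L)
        } else {
          four <- runif(ns) < config$hom_dup_fraction
          cn[i, carrier] <- ifelse(four[carrier], 4L, 3L)
        }
      }
    } else {
      ev <- data.table(chrom = character(), start = integer(), end = integer(),
                       cnv_id = character(), kind = character(),
                       differentiated = logical())
      freq <- matrix(numeric(), nrow = 0, ncol = length(pops),
                     dimnames = list(NULL, pops))
      cn <- matrix(integer(), nrow = 0, ncol = ns,
                   dimnames = list(NULL, smap$sample))
    }
    setcolorder(ev, c("cnv_id", "chrom", "start", "end", "kind", "differentiated"))

    scales <- if (config$sample_scale_sd > 0)
      exp(rnorm(ns, 0, config$sample_scale_sd)) else rep(1, ns)
    names(scales) <- smap$sample

    # Per-sample read placement over step-bins (bin b of chrom = [b*step, b*step+step))
    step <- layout$step
    rl <- config$read_length
    half <- rl %/% 2L
    lam_base <- config$mean_depth / rl *
      gc_bias_curve(gc_track$gc_fraction, config$gc_bias_strength)
    # step-bins share the window-start grid; the last bin per chrom may be short
    bin_width <- pmin(step, as.numeric(chroms[win$chrom]) - win$start)

    reads <- vector("list", ns)
    names(reads) <- smap$sample
    for (s in seq_len(ns)) {
      cn_bin <- rep(2, nw)
      if (n_ev) for (i in seq_len(n_ev)) {
        if (cn[i, s] == 2L) next
        hit <- win$chrom == ev$chrom[i] & win$start >= ev$start[i] & win$start < ev$end[i]
        cn_bin[hit] <- cn[i, s]
      }
      lam <- lam_base * bin_width * (cn_bin / 2) * scales[s]
      counts <- if (config$noise == "poisson") rpois(nw, lam) else as.integer(round(lam))
      tot <- sum(counts)
      if (tot == 0L) {
        reads[[s]] <- data.table(chrom = character(), start = integer(),
                                 length = integer())
        next
      }
      bidx <- rep.int(seq_len(nw), counts)
      within <- if (config$noise == "poisson") {
        floor(runif(tot) * bin_width[bidx])
      } else {
        # evenly spaced midpoints so deterministic runs are grid-stable
        unlist(lapply(which(counts > 0L), function(b) {
          floor(((seq_len(counts[b]) - 0.5) / counts[b]) * bin_width[b])
        }), use.names = FALSE)
      }
      mid <- win$start[bidx] + within
      chrom_len <- as.numeric(chroms[win$chrom[bidx]])
      mid <- pmin(pmax(mid, half), chrom_len - (rl - half))
      reads[[s]] <- data.table(chrom = win$chrom[bidx],
                               start = as.integer(mid - half),
                               length = rl)
    }

    structure(
      list(layout = layout, gc = gc_track, reads = reads,
           truth = list(events = ev, cn = cn, freq = freq),
           sample_map = smap, sample_scales = scales, config = config),
      class = "sim_cohort"
    )
  })
}

#' QTL trait categories used throughout the package
#' @export
qtl_categories <- c("reproduction", "production", "meat_carcass",
                    "milk", "exterior", "health")

#' Simulate gene models and QTL intervals
#'
#' Genes are non-overlapping intervals, each with 1-5 exons strictly inside the
#' gene span; QTLs are (possibly overlapping) intervals carrying one of the six
#' livestock trait categories in [qtl_categories].
#'
#' @param layout A [genome_layout()].
#' @param n_genes,n_qtls Counts of features to draw.
#' @param seed Integer seed.
#' @param gene_length_range,qtl_length_range Feature length ranges in bp.
#' @return List with data.tables `genes` (gene_id, chrom, start, end, biotype),
#'   `exons` (gene_id, chrom, start, end) and `qtls` (qtl_id, chrom, start,
#'   end, category, trait_name).
#' @export
simulate_annotations <- function(layout, n_genes, n_qtls, seed = 1L,
                                 gene_length_range = c(5000L, 30000L),
                                 qtl_length_range = c(20000L, 100000L)) {
  stopifnot(inherits(layout, "genome_layout"), nrow(layout$windows) > 0)
  with_seed(seed, {
    genes <- place_intervals(layout, n_genes, gene_length_range, 0L, "gene")
    if (n_genes > 0L) {
      genes[, gene_id := sprintf("gene%04d", seq_len(.N))]
      genes[, biotype := "protein_coding"]
      exons <- genes[, {
        n_ex <- sample.int(5L, 1L)
        len <- end - start
        # cut the span into 2*n_ex+1 alternating segments, exons strictly inside
        cuts <- sort(sample.int(len - 2L, 2L * n_ex)) + start
        data.table(start = cuts[seq(1L, 2L * n_ex, by = 2L)],
                   end = cuts[seq(2L, 2L * n_ex, by = 2L)])
      }, by = .(gene_id, chrom)]
      exons <- exons[end > start]
    } else {
      genes <- data.table(chrom = character(), start = integer(), end = integer(),
                          gene_id = character(), biotype = character())
      exons <- data.table(gene_id = character(), chrom = character(),
                          start = integer(), end = integer())
    }
    setcolorder(genes, c("gene_id", "chrom", "start", "end", "biotype"))

    if (n_qtls > 0L) {
      ch <- sample(names(layout$chroms), n_qtls, replace = TRUE,
                   prob = as.numeric(layout$chroms))
      len <- round(runif(n_qtls, qtl_length_range[1], qtl_length_range[2]))
      maxs <- pmax(1, as.numeric(layout$chroms[ch]) - len)
      start <- floor(runif(n_qtls) * maxs)
      cat_i <- qtl_categories[((seq_len(n_qtls) - 1L) %% length(qtl_categories)) + 1L]
      cat_i <- sample(cat_i)  # balanced but shuffled category assignment
      qtls <- data.table(qtl_id = sprintf("qtl%04d", seq_len(n_qtls)),
                         chrom = ch, start = as.integer(start),
                         end = as.integer(start + len), category = cat_i,
                         trait_name = paste0(cat_i, "_trait_", seq_len(n_qtls)))
      setorder(qtls, chrom, start)
    } else {
      qtls <- data.table(qtl_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         category = character(), trait_name = character())
    }
    list(genes = genes, exons = exons, qtls = qtls)
  })
}

#' Simulate qPCR Ct tables for planted CNVs
#'
#' Generates replicate Ct values such that ideal inversion of the
#' `2 x 2^-ddCt` formula recovers the planted copy number: the target-assay Ct
#' is `target_base_ct - log2(CN/2)` plus noise, and the reference-gene Ct is
#' constant up to noise. CN=0 samples (no template) are assigned the cycling
#' limit `max_ct`. One CN=2 sample per CNVR is flagged as the calibrator
#' ("standard sample"); its absence is an error.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param samples Character vector of samples to assay.
#' @param cnvr_ids Which truth events to assay (default: all).
#' @param ct_noise_sd Ct noise SD in cycles (0 = ideal chemistry).
#' @param n_replicates Technical replicates per sample and assay (default 3).
#' @param target_base_ct,reference_ct Baseline Ct of the target assay at CN=2
#'   and of the reference gene.
#' @param max_ct Cycling limit used for CN=0 (no amplification).
#' @param seed Integer seed.
#' @return Long-format data.table: cnvr_id, sample, role
#'   (`target`/`reference`), replicate, ct, is_calibrator, true_cn.
#' @export
simulate_qpcr <- function(truth, samples, cnvr_ids = NULL, ct_noise_sd = 0,
                          n_replicates = 3L, target_base_ct = 25,
                          reference_ct = 20, max_ct = 40, seed = 1L) {
  ev_ids <- cnvr_ids %||% truth$events$cnv_id
  stopifnot(all(ev_ids %in% rownames(truth$cn)),
            all(samples %in% colnames(truth$cn)))
  with_seed(seed, {
    out <- lapply(ev_ids, function(id) {
      cns <- truth$cn[id, samples]
      calib <- samples[which(cns == 2L)[1]]
      if (is.na(calib))
        stop(sprintf("simulate_qpcr: no CN=2 calibrator sample available for %s", id))
      ideal_target <- ifelse(cns == 0, max_ct, target_base_ct - log2(cns / 2))
      n <- length(samples) * n_replicates
      data.table(
        cnvr_id = id,
        sample = rep(samples, each = n_replicates),
        role = rep(c("target", "reference"), each = n),
        replicate = rep(seq_len(n_replicates), length(samples)),
        ct = c(rep(ideal_target, each = n_replicates) + rnorm(n, 0, ct_noise_sd),
               rep(reference_ct, n) + rnorm(n, 0, ct_noise_sd)),
        is_calibrator = rep(samples == calib, each = n_replicates),
        true_cn = rep(as.integer(cns), each = n_replicates)
      )
    })
    rbindlist(out)
  })
}
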