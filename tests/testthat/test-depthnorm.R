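test_that("reads are assigned to every window containing their midpoint", {
  gl <- genome_layout(c(chr1 = 1200), window_size = 800L, step = 400L)
  # windows: [0,800) [400,1200) [800,1200)
  reads <- list(s1 = data.frame(chrom = "chr1", start = 850L, length = 100L))
  dm <- compute_window_depth(reads, gl)  # midpoint 900
  expect_equal(as.vector(dm$raw), c(0L, 1L, 1L))

  # midpoint exactly on a window start boundary belongs to that window
  reads2 <- list(s1 = data.frame(chrom = "chr1", start = 350L, length = 100L))
  dm2 <- compute_window_depth(reads2, gl)  # midpoint 400
  expect_equal(as.vector(dm2$raw), c(1L, 1L, 0L))
  reads0 <- list(s1 = data.frame(chrom = "chr1", start = -50L, length = 100L))
  dm0 <- compute_window_depth(reads0, gl)  # midpoint 0
  expect_equal(as.vector(dm0$raw), c(1L, 0L, 0L))
})

test_that("zero-row tables give zero counts but absent tables error by name", {
  gl <- genome_layout(c(chr1 = 1200))
  empty <- data.frame(chrom = character(), start = integer(), length = integer())
  dm <- compute_window_depth(list(s1 = empty), gl)
  expect_true(all(dm$raw == 0L))
  expect_error(compute_window_depth(list(bad_sample = NULL), gl), "bad_sample")
})

test_that("reads on chromosomes outside the layout are dropped and reported", {
  gl <- genome_layout(c(chr1 = 1200))
  reads <- list(s1 = data.frame(chrom = c("chr1", "scaffold_7"),
                                start = c(100L, 100L), length = 100L))
  expect_warning(dm <- compute_window_depth(reads, gl), "dropped")
  expect_equal(unname(dm$dropped["s1"]), 1L)
  expect_equal(sum(dm$raw), 1L)  # midpoint 150 is only inside [0,800)
})

test_that("uniform GC leaves counts unchanged; a 2x GC bias is flattened", {
  gl <- genome_layout(c(chr1 = 80000), window_size = 800L, step = 400L)
  nw <- nrow(gl$windows)
  counts <- matrix(100L, nrow = nw, ncol = 1, dimnames = list(NULL, "s1"))
  dm <- structure(list(layout = gl, samples = "s1", raw = counts),
                  class = "depth_matrix")
  gc_u <- data.frame(chrom = "chr1", window_start = gl$windows$start,
                     gc_fraction = 0.5)
  expect_equal(gc_normalize(dm, gc_u)$gc_corrected[, 1], counts[, 1])

  # two GC classes, high-GC windows at exactly twice the depth
  gc2 <- rep(c(0.3, 0.7), length.out = nw)
  counts2 <- matrix(ifelse(gc2 > 0.5, 200, 100), ncol = 1,
                    dimnames = list(NULL, "s1"))
  dm2 <- structure(list(layout = gl, samples = "s1", raw = counts2),
                   class = "depth_matrix")
  gt2 <- data.frame(chrom = "chr1", window_start = gl$windows$start,
                    gc_fraction = gc2)
  corr <- gc_normalize(dm2, gt2)$gc_corrected[, 1]
  expect_equal(median(corr[gc2 < 0.5]), median(corr[gc2 > 0.5]))

  gt_bad <- within(gt2, gc_fraction[1] <- 1.4)
  expect_error(gc_normalize(dm2, gt_bad), "\\[0,1\\]")
})

test_that("GC correction is idempotent", {
  dm <- zero_noise_dm()
  co <- zero_noise_cohort()
  once <- dm$gc_corrected
  dm2 <- compute_window_depth(co$reads, co$layout)
  dm2$raw <- once
  twice <- gc_normalize(dm2, co$gc)$gc_corrected
  expect_equal(twice, once, tolerance = 0)
})

test_that("an all-zero sample is passed through with a warning", {
  gl <- genome_layout(c(chr1 = 80000))
  nw <- nrow(gl$windows)
  raw <- matrix(0L, nrow = nw, ncol = 1, dimnames = list(NULL, "s1"))
  dm <- structure(list(layout = gl, samples = "s1", raw = raw),
                  class = "depth_matrix")
  gt <- data.frame(chrom = "chr1", window_start = gl$windows$start,
                   gc_fraction = 0.5)
  expect_warning(out <- gc_normalize(dm, gt), "all-zero")
  expect_true(all(out$gc_corrected == 0))
})

test_that("normalization pins the diploid baseline at exactly 1", {
  dm <- zero_noise_dm()
  med <- apply(dm$normalized[dm$window_mask, ], 2, median)
  expect_true(all(abs(med - 1) <= 0.05))
  expect_true(all(dm$normalized >= 0))
})

test_that("normalization is exactly invariant to a per-sample scale factor", {
  co <- zero_noise_cohort()
  dm <- compute_window_depth(co$reads, co$layout)
  dm_s <- dm
  dm_s$raw[, 2] <- dm_s$raw[, 2] * 3L
  n1 <- sample_normalize(gc_normalize(dm, co$gc))
  n2 <- sample_normalize(gc_normalize(dm_s, co$gc))
  expect_identical(n1$window_mask, n2$window_mask)
  expect_equal(n2$normalized, n1$normalized, tolerance = 0)
})

test_that("on noise-free data normalized depth equals CN/2 exactly", {
  co <- zero_noise_cohort()
  dm <- zero_noise_dm()
  tw <- truth_cn_by_window(co)
  check <- dm$window_mask & !tw$boundary
  expect_true(any(tw$cn[check, ] != 2))  # the planted signal is in scope
  expect_true(all(dm$normalized[check, ] == tw$cn[check, ] / 2))
})

test_that("a planted CN=4 region sits at normalized depth 2", {
  cfg <- zero_noise_config(seed = 77L, n_cnvs = 2L)
  cfg$del_fraction <- 0; cfg$hom_dup_fraction <- 1  # all CN=4 duplications
  co <- simulate_cohort(cfg)
  dm <- sample_normalize(gc_normalize(compute_window_depth(co$reads, co$layout), co$gc))
  ev <- co$truth$events[1]
  carrier <- names(which(co$truth$cn[1, ] == 4L))[1]
  expect_false(is.na(carrier))  # frozen seed guarantees a carrier
  win <- co$layout$windows
  inside <- win$chrom == ev$chrom & win$start >= ev$start & win$end <= ev$end
  expect_equal(unique(dm$normalized[inside & dm$window_mask, carrier]), 2)
})

test_that("a sample with zero median depth is rejected by name", {
  gl <- genome_layout(c(chr1 = 80000))
  nw <- nrow(gl$windows)
  raw <- cbind(ok = rep(100L, nw), dead = 0L)
  dm <- structure(list(layout = gl, samples = colnames(raw), raw = raw),
                  class = "depth_matrix")
  gt <- data.frame(chrom = "chr1", window_start = gl$windows$start,
                   gc_fraction = 0.5)
  suppressWarnings(dmg <- gc_normalize(dm, gt))
  expect_error(sample_normalize(dmg), "dead")
})
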