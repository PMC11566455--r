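# Build a depth_matrix with an explicit normalized layer on a w=800/step=400
# grid with exactly nrow(nd) windows (chrom length = 400 * nrow).
flat_dm <- function(nd) {
  gl <- genome_layout(c(chr1 = 400L * nrow(nd)), window_size = 800L, step = 400L)
  stopifnot(nrow(gl$windows) == nrow(nd))
  make_dm(nd, gl)
}
col1 <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "s1"))

test_that("window states follow the depth thresholds with half-open bounds", {
  dm <- flat_dm(col1(c(1.0, 0.5, 0.19, 0.20, 1.3, 1.31, 0.7, 0.69)))
  st <- call_window_states(dm)[, 1]
  expect_equal(st, c("neutral", "het_del", "hom_del", "het_del",
                     "neutral", "dup", "neutral", "het_del"))
  expect_error(call_window_states(dm, lower = 0.8), "thresholds")
})

test_that("masked windows never produce states", {
  dm <- flat_dm(col1(rep(0.1, 4)))
  dm$window_mask[2] <- FALSE
  st <- call_window_states(dm)
  expect_true(is.na(st[2, 1]))
  calls <- segment_sample_cnvs(st, dm)
  expect_equal(calls$n_windows, 3L)  # masked window bridged as a gap
})

test_that("segmentation bridges small gaps and separates directions", {
  # [del, del, neutral, del] with max_gap_windows = 1 -> one call over all 4
  dm <- flat_dm(col1(c(0.5, 0.5, 1.0, 0.5, 1, 1)))
  calls <- segment_sample_cnvs(call_window_states(dm), dm)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 0L)
  expect_equal(calls$end, dm$layout$windows$end[4])
  expect_equal(calls$n_windows, 3L)
  expect_equal(calls$state, "het_del")

  # a single dup window is dropped at min_windows = 2
  dm2 <- flat_dm(col1(c(1, 1.5, 1, 1, 1, 1)))
  expect_equal(nrow(segment_sample_cnvs(call_window_states(dm2), dm2)), 0L)

  # adjacent opposite directions never merge into one call
  dm3 <- flat_dm(col1(c(0.5, 0.5, 1.5, 1.5, 1, 1)))
  calls3 <- segment_sample_cnvs(call_window_states(dm3), dm3)
  expect_equal(nrow(calls3), 2L)
  expect_setequal(calls3$state, c("het_del", "dup"))

  # a gap of 2 neutral windows splits the run at max_gap_windows = 1
  dm4 <- flat_dm(col1(c(0.5, 0.5, 1, 1, 0.5, 0.5)))
  expect_equal(nrow(segment_sample_cnvs(call_window_states(dm4), dm4)), 2L)
})

test_that("deletion runs are restated from the segment mean depth", {
  dm <- flat_dm(col1(c(0.1, 0.1, 0.1, 0.4, 1, 1)))   # mean 0.175 -> hom
  calls <- segment_sample_cnvs(call_window_states(dm), dm)
  expect_equal(calls$state, "hom_del")
  dm2 <- flat_dm(col1(c(0.15, 0.5, 0.5, 0.5, 1, 1))) # mean 0.4125 -> het
  calls2 <- segment_sample_cnvs(call_window_states(dm2), dm2)
  expect_equal(calls2$state, "het_del")
})

test_that("identical calls from different samples merge into one CNVR", {
  nd <- matrix(1, nrow = 10, ncol = 4, dimnames = list(NULL, paste0("s", 1:4)))
  nd[2:3, 1:2] <- 0.5  # two carriers over the same windows
  dm <- flat_dm(nd)
  calls <- segment_sample_cnvs(call_window_states(dm), dm)
  expect_equal(nrow(calls), 2L)
  cnvrs <- merge_to_cnvrs(calls, dm)
  expect_equal(nrow(cnvrs), 1L)
  expect_equal(cnvrs$n_carriers, 2L)
  expect_equal(cnvrs$type, "deletion")
})

test_that("the 20% gap rule plus correlated depth merges nearby calls", {
  # calls at [0,1000) and [1300,2300): gap 300 < 0.2 * 2000 = 400
  calls <- data.table::data.table(
    sample = c("s1", "s2"), chrom = "chr1",
    start = c(0L, 1300L), end = c(1000L, 2300L),
    state = "het_del", mean_norm_depth = 0.5, n_windows = 2L)
  # per-sample depth profile constant along the genome -> the two regions'
  # depth vectors are identical across samples -> r = 1, p < 0.01
  prof <- c(0.5, 0.6, 0.9, 1.0)
  nd <- matrix(rep(prof, each = 10), nrow = 10,
               dimnames = list(NULL, paste0("s", 1:4)))
  dm <- flat_dm(nd)
  merged <- merge_to_cnvrs(calls, dm)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 0L)
  expect_equal(merged$end, 2300L)

  # same geometry but uncorrelated depth vectors: no merge
  set.seed(401)  # frozen seed; the premise is asserted below
  nd2 <- matrix(runif(10 * 4, 0.8, 1.2), nrow = 10,
                dimnames = list(NULL, paste0("s", 1:4)))
  dm2 <- flat_dm(nd2)
  v1 <- nd2[1, ]                 # windows contained in [0,1000)
  v2 <- colMeans(nd2[3:6, ])     # windows overlapping [1300,2300)
  expect_gte(stats::cor.test(v1, v2)$p.value, 0.01)
  expect_equal(nrow(merge_to_cnvrs(calls, dm2)), 2L)

  # gap 500 >= 0.2 * 2000: never merged even when perfectly correlated
  calls3 <- data.table::copy(calls)
  calls3[2, `:=`(start = 1500L, end = 2500L)]
  expect_equal(nrow(merge_to_cnvrs(calls3, dm)), 2L)
})

test_that("merge significance agrees with cor.test's t test on r", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(rdcnv:::pearson_p(x, y), stats::cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("merging with fewer than 4 samples falls back to the gap rule", {
  nd <- matrix(1, nrow = 10, ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  nd[2:3, ] <- 0.5
  dm <- flat_dm(nd)
  calls <- segment_sample_cnvs(call_window_states(dm), dm)
  expect_warning(cnvrs <- merge_to_cnvrs(calls, dm), "fewer than 4")
  expect_equal(nrow(cnvrs), 1L)
})

test_that("merging is a fixed point of itself", {
  rep <- study_report()
  refit <- merge_to_cnvrs(rep$cnvrs, rep$dm, rep$params$merge_gap_fraction,
                          rep$params$corr_alpha)
  expect_equal(nrow(refit), nrow(rep$cnvrs))
  data.table::setorder(refit, chrom, start)
  expect_equal(refit[, .(chrom, start, end, n_carriers)],
               rep$cnvrs[order(chrom, start), .(chrom, start, end, n_carriers)])
})

test_that("CNVR type classification covers all carrier mixes", {
  expect_equal(classify_cnvr_type(c("het_del", "hom_del")), "deletion")
  expect_equal(classify_cnvr_type(c("dup", "dup")), "duplication")
  expect_equal(classify_cnvr_type(c("het_del", "dup")), "mixed")
  expect_error(classify_cnvr_type(character()), "no carriers")
  expect_error(classify_cnvr_type(c("het_del", "neutral")), "non-CNV state")
})

test_that("the carrier and placement filters drop what they must", {
  regions <- data.table::data.table(
    id = c("a", "b", "c"), chrom = c("chr1", "chr1", "scaffold_12"),
    start = c(0L, 0L, 0L), end = c(2000L, 2000L, 2000L),
    type = "deletion", n_carriers = c(1L, 3L, 5L),
    carriers = list("s1", c("s1", "s2", "s3"), c("s1", "s2", "s3", "s4", "s5")),
    states = list("het_del", rep("het_del", 3), rep("het_del", 5)))
  kept <- filter_cnvrs(regions, min_samples = 2L, placed_chroms = "chr1")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_carriers, 3L)
  # the strict "more than two samples" reading
  expect_equal(nrow(filter_cnvrs(regions, min_samples = 3L)), 2L)
  expect_equal(nrow(filter_cnvrs(regions[0])), 0L)
})

test_that("filtered CNVRs respect the carrier floor and types partition", {
  rep <- study_report()
  expect_true(all(rep$cnvrs$n_carriers >= rep$params$min_samples))
  expect_equal(sum(rep$cnvrs$type == "deletion") +
                 sum(rep$cnvrs$type == "duplication") +
                 sum(rep$cnvrs$type == "mixed"),
               nrow(rep$cnvrs))
})
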