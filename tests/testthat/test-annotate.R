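simple_genes <- function() {
  list(genes = data.table::data.table(gene_id = "g1", chrom = "chr1",
                                      start = 10000L, end = 30000L,
                                      biotype = "protein_coding"),
       exons = data.table::data.table(gene_id = "g1", chrom = "chr1",
                                      start = c(12000L, 25000L),
                                      end = c(13000L, 26000L)))
}
reg <- function(id, chrom, start, end)
  data.table::data.table(id = id, chrom = chrom, start = as.integer(start),
                         end = as.integer(end))

test_that("genic context applies exonic > intronic > intergenic precedence", {
  g <- simple_genes()
  r <- rbind(reg("intron", "chr1", 14000, 16000),     # inside gene, no exon
             reg("exon_span", "chr1", 12500, 14000),  # crosses an exon edge
             reg("outside", "chr1", 50000, 52000),    # clear of the gene
             reg("otherchr", "chr2", 12000, 16000))
  ctx <- genic_context(r, g)
  expect_equal(ctx$genic_context,
               c("exonic", "intronic", "intergenic", "intergenic")[c(2, 1, 3, 4)])
  # empty gene set -> everything intergenic
  g0 <- list(genes = g$genes[0], exons = g$exons[0])
  expect_true(all(genic_context(r, g0)$genic_context == "intergenic"))
  # malformed interval names the record
  bad <- reg("broken", "chr1", 5000, 5000)
  expect_error(genic_context(bad, g), "broken")
})

test_that("genic context labels partition the CNVR set", {
  rep <- study_report()
  tab <- rep$annotation$genic
  expect_equal(sum(tab$N), nrow(rep$cnvrs))
  expect_setequal(tab$genic_context, c("exonic", "intronic", "intergenic"))
})

test_that("size bins are half-open kb intervals with half-up percentages", {
  r <- reg(paste0("r", 1:4), "chr1", 0, c(1500, 3000, 7000, 20000))
  sd <- size_distribution(r)
  expect_equal(sd$n, c(0L, 1L, 1L, 1L, 1L))
  expect_equal(sd$pct, c(0, 25, 25, 25, 25))
  # single region -> its bin gets 100%
  one <- size_distribution(reg("a", "chr1", 0, 2500))
  expect_equal(one[bin == "2-5 kb", pct], 100)
  # a sub-kb region lands in the overflow bin with a warning
  expect_warning(sd2 <- size_distribution(reg("tiny", "chr1", 0, 500)), "overflow")
  expect_equal(sd2[bin == "<1 kb", n], 1L)
  # empty input flagged
  sd0 <- size_distribution(reg(character(), character(), integer(), integer()))
  expect_true(all(sd0$n == 0L))
  expect_true(isTRUE(attr(sd0, "empty")))
})

test_that("boundary lengths fall on the half-open side", {
  r <- reg(c("a", "b"), "chr1", 0, c(2000, 5000))  # exactly 2 kb and 5 kb
  sd <- size_distribution(r)
  expect_equal(sd[bin == "2-5 kb", n], 1L)   # the 2 kb region
  expect_equal(sd[bin == "5-10 kb", n], 1L)  # the 5 kb region
})

test_that("breed sharing produces all Venn cells and they partition", {
  smap <- data.frame(sample = c("a1", "a2", "b1", "b2", "c1"),
                     population = c("A", "A", "B", "B", "C"))
  regions <- data.table::data.table(
    id = c("r1", "r2", "r3"), chrom = "chr1",
    start = c(0L, 5000L, 10000L), end = c(2000L, 7000L, 12000L),
    type = "deletion", n_carriers = c(1L, 3L, 2L),
    carriers = list("a1", c("a1", "b1", "c1"), c("b1", "b2")),
    states = list("het_del", rep("het_del", 3), rep("het_del", 2)))
  sh <- breed_sharing(regions, smap)
  expect_equal(nrow(sh$venn), 2^3 - 1)
  expect_equal(sum(sh$venn$n), nrow(regions))        # cells partition
  expect_equal(unname(sh$unique_counts["A"]), 1L)    # r1
  expect_equal(unname(sh$unique_counts["B"]), 1L)    # r3
  expect_equal(sh$venn[populations == "A+B+C", n], 1L)  # r2
  regions$carriers[[1]] <- "ghost"
  expect_error(breed_sharing(regions, smap), "ghost")
})

test_that("QTL overlap counts CNVRs and category shares of QTL hits", {
  qtls <- data.table::data.table(
    qtl_id = c("q1", "q2", "q3"), chrom = "chr1",
    start = c(0L, 500L, 100000L), end = c(1000L, 1500L, 110000L),
    category = c("milk", "health", "milk"), trait_name = "t")
  r <- reg(c("r1", "r2"), "chr1", c(800, 50000), c(1200, 52000))
  ov <- qtl_overlap(r, qtls)
  expect_equal(ov$summary$n_overlapping, 1L)       # only r1 hits QTLs
  expect_equal(ov$summary$pct_overlapping, 50)
  expect_equal(ov$summary$n_qtls_hit, 2L)          # q1 and q2
  expect_equal(ov$by_category[category == "milk", pct], 50)
  expect_equal(ov$by_category[category == "health", pct], 50)
  # disjoint sets
  ov0 <- qtl_overlap(reg("x", "chr2", 0, 1000), qtls)
  expect_equal(ov0$summary$n_overlapping, 0L)
  expect_equal(ov0$summary$n_qtls_hit, 0L)
  # one CNVR inside one milk QTL
  ov1 <- qtl_overlap(reg("y", "chr1", 101000, 102000), qtls)
  expect_equal(ov1$summary$pct_overlapping, 100)
  expect_equal(ov1$by_category[category == "milk", pct], 100)
  qtls_bad <- data.table::copy(qtls)[1, category := "growth"]
  expect_error(qtl_overlap(r, qtls_bad), "growth")
})

test_that("cross-study CNVR comparison reports overlap ratio in percent", {
  a <- reg(paste0("a", 1:4), "chr1", c(0, 10000, 20000, 30000),
           c(2000, 12000, 22000, 32000))
  b <- reg("b1", "chr1", 1000, 1500)
  cmp <- compare_cnvr_sets(a, b)
  expect_equal(cmp$n_overlapping, 1L)
  expect_equal(cmp$ratio_pct, 25)
  expect_equal(compare_cnvr_sets(a, a)$ratio_pct, 100)
  far <- reg("f", "chr2", 0, 1000)
  expect_equal(compare_cnvr_sets(a, far)$n_overlapping, 0L)
  expect_error(compare_cnvr_sets(a[0], b), "empty")
  # reciprocal-overlap option: 500/2000 = 25% of a1 but 100% of b1
  expect_equal(compare_cnvr_sets(a, b, reciprocal = 0.5)$n_overlapping, 0L)
  expect_equal(compare_cnvr_sets(a, b, reciprocal = 0.2)$n_overlapping, 1L)
})

test_that("interval operations agree with a brute-force pairwise scan", {
  set.seed(99)
  for (rep_i in 1:3) {
    a <- random_regions(150)
    b <- random_regions(80)
    bf <- brute_overlaps(a, b)
    cmp <- compare_cnvr_sets(a, b)
    expect_equal(cmp$n_overlapping, length(unique(bf[, 1])))
    # genic context vs brute force with b as single-exon genes
    genes <- list(
      genes = data.table::data.table(gene_id = b$id, chrom = b$chrom,
                                     start = b$start, end = b$end,
                                     biotype = "protein_coding"),
      exons = data.table::data.table(gene_id = b$id, chrom = b$chrom,
                                     start = b$start, end = b$end))
    ctx <- genic_context(a, genes)
    hit <- seq_len(nrow(a)) %in% bf[, 1]
    expect_equal(ctx$genic_context == "exonic", hit)
    # QTL overlap vs brute force
    qt <- data.table::data.table(qtl_id = b$id, chrom = b$chrom,
                                 start = b$start, end = b$end,
                                 category = "milk", trait_name = "t")
    ov <- qtl_overlap(a, qt)
    expect_equal(ov$summary$n_overlapping, length(unique(bf[, 1])))
    expect_equal(ov$summary$n_qtls_hit, length(unique(bf[, 2])))
  }
})
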