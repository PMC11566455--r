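#' Genic-context classification of CNVRs
#'
#' Labels each CNVR `exonic` if it intersects any exon (>= 1 bp), otherwise
#' `intronic` if it intersects any gene body, otherwise `intergenic` — a
#' single-label precedence (exonic > intronic > intergenic) so the three
#' classes partition the CNVR set.
#'
#' @param regions CNVR table (needs `id`, `chrom`, `start`, `end`).
#' @param genes Gene-model list with data.tables `genes` (gene_id, chrom,
#'   start, end) and `exons` (gene_id, chrom, start, end), e.g. from
#'   [simulate_annotations()] or [read_gene_models_bed12()].
#' @return data.table `id`, `genic_context`.
#' @export
genic_context <- function(regions, genes) {
  if (!nrow(regions))
    return(data.table(id = character(), genic_context = character()))
  if (any(regions$end <= regions$start))
    stop(sprintf("malformed interval(s): %s",
                 paste(regions$id[regions$end <= regions$start], collapse = ", ")))
  ctx <- rep("intergenic", nrow(regions))
  lv <- unique(c(regions$chrom, genes$genes$chrom, genes$exons$chrom))
  gr <- to_granges(regions$chrom, regions$start, regions$end, lv)
  if (nrow(genes$exons)) {
    ex <- to_granges(genes$exons$chrom, genes$exons$start, genes$exons$end, lv)
    ctx[overlapsAny(gr, ex)] <- "exonic"
  }
  if (nrow(genes$genes)) {
    gb <- to_granges(genes$genes$chrom, genes$genes$start, genes$genes$end, lv)
    ctx[ctx == "intergenic" & overlapsAny(gr, gb)] <- "intronic"
  }
  data.table(id = regions$id, genic_context = ctx)
}

#' Size distribution of CNVRs
#'
#' Bins CNVR lengths into half-open kb bins (default 1-2, 2-5, 5-10, >10 kb).
#' Regions shorter than the smallest edge land in an explicit `<1 kb` overflow
#' bin with a warning.
#'
#' @param regions CNVR table.
#' @param bin_edges_kb Increasing bin edges in kb, last may be `Inf`.
#' @return data.table `bin`, `n`, `pct` (percent of total, half-up 2 dp;
#'   reported as 0 with attribute `empty = TRUE` on empty input).
#' @export
size_distribution <- function(regions, bin_edges_kb = c(1, 2, 5, 10, Inf)) {
  stopifnot(length(bin_edges_kb) >= 2, !is.unsorted(bin_edges_kb))
  lab <- function(lo, hi) if (is.infinite(hi)) sprintf(">%g kb", lo)
                          else sprintf("%g-%g kb", lo, hi)
  labels <- c(sprintf("<%g kb", bin_edges_kb[1]),
              mapply(lab, head(bin_edges_kb, -1), tail(bin_edges_kb, -1)))
  if (!nrow(regions)) {
    out <- data.table(bin = labels, n = 0L, pct = 0)
    setattr(out, "empty", TRUE)
    return(out)
  }
  len_kb <- (regions$end - regions$start) / 1000
  if (any(len_kb <= 0)) stop("all region lengths must be > 0")
  idx <- findInterval(len_kb, bin_edges_kb) + 1L  # 1 = overflow "<min" bin
  if (any(idx == 1L))
    warning(sprintf("%d region(s) shorter than %g kb counted in the overflow bin",
                    sum(idx == 1L), bin_edges_kb[1]))
  n <- tabulate(idx, nbins = length(labels))
  data.table(bin = labels, n = n, pct = pct_of(n, nrow(regions)))
}

#' Breed/population sharing of CNVRs (Venn cells)
#'
#' A CNVR belongs to a population iff at least one of its carriers belongs to
#' it; "unique to P" means it belongs to P and no other population. Returns
#' all `2^k - 1` Venn cells for `k` populations; the cells partition the CNVR
#' set.
#'
#' @param regions CNVR table with `carriers` list-column.
#' @param sample_map data.frame `sample`, `population`.
#' @return List: `venn` (data.table `populations` (cell label, `+`-joined),
#'   `n`), `unique_counts` (named vector, CNVRs unique to each population),
#'   `membership` (data.table `id`, `populations`).
#' @export
breed_sharing <- function(regions, sample_map) {
  smap <- as.data.table(sample_map)
  pops <- sort(unique(smap$population))
  pop_of <- setNames(smap$population, smap$sample)
  cells <- vapply(seq_len(nrow(regions)), function(i) {
    car <- regions$carriers[[i]]
    miss <- setdiff(car, names(pop_of))
    if (length(miss))
      stop(sprintf("carrier sample(s) not in sample map: %s",
                   paste(miss, collapse = ", ")))
    paste(sort(unique(pop_of[car])), collapse = "+")
  }, character(1))
  all_cells <- unlist(lapply(seq_along(pops), function(k)
    utils::combn(pops, k, paste, collapse = "+", simplify = FALSE)))
  venn <- data.table(populations = all_cells,
                     n = as.integer(table(factor(cells, levels = all_cells))))
  uniq <- setNames(venn[populations %in% pops, n], pops)
  list(venn = venn, unique_counts = uniq,
       membership = data.table(id = regions$id, populations = cells))
}

#' Overlap CNVRs with QTL intervals
#'
#' A CNVR overlaps a QTL iff the intersection is at least 1 bp. Reports the
#' number and percentage of CNVRs hitting any QTL, the number of distinct QTLs
#' hit, and the per-trait-category share of those QTL hits (a QTL is counted
#' in its own category; one CNVR can hit QTLs of several categories, so
#' category percentages are shares of QTL hits, not of CNVRs).
#'
#' @param regions CNVR table.
#' @param qtls QTL data.table (`qtl_id`, `chrom`, `start`, `end`, `category`).
#' @return List: `summary` (n_cnvrs_total, n_overlapping, pct_overlapping,
#'   n_qtls_hit), `by_category` (data.table category, n_qtls, pct of QTL
#'   hits), `hits` (data.table id, qtl_id, category).
#' @export
qtl_overlap <- function(regions, qtls) {
  bad <- setdiff(unique(qtls$category), qtl_categories)
  if (length(bad))
    stop(sprintf("unknown QTL category label(s): %s", paste(bad, collapse = ", ")))
  if (!nrow(regions) || !nrow(qtls)) {
    hits <- data.table(id = character(), qtl_id = character(),
                       category = character())
  } else {
    lv <- unique(c(regions$chrom, qtls$chrom))
    gr <- to_granges(regions$chrom, regions$start, regions$end, lv)
    gq <- to_granges(qtls$chrom, qtls$start, qtls$end, lv)
    ov <- GenomicRanges::findOverlaps(gr, gq)
    hits <- data.table(id = regions$id[S4Vectors::queryHits(ov)],
                       qtl_id = qtls$qtl_id[S4Vectors::subjectHits(ov)],
                       category = qtls$category[S4Vectors::subjectHits(ov)])
  }
  n_total <- nrow(regions)
  n_over <- length(unique(hits$id))
  qtl_hits <- unique(hits[, .(qtl_id, category)])
  n_qtls <- nrow(qtl_hits)
  by_cat <- qtl_hits[, .(n_qtls = .N), by = category]
  by_cat <- merge(data.table(category = qtl_categories), by_cat,
                  by = "category", all.x = TRUE, sort = FALSE)
  by_cat[is.na(n_qtls), n_qtls := 0L]
  by_cat$pct <- if (n_qtls > 0) pct_of(by_cat$n_qtls, n_qtls) else rep(0, nrow(by_cat))
  list(
    summary = data.table(n_cnvrs_total = n_total, n_overlapping = n_over,
                         pct_overlapping = if (n_total > 0) pct_of(n_over, n_total) else 0,
                         n_qtls_hit = n_qtls),
    by_category = by_cat[],
    hits = hits
  )
}

#' Compare two CNVR sets by interval overlap
#'
#' Counts the regions of `set_a` intersecting at least one region of `set_b`
#' by at least `min_overlap_bp`, and the overlap ratio as a percentage of
#' `|set_a|` — the cross-study comparison statistic. Optionally requires a
#' reciprocal overlap fraction instead of a fixed bp threshold.
#'
#' @param set_a,set_b CNVR tables (`chrom`, `start`, `end`).
#' @param min_overlap_bp Minimum intersection width in bp (default 1).
#' @param reciprocal Optional reciprocal-overlap fraction in (0,1]; when set,
#'   a pair counts only if the intersection covers at least this fraction of
#'   both regions.
#' @return List `n_overlapping`, `ratio_pct` (half-up, 2 dp).
#' @export
compare_cnvr_sets <- function(set_a, set_b, min_overlap_bp = 1L,
                              reciprocal = NULL) {
  if (!nrow(set_a)) stop("set_a is empty; overlap ratio undefined")
  if (!nrow(set_b))
    return(list(n_overlapping = 0L, ratio_pct = 0))
  lv <- unique(c(set_a$chrom, set_b$chrom))
  ga <- to_granges(set_a$chrom, set_a$start, set_a$end, lv)
  gb <- to_granges(set_b$chrom, set_b$start, set_b$end, lv)
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = as.integer(min_overlap_bp))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (!is.null(reciprocal) && length(qh)) {
    inter <- IRanges::width(IRanges::pintersect(IRanges::ranges(ga)[qh],
                                                IRanges::ranges(gb)[sh]))
    keep <- inter >= reciprocal * IRanges::width(ga)[qh] &
            inter >= reciprocal * IRanges::width(gb)[sh]
    qh <- qh[keep]
  }
  n <- length(unique(qh))
  list(n_overlapping = n, ratio_pct = pct_of(n, nrow(set_a)))
}

#' Full annotation summary for a CNVR set
#'
#' Convenience wrapper combining [genic_context()], [size_distribution()],
#' [breed_sharing()] and [qtl_overlap()] into one report.
#'
#' @param regions CNVR table.
#' @param genes Gene models (see [genic_context()]).
#' @param qtls QTL table.
#' @param sample_map Sample-to-population map.
#' @return List with `genic` (counts and pct per context), `context_by_id`,
#'   `sizes`, `sharing`, `qtl`.
#' @export
annotate_cnvrs <- function(regions, genes, qtls, sample_map) {
  ctx <- genic_context(regions, genes)
  tab <- ctx[, .N, by = genic_context]
  tab <- merge(data.table(genic_context = c("exonic", "intronic", "intergenic")),
               tab, by = "genic_context", all.x = TRUE, sort = FALSE)
  tab[is.na(N), N := 0L]
  tab[, pct := if (nrow(regions) > 0) pct_of(N, nrow(regions)) else 0]
  list(genic = tab[], context_by_id = ctx,
       sizes = size_distribution(regions),
       sharing = breed_sharing(regions, sample_map),
       qtl = qtl_overlap(regions, qtls))
}
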