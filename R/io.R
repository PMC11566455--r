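# Readers and writers for the package's plain-text interchange formats.
# All BED-like outputs are 0-based half-open.

#' Write a simulated cohort to disk
#'
#' Writes per-sample read-placement TSVs (`chrom`, `start`, `length`), the GC
#' track, the sample map, and the truth events as BED-like TSV with the
#' per-sample copy-number map as a JSON sidecar.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (s in names(cohort$reads)) {
    p <- file.path(dir, "reads", paste0(s, ".reads.tsv"))
    fwrite(cohort$reads[[s]], p, sep = "\t")
    paths[s] <- p
  }
  fwrite(cohort$gc, file.path(dir, "gc_track.tsv"), sep = "\t")
  fwrite(cohort$sample_map, file.path(dir, "sample_map.tsv"), sep = "\t")
  fwrite(cohort$truth$events, file.path(dir, "truth_events.bed.tsv"), sep = "\t")
  jsonlite::write_json(
    list(cn = as.data.frame(cohort$truth$cn),
         freq = as.data.frame(cohort$truth$freq)),
    file.path(dir, "truth_cn.json"), digits = NA)
  invisible(c(paths, gc = file.path(dir, "gc_track.tsv"),
              sample_map = file.path(dir, "sample_map.tsv"),
              truth = file.path(dir, "truth_events.bed.tsv")))
}

#' Read per-sample read placements
#'
#' @param files Named character vector of TSV paths (sample -> file), each
#'   with columns `chrom`, `start`, `length`. Plain or gzipped.
#' @return Named list of data.tables, one per sample.
#' @export
read_reads_tsv <- function(files) {
  if (is.null(names(files))) names(files) <- sub("\\.reads\\.tsv(\\.gz)?$", "", basename(files))
  lapply(as.list(files), function(p) {
    rd <- fread(p)
    if (!nrow(rd)) stop(sprintf("empty read file: %s", p))
    rd
  })
}

#' Read a GC track TSV (chrom, window_start, gc_fraction)
#' @param path TSV path.
#' @return data.table.
#' @export
read_gc_track <- function(path) fread(path)

#' Read a sample-to-population map TSV (sample, population)
#' @param path TSV path.
#' @return data.table.
#' @export
read_sample_map <- function(path) fread(path)

#' Read gene models from a BED12 file
#'
#' Parses the 12-column BED gene format: exons are reconstructed from
#' `blockSizes`/`blockStarts` relative to the gene start (0-based half-open).
#'
#' @param path BED12 path.
#' @return Gene-model list (`genes`, `exons`) as used by [genic_context()].
#' @export
read_gene_models_bed12 <- function(path) {
  b <- fread(path, header = FALSE)
  if (ncol(b) < 12) stop("expected 12 BED columns (gene models with blocks)")
  setnames(b, 1:12, c("chrom", "start", "end", "name", "score", "strand",
                      "thickStart", "thickEnd", "rgb", "blockCount",
                      "blockSizes", "blockStarts"))
  genes <- b[, .(gene_id = name, chrom, start, end, biotype = "protein_coding")]
  exons <- b[, {
    sizes <- as.integer(strsplit(sub(",$", "", blockSizes), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", blockStarts), ",")[[1]])
    .(start = start + offs, end = start + offs + sizes)
  }, by = .(gene_id = name, chrom)]
  list(genes = genes, exons = exons)
}

#' Read QTL intervals (BED3 + category + trait name columns)
#' @param path TSV path with columns qtl_id, chrom, start, end, category,
#'   trait_name (header required).
#' @return data.table.
#' @export
read_qtls <- function(path) {
  q <- fread(path)
  bad <- setdiff(unique(q$category), qtl_categories)
  if (length(bad)) stop(sprintf("unknown QTL category: %s", paste(bad, collapse = ", ")))
  q
}

#' Write a CNVR table as BED-derived TSV
#'
#' Columns: chrom, start, end, id, type, n_carriers, comma-joined carrier
#' list, and (when a depth matrix is supplied) the per-sample continuous copy
#' numbers as a JSON column.
#'
#' @param regions CNVR table.
#' @param path Output path.
#' @param dm Optional `depth_matrix` for the copy-number JSON column.
#' @return Invisibly, `path`.
#' @export
write_cnvr_bed <- function(regions, path, dm = NULL) {
  out <- data.table(chrom = regions$chrom, start = regions$start,
                    end = regions$end, id = regions$id, type = regions$type,
                    n_carriers = regions$n_carriers,
                    carriers = vapply(regions$carriers, paste,
                                      character(1), collapse = ","))
  if (!is.null(dm)) {
    out[, copy_numbers := vapply(seq_len(nrow(regions)), function(i)
      as.character(jsonlite::toJSON(
        as.list(round(copy_number_vector(regions[i], dm), 4)),
        auto_unbox = TRUE)), character(1))]
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a depth-matrix layer as TSV with a JSON header sidecar
#'
#' @param dm `depth_matrix`.
#' @param path Output TSV path (sidecar written next to it as `<path>.json`).
#' @param layer One of `raw`, `gc_corrected`, `normalized`.
#' @return Invisibly, `path`.
#' @export
write_depth_matrix <- function(dm, path, layer = c("normalized", "raw", "gc_corrected")) {
  layer <- match.arg(layer)
  mat <- dm[[layer]]
  if (is.null(mat)) stop(sprintf("layer '%s' not computed", layer))
  out <- cbind(dm$layout$windows[, .(chrom, start, end)], as.data.table(mat))
  fwrite(out, path, sep = "\t")
  jsonlite::write_json(
    list(layer = layer, window_size = dm$layout$window_size,
         step = dm$layout$step, samples = dm$samples,
         masked_windows = if (is.null(dm$window_mask)) 0L else sum(!dm$window_mask)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
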