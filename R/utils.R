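#' @importFrom data.table data.table as.data.table := setorder rbindlist setnames setcolorder copy setattr fwrite fread
#' @importFrom IRanges overlapsAny
#' @importFrom stats median rpois rnorm runif rbinom quantile var cor.test setNames
#' @importFrom utils head tail
NULL

# Round half away from zero at `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded half-up
#'
#' Reporting convention used by every summary in the package:
#' `100 * count / total`, rounded half away from zero.
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric percentage(s).
#' @export
#' @examples
#' pct_of(192, 3893)   # 4.93
#' pct_of(2612, 3893)  # 67.09
pct_of <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, digits)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 0-based half-open intervals -> GRanges (1-based closed). `seqlevels` lets
# two sets share a chromosome universe so overlap queries stay silent.
to_granges <- function(chrom, start, end, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom),
                      levels = seqlevels %||% unique(as.character(chrom))),
    ranges = IRanges::IRanges(start = start + 1L, end = pmax(start + 1L, end))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
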