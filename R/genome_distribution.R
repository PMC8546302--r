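# Genome-wide distribution summaries: counts by subgenome / homoeologous
# group / chromosome, chi-squared goodness-of-fit against uniformity, and
# centromere-anchored density profiles in 50 cM bins.

#' Chi-squared goodness-of-fit against equal category counts
#'
#' Pearson test of observed category counts against the uniform expectation
#' total/k, with k - 1 degrees of freedom.
#'
#' @param counts non-negative category counts, length >= 2, total > 0.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
chi2_uniform <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 categories")
  if (any(is.na(counts)) || any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with positive total")
  }
  ht <- stats::chisq.test(counts)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Count items by wheat subgenome (A/B/D)
#'
#' @param chrom character vector of chromosome labels.
#' @return list: `counts` (named integer A, B, D), `rejected` (data.frame
#'   of malformed labels with reasons).
#' @export
count_by_genome <- function(chrom) {
  ok <- is_wheat_chromosome(chrom)
  parsed <- parse_chromosome(chrom[ok])
  counts <- table(parsed$genome)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       rejected = data.frame(label = chrom[!ok],
                             reason = rep("invalid_chromosome", sum(!ok)),
                             stringsAsFactors = FALSE))
}

#' Count items by homoeologous group (1-7)
#' @inheritParams count_by_genome
#' @return list as in [count_by_genome()], counts named "1".."7".
#' @export
count_by_group <- function(chrom) {
  ok <- is_wheat_chromosome(chrom)
  parsed <- parse_chromosome(chrom[ok])
  counts <- table(factor(parsed$group, levels = 1:7))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       rejected = data.frame(label = chrom[!ok],
                             reason = rep("invalid_chromosome", sum(!ok)),
                             stringsAsFactors = FALSE))
}

#' Count items per chromosome
#' @inheritParams count_by_genome
#' @return list as in [count_by_genome()], counts named by the 21
#'   chromosome labels (zeros included).
#' @export
count_by_chromosome <- function(chrom) {
  ok <- is_wheat_chromosome(chrom)
  counts <- table(factor(chrom[ok], levels = wheat_chromosomes()))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       rejected = data.frame(label = chrom[!ok],
                             reason = rep("invalid_chromosome", sum(!ok)),
                             stringsAsFactors = FALSE))
}

#' Read a centromere position table
#'
#' TSV with columns `chromosome`, `centromere_cM` (one row per chromosome).
#'
#' @param path path to the TSV.
#' @return named numeric vector of centromere positions keyed by
#'   chromosome.
#' @export
read_centromere_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("chromosome", "centromere_cM"), names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(df$chromosome)) stop("duplicate chromosome entries")
  stats::setNames(df$centromere_cM, df$chromosome)
}

#' Centromere-anchored density profile
#'
#' Bins located QTLs/MQTLs by their signed cM offset from the chromosome's
#' centromere (position 0), in half-open bins `[k*w, (k+1)*w)` of width
#' `bin_width`. Negative offsets are the short-arm side. Per-trait and
#' pooled profiles are returned.
#'
#' @param positions data.frame with columns `chrom`, `position_cM` and
#'   optionally `trait`.
#' @param centromeres named numeric vector: chromosome -> centromere cM.
#' @param bin_width bin width in cM (default 50).
#' @return list: `profile` (data.frame `trait`, `bin_lo`, `bin_hi`,
#'   `count`; trait `"all"` is the pooled profile) and `excluded`
#'   (data.frame of items without a centromere entry).
#' @export
density_profile <- function(positions, centromeres, bin_width = 50) {
  has <- positions$chrom %in% names(centromeres)
  excluded <- positions[!has, , drop = FALSE]
  inc <- positions[has, , drop = FALSE]
  offset <- inc$position_cM - centromeres[inc$chrom]
  bin <- floor(offset / bin_width)
  trait <- if ("trait" %in% names(inc)) inc$trait else
    rep("all", nrow(inc))
  mk <- function(tr, b) {
    tb <- table(b)
    lo <- as.integer(names(tb)) * bin_width
    data.frame(trait = tr, bin_lo = lo, bin_hi = lo + bin_width,
               count = as.integer(tb), stringsAsFactors = FALSE)
  }
  prof <- mk("all", bin)
  if ("trait" %in% names(inc)) {
    for (tr in sort(unique(trait))) {
      prof <- rbind(prof, mk(tr, bin[trait == tr]))
    }
  }
  rownames(prof) <- NULL
  list(profile = prof, excluded = excluded)
}

#' Pearson correlation between paired per-chromosome counts
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: `r`, `p_value` (two-sided, t-based), `n`.
#' @export
correlate_counts <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
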