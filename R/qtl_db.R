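#' @keywords internal
"_PACKAGE"

# Columns every QTL table must carry, in canonical order.
QTL_COLUMNS <- c("qtl_id", "trait", "population", "cross_type", "pop_size",
                 "chrom", "peak_cM", "ci_lo_cM", "ci_hi_cM", "lod", "r2")

#' Wheat chromosome nomenclature
#'
#' The 21 chromosomes of hexaploid bread wheat: homoeologous groups 1-7
#' crossed with the A, B and D subgenomes.
#'
#' @return Character vector of the 21 chromosome labels (`"1A"` ... `"7D"`).
#' @export
wheat_chromosomes <- function() {
  as.vector(outer(1:7, c("A", "B", "D"), paste0))
}

#' Validate chromosome labels
#'
#' @param chrom character vector of chromosome labels.
#' @return Logical vector: does each label follow the digit 1-7 plus
#'   genome letter A/B/D convention?
#' @export
is_wheat_chromosome <- function(chrom) {
  !is.na(chrom) & chrom %in% wheat_chromosomes()
}

#' Decompose chromosome labels into homoeologous group and subgenome
#'
#' @param chrom character vector of valid chromosome labels.
#' @return data.frame with columns `chrom`, `group` (integer 1-7) and
#'   `genome` (factor with levels A, B, D).
#' @export
parse_chromosome <- function(chrom) {
  bad <- !is_wheat_chromosome(chrom)
  if (any(bad)) {
    stop("invalid wheat chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  }
  data.frame(
    chrom = chrom,
    group = as.integer(substr(chrom, 1, 1)),
    genome = factor(substr(chrom, 2, 2), levels = c("A", "B", "D")),
    stringsAsFactors = FALSE
  )
}

#' Trait registry
#'
#' Loads the packaged registry of trait codes and their categories
#' (agronomic, quality, micronutrient), or a user-supplied registry in the
#' same two-column TSV dialect (`code`, `category`).
#'
#' @param path optional path to a registry TSV; defaults to the packaged
#'   70-trait wheat registry.
#' @return data.frame with columns `code` and `category`.
#' @export
trait_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trait_categories.tsv", package = "mqtlr")
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("code", "category") %in% names(reg))) {
    stop("trait registry must have columns 'code' and 'category'")
  }
  if (anyDuplicated(reg$code)) {
    stop("duplicate trait codes in registry")
  }
  allowed <- c("agronomic", "quality", "micronutrient")
  if (!all(reg$category %in% allowed)) {
    stop("trait categories must be one of: ", paste(allowed, collapse = ", "))
  }
  reg
}

#' Estimate explained phenotypic variance from a LOD score
#'
#' Applies the standard relation between a LOD score and the proportion of
#' phenotypic variance explained by a locus in a population of n lines:
#' R^2 = 1 - 10^(-2 LOD / n). Used to fill in missing R^2 values when a
#' published study reports only the LOD score.
#'
#' @param lod LOD score(s), non-negative.
#' @param n population size(s) in lines, at least 2.
#' @return R^2 value(s) in `[0, 1)`.
#' @examples
#' estimate_r2(3, 150)
#' @export
estimate_r2 <- function(lod, n) {
  if (any(is.na(lod)) || any(lod < 0)) stop("lod must be non-negative")
  if (any(is.na(n)) || any(n < 2)) stop("population size n must be >= 2")
  1 - 10^(-2 * lod / n)
}

#' Invert the LOD/R-squared relation
#'
#' Recovers the LOD score implied by an explained-variance fraction under
#' the same model used by [estimate_r2()]: LOD = -n log10(1 - R^2) / 2.
#'
#' @param r2 explained variance fraction(s) in `[0, 1)`.
#' @param n population size(s) in lines, at least 2.
#' @return LOD score(s), non-negative.
#' @export
lod_from_r2 <- function(r2, n) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    stop("r2 must lie in [0, 1)")
  }
  if (any(is.na(n)) || any(n < 2)) stop("population size n must be >= 2")
  -n * log10(1 - r2) / 2
}

#' Complete missing effect statistics in a QTL table
#'
#' For each record with exactly one of LOD score or R^2 present, the other is
#' filled in via the shared LOD/R^2 relation ([estimate_r2()] and its
#' inverse). Records with neither statistic are retained but flagged
#' `"no_effect_statistic"`: the meta-analysis needs positions and intervals,
#' not effect sizes, so such records are excluded only where a statistic is
#' actually required.
#'
#' @param records data.frame of QTL records (see [read_qtl_table()]).
#' @return The same data.frame with `lod`/`r2` completed where possible and
#'   a `flag` character column (`NA` when no issue).
#' @export
complete_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- setdiff(c("pop_size", "lod", "r2"), names(records))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  if (!("flag" %in% names(records))) records$flag <- NA_character_
  fill_r2 <- is.na(records$r2) & !is.na(records$lod)
  if (any(fill_r2)) {
    records$r2[fill_r2] <- estimate_r2(records$lod[fill_r2],
                                       records$pop_size[fill_r2])
  }
  fill_lod <- is.na(records$lod) & !is.na(records$r2)
  if (any(fill_lod)) {
    records$lod[fill_lod] <- lod_from_r2(records$r2[fill_lod],
                                         records$pop_size[fill_lod])
  }
  none <- is.na(records$lod) & is.na(records$r2)
  records$flag[none] <- "no_effect_statistic"
  records
}

#' Read a QTL compilation table
#'
#' Parses a tab-separated QTL table with header columns `qtl_id trait
#' population cross_type pop_size chrom peak_cM ci_lo_cM ci_hi_cM lod r2`
#' (empty cells mark absent LOD/R^2). Every row either becomes an accepted
#' record or is reported as a rejection with its row number and a reason
#' code; nothing is silently dropped.
#'
#' @param path path to the TSV file.
#' @param complete fill missing LOD/R^2 via [complete_records()] (default
#'   TRUE).
#' @return A list with elements `records` (accepted rows, canonical column
#'   order), `rejected` (data.frame `row`, `qtl_id`, `reason`), and counts
#'   `n_accepted`, `n_rejected`.
#' @export
read_qtl_table <- function(path, complete = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(QTL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("QTL table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[QTL_COLUMNS]
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  df <- data.frame(
    qtl_id = raw$qtl_id, trait = raw$trait, population = raw$population,
    cross_type = raw$cross_type, pop_size = num(raw$pop_size),
    chrom = raw$chrom, peak_cM = num(raw$peak_cM),
    ci_lo_cM = num(raw$ci_lo_cM), ci_hi_cM = num(raw$ci_hi_cM),
    lod = num(raw$lod), r2 = num(raw$r2),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, nrow(df))
  mark <- function(cond, code) {
    ifelse(is.na(reason) & cond, code, reason)
  }
  reason <- mark(is.na(df$peak_cM), "non_numeric_position")
  reason <- mark(is.na(df$ci_lo_cM) | is.na(df$ci_hi_cM), "missing_ci")
  reason <- mark(!is.na(df$ci_lo_cM) & !is.na(df$ci_hi_cM) &
                   df$ci_lo_cM > df$ci_hi_cM, "inverted_ci")
  reason <- mark(!is.na(df$peak_cM) & !is.na(df$ci_lo_cM) &
                   !is.na(df$ci_hi_cM) &
                   (df$peak_cM < df$ci_lo_cM | df$peak_cM > df$ci_hi_cM),
                 "peak_outside_ci")
  reason <- mark(!is_wheat_chromosome(df$chrom), "invalid_chromosome")
  reason <- mark(is.na(df$pop_size) | df$pop_size < 2, "invalid_pop_size")
  reason <- mark(!(df$cross_type %in% c("RIL", "DH")), "invalid_cross_type")
  reason <- mark(!is.na(df$r2) & (df$r2 < 0 | df$r2 >= 1), "invalid_r2")
  reason <- mark(!is.na(df$lod) & df$lod < 0, "invalid_lod")
  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep),
                         qtl_id = df$qtl_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (complete && nrow(records)) records <- complete_records(records)
  list(records = records, rejected = rejected,
       n_accepted = nrow(records), n_rejected = nrow(rejected))
}

#' Write a QTL table
#'
#' Inverse of [read_qtl_table()]: writes the canonical columns as TSV with
#' empty cells for absent LOD/R^2, so that write-then-read round-trips
#' accepted records field for field.
#'
#' @param records data.frame of QTL records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(records, path) {
  out <- records[intersect(QTL_COLUMNS, names(records))]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
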