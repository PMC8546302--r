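# Binary MQTL x trait incidence matrix and the co-localization statistics
# built on it.

#' Build the binary MQTL-by-trait presence matrix
#'
#' Cell (m, t) is 1 when meta-QTL m contains at least one member QTL of
#' trait t. Rows are MQTL names, columns are trait codes (sorted).
#'
#' @param mqtl data.frame with columns `name` and `traits`
#'   (semicolon-separated trait codes), as produced by
#'   [run_meta_analysis()] or [mqtl_catalog()].
#' @return integer 0/1 matrix with MQTL row names and trait column names.
#' @export
build_presence_matrix <- function(mqtl) {
  if (anyDuplicated(mqtl$name)) stop("duplicate MQTL names")
  sets <- strsplit(mqtl$traits, ";", fixed = TRUE)
  sets <- lapply(sets, function(x) unique(x[nzchar(x)]))
  if (any(lengths(sets) == 0L)) {
    stop("every MQTL must carry at least one trait")
  }
  traits <- sort(unique(unlist(sets)))
  m <- matrix(0L, nrow = nrow(mqtl), ncol = length(traits),
              dimnames = list(mqtl$name, traits))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

#' Co-localization frequency of a trait with a target trait
#'
#' The percentage of target-trait MQTLs that also contain the trait:
#' 100 * n_both / n_target, truncated toward zero to an integer. The
#' denominator is always the target (second-named) trait's MQTL count, so
#' the frequency is not symmetric in its arguments.
#'
#' @param matrix presence matrix from [build_presence_matrix()].
#' @param trait,target trait column names.
#' @return integer percentage in 0..100.
#' @export
colocalization_frequency <- function(matrix, trait, target) {
  if (!all(c(trait, target) %in% colnames(matrix))) {
    stop("trait and target must be columns of the presence matrix")
  }
  n_target <- sum(matrix[, target])
  if (n_target == 0L) stop("undefined frequency: target has no MQTLs")
  n_both <- sum(matrix[, trait] & matrix[, target])
  as.integer(100 * n_both / n_target)
}

#' Single-cell chi-squared test of trait/target co-localization
#'
#' Tests whether a trait co-localizes with a target trait more often than
#' expected under random scatter of trait-QTLs over MQTLs. The expected
#' joint count is constructed as n_trait * (n_target / N) and compared to
#' the observed joint count by a one-degree-of-freedom Pearson cell
#' statistic (observed - expected)^2 / expected. Note this is deliberately
#' a single-cell construction, not a full 2x2 independence test; see
#' [chi2_association_2x2()] for the orthodox contingency-table diagnostic.
#'
#' @inheritParams colocalization_frequency
#' @return one-row data.frame: `trait`, `target`, `n_trait`, `n_target`,
#'   `n_both`, `frequency_percent`, `expected_both`, `chi2`, `df`,
#'   `p_value`, `more_than_expected`.
#' @export
chi2_association <- function(matrix, trait, target) {
  if (!all(c(trait, target) %in% colnames(matrix))) {
    stop("trait and target must be columns of the presence matrix")
  }
  N <- nrow(matrix)
  if (N == 0L) stop("empty presence matrix")
  n_trait <- sum(matrix[, trait])
  n_target <- sum(matrix[, target])
  n_both <- sum(matrix[, trait] & matrix[, target])
  expected <- n_trait * n_target / N
  if (expected == 0) stop("test not applicable: expected joint count is 0")
  chi2 <- (n_both - expected)^2 / expected
  data.frame(trait = trait, target = target, n_trait = n_trait,
             n_target = n_target, n_both = n_both,
             frequency_percent = as.integer(100 * n_both / n_target),
             expected_both = expected, chi2 = chi2, df = 1L,
             p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
             more_than_expected = n_both > expected,
             stringsAsFactors = FALSE)
}

#' Standard 2x2 chi-squared independence diagnostic
#'
#' The orthodox Pearson contingency-table test of independence between
#' presence of `trait` and presence of `target` across MQTLs, without
#' continuity correction. Provided as a clearly separated alternative to
#' the single-cell construction of [chi2_association()].
#'
#' @inheritParams colocalization_frequency
#' @return list: `statistic`, `df`, `p_value`, `table` (the 2x2 counts).
#' @export
chi2_association_2x2 <- function(matrix, trait, target) {
  tab <- table(factor(matrix[, trait], levels = 0:1),
               factor(matrix[, target], levels = 0:1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}

#' Regress co-localization frequency on per-trait MQTL count
#'
#' Ordinary least squares of each trait's co-localization frequency with
#' the target on that trait's total MQTL count, across all traits other
#' than the target with a defined frequency. R^2 is reported as a
#' percentage.
#'
#' @inheritParams colocalization_frequency
#' @param target target trait column name.
#' @return list: `slope`, `intercept`, `r2_percent`, `n_traits`, `data`
#'   (the per-trait count/frequency table used).
#' @export
regression_coloc <- function(matrix, target) {
  if (!(target %in% colnames(matrix))) stop("unknown target trait")
  traits <- setdiff(colnames(matrix), target)
  counts <- colSums(matrix[, traits, drop = FALSE])
  freq <- vapply(traits, function(tr) {
    colocalization_frequency(matrix, tr, target)
  }, integer(1L))
  if (length(traits) < 3L) stop("need at least 3 traits")
  if (stats::sd(counts) == 0) stop("regression undefined: constant counts")
  fit <- stats::lm(freq ~ counts)
  r2 <- if (stats::sd(freq) == 0) 0 else summary(fit)$r.squared
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2_percent = 100 * r2, n_traits = length(traits),
       data = data.frame(trait = traits, n_mqtl = unname(counts),
                         frequency_percent = unname(freq),
                         stringsAsFactors = FALSE))
}

#' Write a co-localization report
#'
#' Runs [chi2_association()] for every trait against each target trait and
#' writes the combined report as TSV.
#'
#' @param matrix presence matrix.
#' @param targets target trait codes (default the four grain targets
#'   present in the matrix).
#' @param path output path, or NULL to return the data.frame only.
#' @return the report data.frame, invisibly when written.
#' @export
colocalization_report <- function(matrix,
                                  targets = intersect(
                                    c("GPC", "GZnC", "GFeC", "GY"),
                                    colnames(matrix)),
                                  path = NULL) {
  rows <- list()
  for (tg in targets) {
    for (tr in setdiff(colnames(matrix), tg)) {
      rows[[length(rows) + 1L]] <- chi2_association(matrix, tr, tg)
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
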