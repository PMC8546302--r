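# Accessors for the packaged plain-text fixtures: a transcription of a
# published catalog of 100 wheat meta-QTLs with its physical-interval,
# GWAS-signal and cross-species interval companions, plus a synthetic
# ortholog-pair table (real gene pairs live in annotation databases and
# are not shipped; the synthetic pairs preserve the published interval
# pairing structure).

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mqtlr")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Packaged wheat meta-QTL catalog
#'
#' A transcription of a published catalog of 100 wheat MQTLs: name,
#' chromosome, flanking markers, consensus position (cM), 95% confidence
#' interval width (cM) and the semicolon-separated list of traits whose
#' QTLs the MQTL contains.
#'
#' @return data.frame with columns `name`, `chrom`, `left_marker`,
#'   `right_marker`, `position_cM`, `ci_cM`, `traits`.
#' @export
mqtl_catalog <- function() {
  df <- utils::read.delim(fixture_path("wheat_mqtl_catalog.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "mqtl"] <- "name"
  df
}

#' Physical (Mb) intervals of the stable catalog MQTLs
#' @return data.frame `mqtl`, `chrom`, `start_mb`, `end_mb`.
#' @export
mqtl_physical_intervals <- function() {
  utils::read.delim(fixture_path("wheat_mqtl_physical.tsv"),
                    stringsAsFactors = FALSE)
}

#' Packaged wheat GWAS signal table
#' @return data.frame `snp`, `chrom`, `mb`, `trait`, `study`.
#' @export
gwas_signal_fixture <- function() {
  read_gwas_signals(fixture_path("wheat_gwas_signals.tsv"))
}

#' Cross-species orthologous-MQTL interval table
#'
#' Linked wheat and rice/maize MQTL physical intervals.
#'
#' @return data.frame with wheat and partner interval coordinates per
#'   orthologous-MQTL row.
#' @export
ormqtl_interval_fixture <- function() {
  df <- utils::read.delim(fixture_path("ormqtl_intervals.tsv"),
                          stringsAsFactors = FALSE)
  df$partner_chr <- as.character(df$partner_chr)
  df
}

#' Synthetic ortholog gene pairs consistent with the interval table
#'
#' One synthetic gene pair per linked interval pair, each gene placed at
#' its interval midpoint, so ortholog-based interval matching recovers the
#' published pairing structure exactly.
#'
#' @return data.frame in the [read_ortholog_pairs()] dialect.
#' @export
ortholog_pair_fixture <- function() {
  read_ortholog_pairs(fixture_path("ortholog_pairs_synthetic.tsv"))
}
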