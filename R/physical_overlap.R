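# Physical (Mb) anchoring of MQTLs and overlap with GWAS signals and
# cross-species ortholog intervals. All coordinate comparisons use closed
# intervals on Mb reals, matching how published tables report ranges.

#' Anchor meta-QTLs to physical coordinates through flanking markers
#'
#' The physical interval of an MQTL is the [min, max] span of the Mb
#' positions of its two flanking markers. When a flanking marker has no
#' physical position, the nearest physically mapped marker on the correct
#' side of the MQTL on the consensus map substitutes, and the substitution
#' is recorded; if no mappable marker exists on one side the MQTL is
#' reported as an anchoring failure.
#'
#' @param mqtl data.frame with columns `name`, `chrom`, `left_marker`,
#'   `right_marker` and (for substitution search) `ci_lo_cM`, `ci_hi_cM`.
#' @param marker_bp data.frame `marker`, `chromosome`, `mb` of physical
#'   marker positions.
#' @param consensus optional consensus `genetic_map`; required for
#'   nearest-marker substitution.
#' @return list: `intervals` (data.frame `mqtl`, `chrom`, `start_mb`,
#'   `end_mb`, `substituted`), `failed` (data.frame `mqtl`, `reason`).
#' @export
anchor_mqtl <- function(mqtl, marker_bp, consensus = NULL) {
  pos_of <- function(marker, chrom) {
    hit <- marker_bp$marker == marker & marker_bp$chromosome == chrom
    if (any(hit)) marker_bp$mb[which(hit)[1L]] else NA_real_
  }
  substitute_marker <- function(chrom, bound_cM, side) {
    if (is.null(consensus)) return(NA_character_)
    mk <- consensus[consensus$linkage_group == chrom, , drop = FALSE]
    mk <- mk[mk$marker %in%
               marker_bp$marker[marker_bp$chromosome == chrom], ,
             drop = FALSE]
    if (!nrow(mk)) return(NA_character_)
    if (side == "left") {
      cand <- mk[mk$position_cM <= bound_cM, , drop = FALSE]
      if (!nrow(cand)) return(NA_character_)
      cand$marker[which.max(cand$position_cM)]
    } else {
      cand <- mk[mk$position_cM >= bound_cM, , drop = FALSE]
      if (!nrow(cand)) return(NA_character_)
      cand$marker[which.min(cand$position_cM)]
    }
  }
  intervals <- list()
  failed <- list()
  for (i in seq_len(nrow(mqtl))) {
    row <- mqtl[i, , drop = FALSE]
    subbed <- character()
    mb <- c(pos_of(row$left_marker, row$chrom),
            pos_of(row$right_marker, row$chrom))
    sides <- c("left", "right")
    bounds <- c(row$ci_lo_cM %||% NA_real_, row$ci_hi_cM %||% NA_real_)
    for (j in 1:2) {
      if (is.na(mb[j]) && !is.na(bounds[j])) {
        alt <- substitute_marker(row$chrom, bounds[j], sides[j])
        if (!is.na(alt)) {
          mb[j] <- pos_of(alt, row$chrom)
          subbed <- c(subbed, paste0(sides[j], "=", alt))
        }
      }
    }
    if (anyNA(mb)) {
      failed[[length(failed) + 1L]] <- data.frame(
        mqtl = row$name, reason = "no_mappable_marker",
        stringsAsFactors = FALSE)
    } else {
      intervals[[length(intervals) + 1L]] <- data.frame(
        mqtl = row$name, chrom = row$chrom,
        start_mb = min(mb), end_mb = max(mb),
        substituted = paste(subbed, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(intervals = if (length(intervals)) do.call(rbind, intervals) else
    data.frame(mqtl = character(), chrom = character(),
               start_mb = numeric(), end_mb = numeric(),
               substituted = character(), stringsAsFactors = FALSE),
    failed = if (length(failed)) do.call(rbind, failed) else
      data.frame(mqtl = character(), reason = character(),
                 stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap MQTL physical intervals with GWAS signals
#'
#' A signal overlaps an interval when it lies on the same chromosome and
#' `start_mb <= position <= end_mb` (closed interval, so a signal exactly
#' at a bound counts).
#'
#' @param intervals data.frame `mqtl`, `chrom`, `start_mb`, `end_mb`.
#' @param signals data.frame `snp`, `chrom`, `mb`, `trait` (and optionally
#'   `study`).
#' @param trait_sets optional named list: MQTL name -> character vector of
#'   its trait codes; when given, only same-trait overlaps are kept.
#' @return data.frame of (mqtl, snp, trait, chrom, mb) overlap triples.
#' @export
gwas_overlap <- function(intervals, signals, trait_sets = NULL) {
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, , drop = FALSE]
    hit <- signals$chrom == iv$chrom &
      signals$mb >= iv$start_mb & signals$mb <= iv$end_mb
    if (!is.null(trait_sets)) {
      allowed <- trait_sets[[iv$mqtl]] %||% character()
      hit <- hit & signals$trait %in% allowed
    }
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mqtl = iv$mqtl, snp = signals$snp[hit],
        trait = signals$trait[hit], chrom = iv$chrom,
        mb = signals$mb[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mqtl = character(), snp = character(), trait = character(),
               chrom = character(), mb = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# closed-interval any-overlap test between a gene span and an interval
span_overlaps <- function(g_start, g_end, i_start, i_end) {
  g_end >= i_start & g_start <= i_end
}

#' Detect orthologous MQTLs through shared ortholog pairs
#'
#' An (interval_a, interval_b) pair across two species is reported as an
#' orthologous MQTL when at least one ortholog gene pair has its species-A
#' gene overlapping interval_a and its species-B gene overlapping
#' interval_b (any-overlap, closed intervals). Supporting gene pairs are
#' listed per reported pair.
#'
#' @param intervals_a,intervals_b data.frames `mqtl`, `chrom`, `start_mb`,
#'   `end_mb` for species A and B.
#' @param pairs data.frame `gene_a`, `chr_a`, `start_a`, `end_a`,
#'   `gene_b`, `chr_b`, `start_b`, `end_b` (coordinates of side A in
#'   species A, side B in species B).
#' @return data.frame: `mqtl_a`, `mqtl_b`, `n_support`, `genes`
#'   (semicolon list of "gene_a|gene_b" supporting pairs).
#' @export
detect_ormqtl <- function(intervals_a, intervals_b, pairs) {
  if (!nrow(pairs)) {
    warning("empty ortholog pair table")
    return(data.frame(mqtl_a = character(), mqtl_b = character(),
                      n_support = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- list()
  for (p in seq_len(nrow(pairs))) {
    pr <- pairs[p, , drop = FALSE]
    in_a <- intervals_a$chrom == pr$chr_a &
      span_overlaps(pr$start_a, pr$end_a,
                    intervals_a$start_mb, intervals_a$end_mb)
    in_b <- intervals_b$chrom == pr$chr_b &
      span_overlaps(pr$start_b, pr$end_b,
                    intervals_b$start_mb, intervals_b$end_mb)
    if (!any(in_a) || !any(in_b)) next
    for (ia in which(in_a)) {
      for (ib in which(in_b)) {
        key <- paste(intervals_a$mqtl[ia], intervals_b$mqtl[ib],
                     sep = "\r")
        hits[[key]] <- c(hits[[key]], paste(pr$gene_a, pr$gene_b,
                                            sep = "|"))
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(mqtl_a = character(), mqtl_b = character(),
                      n_support = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- strsplit(names(hits), "\r", fixed = TRUE)
  out <- data.frame(
    mqtl_a = vapply(keys, `[`, character(1L), 1L),
    mqtl_b = vapply(keys, `[`, character(1L), 2L),
    n_support = lengths(hits),
    genes = vapply(hits, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$mqtl_a, out$mqtl_b), , drop = FALSE]
}

#' Read marker physical positions (TSV `marker chromosome mb`)
#' @param path path to the TSV.
#' @return data.frame `marker`, `chromosome`, `mb`.
#' @export
read_marker_positions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("marker", "chromosome", "mb"), names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  df
}

#' Read a GWAS signal table (TSV `snp chrom mb trait study`)
#' @param path path to the TSV.
#' @return data.frame of signals.
#' @export
read_gwas_signals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("snp", "chrom", "mb", "trait"), names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  df
}

#' Read an ortholog pair table
#' @param path TSV with columns `gene_a chr_a start_a end_a gene_b chr_b
#'   start_b end_b species_a species_b`.
#' @return data.frame of ortholog pairs.
#' @export
read_ortholog_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- setdiff(c("gene_a", "chr_a", "start_a", "end_a",
                    "gene_b", "chr_b", "start_b", "end_b"), names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  df$chr_a <- as.character(df$chr_a)
  df$chr_b <- as.character(df$chr_b)
  df
}

#' Export physical intervals as BED
#'
#' Converts the closed 1-based Mb intervals to BED's 0-based half-open bp
#' convention: start_bp = round(start_mb * 1e6) - 1, end_bp =
#' round(end_mb * 1e6).
#'
#' @param intervals data.frame `mqtl`, `chrom`, `start_mb`, `end_mb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = pmax(round(intervals$start_mb * 1e6) - 1, 0),
                    end = round(intervals$end_mb * 1e6),
                    name = intervals$mqtl)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
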