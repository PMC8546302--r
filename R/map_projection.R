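# Consensus genetic map construction and anchor-based QTL projection.
#
# The projection rule throughout is flanking-shared-anchor linear rescaling:
# a point at position p on a component linkage group, bracketed by shared
# anchors at component positions (m_left, m_right) with consensus positions
# (c_left, c_right), maps to
#   c_left + (p - m_left) * (c_right - c_left) / (m_right - m_left).
# Points outside the outermost shared anchors are not extrapolated.

#' Construct a genetic map object
#'
#' A genetic map is a data.frame of marker loci (`marker`, `linkage_group`,
#' `position_cM`) ordered by position within each linkage group. Duplicate
#' positions are allowed (co-segregating markers); duplicate (marker,
#' linkage_group) pairs are not.
#'
#' @param df data.frame with columns `marker`, `linkage_group`,
#'   `position_cM`.
#' @param map_id identifier for the map (stored as an attribute).
#' @return A `genetic_map` (data.frame subclass).
#' @export
genetic_map <- function(df, map_id = "map") {
  need <- setdiff(c("marker", "linkage_group", "position_cM"), names(df))
  if (length(need)) stop("missing column(s): ", paste(need, collapse = ", "))
  if (any(is.na(df$position_cM)) || any(df$position_cM < 0)) {
    stop("marker positions must be non-negative cM values")
  }
  if (anyDuplicated(df[c("marker", "linkage_group")])) {
    stop("duplicate (marker, linkage_group) pairs in map")
  }
  df <- df[order(df$linkage_group, df$position_cM, df$marker), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, map_id = map_id, class = c("genetic_map", "data.frame"))
}

#' Read a genetic map from TSV
#'
#' Expects columns `marker`, `linkage_group`, `position_cM`, one map per
#' file.
#'
#' @param path path to the TSV file.
#' @param map_id map identifier; defaults to the file name.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, map_id = NULL) {
  if (is.null(map_id)) map_id <- tools::file_path_sans_ext(basename(path))
  genetic_map(utils::read.delim(path, stringsAsFactors = FALSE), map_id)
}

#' Write a genetic map to TSV
#' @param map a `genetic_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Shared-anchor table for one linkage group of (component, consensus).
# Returns NULL when fewer than 2 usable anchors, otherwise a data.frame
# (marker, comp, cons) sorted by component position with duplicate component
# positions collapsed, plus an 'inverted' attribute when consensus order
# disagrees with component order.
anchor_table <- function(component, consensus, lg) {
  comp <- component[component$linkage_group == lg, , drop = FALSE]
  cons <- consensus[consensus$linkage_group == lg, , drop = FALSE]
  shared <- intersect(comp$marker, cons$marker)
  if (length(shared) < 2) return(NULL)
  a <- data.frame(
    marker = shared,
    comp = comp$position_cM[match(shared, comp$marker)],
    cons = cons$position_cM[match(shared, cons$marker)],
    stringsAsFactors = FALSE
  )
  a <- a[order(a$comp, a$cons), , drop = FALSE]
  a <- a[!duplicated(a$comp), , drop = FALSE]
  if (nrow(a) < 2) return(NULL)
  attr(a, "inverted") <- is.unsorted(a$cons)
  a
}

# Piecewise-linear map of points p through anchors (strictly increasing x).
# Returns consensus positions; NA for points outside [x_1, x_n].
interpolate_anchor <- function(p, x, y) {
  i <- findInterval(p, x)
  ii <- pmin(pmax(i, 1L), length(x) - 1L)
  t <- (p - x[ii]) / (x[ii + 1L] - x[ii])
  out <- y[ii] + t * (y[ii + 1L] - y[ii])
  out[p < x[1L] | p > x[length(x)]] <- NA_real_
  out
}

#' Integrate component maps around a reference into a consensus map
#'
#' Reference marker positions are preserved verbatim. A component-only
#' marker lying between shared anchors is placed by linear interpolation;
#' markers outside the anchored span, on linkage groups with fewer than two
#' shared anchors, or with conflicting placements across components (spread
#' greater than `conflict_tol` cM) are left unplaced and reported.
#' Consistent multi-component placements are averaged.
#'
#' @param reference the reference `genetic_map`.
#' @param components list of component `genetic_map`s.
#' @param conflict_tol maximum spread (cM) across per-component placements
#'   of the same new marker before it is declared conflicting (default 5).
#' @return list with `map` (the consensus `genetic_map`) and `report`
#'   (data.frame `map_id`, `marker`, `linkage_group`, `status`,
#'   `position_cM`; statuses `placed`, `outside_anchors`, `no_anchors`,
#'   `inverted_anchor_order`, `conflicting`).
#' @export
build_consensus_map <- function(reference, components = list(),
                                conflict_tol = 5) {
  stopifnot(inherits(reference, "genetic_map"))
  proposals <- list()  # key "lg\rmarker" -> numeric vector of placements
  report <- list()
  note <- function(map_id, marker, lg, status, pos = NA_real_) {
    report[[length(report) + 1L]] <<- data.frame(
      map_id = map_id, marker = marker, linkage_group = lg,
      status = status, position_cM = pos, stringsAsFactors = FALSE)
  }
  for (comp in components) {
    stopifnot(inherits(comp, "genetic_map"))
    cid <- attr(comp, "map_id")
    for (lg in unique(comp$linkage_group)) {
      sub <- comp[comp$linkage_group == lg, , drop = FALSE]
      new <- sub[!(sub$marker %in%
                     reference$marker[reference$linkage_group == lg]), ,
                 drop = FALSE]
      if (!nrow(new)) next
      a <- anchor_table(comp, reference, lg)
      if (is.null(a)) {
        for (k in seq_len(nrow(new)))
          note(cid, new$marker[k], lg, "no_anchors")
        next
      }
      if (isTRUE(attr(a, "inverted"))) {
        for (k in seq_len(nrow(new)))
          note(cid, new$marker[k], lg, "inverted_anchor_order")
        next
      }
      pos <- interpolate_anchor(new$position_cM, a$comp, a$cons)
      for (k in seq_len(nrow(new))) {
        if (is.na(pos[k])) {
          note(cid, new$marker[k], lg, "outside_anchors")
        } else {
          key <- paste(lg, new$marker[k], sep = "\r")
          proposals[[key]] <- c(proposals[[key]], pos[k])
          note(cid, new$marker[k], lg, "placed", pos[k])
        }
      }
    }
  }
  placed <- list()
  for (key in names(proposals)) {
    v <- proposals[[key]]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    if (diff(range(v)) > conflict_tol) {
      report[[length(report) + 1L]] <- data.frame(
        map_id = "consensus", marker = parts[2L], linkage_group = parts[1L],
        status = "conflicting", position_cM = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      placed[[length(placed) + 1L]] <- data.frame(
        marker = parts[2L], linkage_group = parts[1L],
        position_cM = mean(v), stringsAsFactors = FALSE)
    }
  }
  out <- as.data.frame(reference)[c("marker", "linkage_group", "position_cM")]
  if (length(placed)) out <- rbind(out, do.call(rbind, placed))
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(map_id = character(), marker = character(),
               linkage_group = character(), status = character(),
               position_cM = numeric(), stringsAsFactors = FALSE)
  # a marker noted 'placed' per component may still have been conflicting
  conflicted <- report$marker[report$status == "conflicting"]
  report <- report[!(report$status == "placed" &
                       report$marker %in% conflicted), , drop = FALSE]
  rownames(report) <- NULL
  list(map = genetic_map(out, map_id = "consensus"), report = report)
}

#' Project one QTL onto the consensus map
#'
#' The peak and both confidence-interval endpoints are each rescaled through
#' their own bracketing pair of shared anchors. Failure modes are reported
#' as a status rather than an error: `no_anchors` (fewer than two shared
#' markers on the group), `inverted_anchor_order` (anchor order disagrees
#' between the maps), and `outside_anchors` (any of the three points falls
#' outside the outermost shared anchors; no extrapolation is attempted).
#'
#' @param qtl single-row data.frame with at least `qtl_id`, `chrom`,
#'   `peak_cM`, `ci_lo_cM`, `ci_hi_cM`.
#' @param component the source `genetic_map`.
#' @param consensus the consensus `genetic_map`.
#' @return One-row data.frame: `qtl_id`, `chrom`, `status`,
#'   `consensus_peak`, `consensus_ci_lo`, `consensus_ci_hi`, `left_anchor`,
#'   `right_anchor`.
#' @export
project_qtl <- function(qtl, component, consensus) {
  lg <- qtl$chrom
  if (!(lg %in% component$linkage_group) ||
      !(lg %in% consensus$linkage_group)) {
    stop("linkage group ", lg, " absent from component or consensus map")
  }
  res <- data.frame(qtl_id = qtl$qtl_id, chrom = lg, status = "projected",
                    consensus_peak = NA_real_, consensus_ci_lo = NA_real_,
                    consensus_ci_hi = NA_real_, left_anchor = NA_character_,
                    right_anchor = NA_character_, stringsAsFactors = FALSE)
  a <- anchor_table(component, consensus, lg)
  if (is.null(a)) {
    res$status <- "no_anchors"
    return(res)
  }
  if (isTRUE(attr(a, "inverted"))) {
    res$status <- "inverted_anchor_order"
    return(res)
  }
  pts <- c(qtl$peak_cM, qtl$ci_lo_cM, qtl$ci_hi_cM)
  mapped <- interpolate_anchor(pts, a$comp, a$cons)
  if (anyNA(mapped)) {
    res$status <- "outside_anchors"
    return(res)
  }
  res$consensus_peak <- mapped[1L]
  res$consensus_ci_lo <- mapped[2L]
  res$consensus_ci_hi <- mapped[3L]
  i <- min(max(findInterval(pts[1L], a$comp), 1L), nrow(a) - 1L)
  res$left_anchor <- a$marker[i]
  res$right_anchor <- a$marker[i + 1L]
  res
}

#' Project a QTL compilation onto the consensus map
#'
#' @param qtls data.frame of QTL records (see [read_qtl_table()]); the
#'   `population` column selects the component map.
#' @param maps named list of component `genetic_map`s keyed by population
#'   id.
#' @param consensus the consensus `genetic_map`.
#' @return list with `projected` (one row per QTL: record columns plus
#'   projection result columns) and `summary` (list: `n_total`,
#'   `n_projected`, `projected_fraction`, `by_status`).
#' @export
project_all <- function(qtls, maps, consensus) {
  rows <- vector("list", nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, , drop = FALSE]
    m <- maps[[q$population]]
    if (is.null(m)) {
      rows[[i]] <- data.frame(
        qtl_id = q$qtl_id, chrom = q$chrom, status = "no_map",
        consensus_peak = NA_real_, consensus_ci_lo = NA_real_,
        consensus_ci_hi = NA_real_, left_anchor = NA_character_,
        right_anchor = NA_character_, stringsAsFactors = FALSE)
    } else if (!(q$chrom %in% m$linkage_group) ||
               !(q$chrom %in% consensus$linkage_group)) {
      rows[[i]] <- data.frame(
        qtl_id = q$qtl_id, chrom = q$chrom, status = "no_anchors",
        consensus_peak = NA_real_, consensus_ci_lo = NA_real_,
        consensus_ci_hi = NA_real_, left_anchor = NA_character_,
        right_anchor = NA_character_, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- project_qtl(q, m, consensus)
    }
  }
  proj <- do.call(rbind, rows)
  out <- cbind(qtls[setdiff(names(qtls), names(proj))], proj)
  rownames(out) <- NULL
  by_status <- table(factor(out$status,
                            levels = c("projected", "no_anchors",
                                       "outside_anchors",
                                       "inverted_anchor_order", "no_map")))
  n <- nrow(out)
  list(projected = out,
       summary = list(n_total = n,
                      n_projected = unname(by_status[["projected"]]),
                      projected_fraction =
                        if (n) unname(by_status[["projected"]]) / n else NA,
                      by_status = by_status))
}
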