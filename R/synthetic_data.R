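# Seeded generator of multi-population QTL compilations with known ground
# truth, used to exercise every pipeline stage without external data.
#
# The generator emulates the structure of a published wheat QTL
# compilation: per-chromosome clusters of QTL peaks with heteroscedastic
# confidence-interval widths, trait labels with controlled pairwise
# co-occurrence, LOD / population-size metadata, and component genetic
# maps that share anchor markers with a dense reference map but are
# distorted by monotone piecewise-linear stretches.

#' Build a synthetic-study configuration
#'
#' Defaults emulate the scale of a large multi-population wheat
#' compilation: 21 chromosomes, 27 populations (RIL-heavy) of 92-485
#' lines, 5 planted QTL clusters per chromosome with 7 members each
#' (735 QTLs), confidence-interval widths log-normal with median 13.7 cM,
#' and an attrition fraction of 0.39 constructed by placing QTLs beyond
#' anchor coverage.
#'
#' @param seed mandatory integer seed.
#' @param n_chromosomes number of chromosomes simulated (uses the first n
#'   wheat labels).
#' @param chrom_length_cM linkage-group length.
#' @param n_populations number of component mapping populations.
#' @param pop_size_range inclusive range population sizes are drawn from.
#' @param dh_fraction fraction of populations that are double-haploid (the
#'   rest are RILs).
#' @param n_clusters true QTL clusters per chromosome.
#' @param members_per_cluster QTLs per cluster.
#' @param min_separation minimum pairwise distance between cluster means,
#'   cM.
#' @param end_margin_cM keep cluster means this far from chromosome ends.
#' @param ci_meanlog,ci_sdlog log-normal parameters of the 95% CI width
#'   distribution, cM.
#' @param lod_range uniform range LOD scores are drawn from.
#' @param miss_lod_rate,miss_r2_rate per-record probabilities of blanking
#'   the LOD / R^2 field (never both).
#' @param anchor_spacing_cM reference marker spacing.
#' @param marker_keep_frac fraction of interior reference markers retained
#'   in each component map.
#' @param stretch_sdlog log-normal sd of per-interval map stretch factors.
#' @param attrition_fraction fraction of QTLs deliberately placed outside
#'   anchor coverage so they cannot be projected.
#' @param trait_base_rates named per-trait presence probabilities for
#'   cluster trait sets.
#' @param trait_pair_odds list of `c(trait_a, trait_b, odds_multiplier)`
#'   triples steering pairwise co-occurrence.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 21L,
                              chrom_length_cM = 160,
                              n_populations = 27L,
                              pop_size_range = c(92L, 485L),
                              dh_fraction = 7 / 27,
                              n_clusters = 5L,
                              members_per_cluster = 7L,
                              min_separation = 20,
                              end_margin_cM = 15,
                              ci_meanlog = log(13.7),
                              ci_sdlog = 0.35,
                              lod_range = c(2.5, 12),
                              miss_lod_rate = 0.2,
                              miss_r2_rate = 0.5,
                              anchor_spacing_cM = 5,
                              marker_keep_frac = 0.5,
                              stretch_sdlog = 0.05,
                              attrition_fraction = 0.39,
                              trait_base_rates = c(GY = 0.35, TKW = 0.40,
                                                   GPC = 0.20, GFeC = 0.15,
                                                   GZnC = 0.12, NG = 0.25,
                                                   PH = 0.25, SNS = 0.20),
                              trait_pair_odds = list(
                                c("GFeC", "GZnC", "8"),
                                c("GY", "TKW", "4"))) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_length_cM = chrom_length_cM,
              n_populations = n_populations,
              pop_size_range = pop_size_range, dh_fraction = dh_fraction,
              n_clusters = n_clusters,
              members_per_cluster = members_per_cluster,
              min_separation = min_separation,
              end_margin_cM = end_margin_cM,
              ci_meanlog = ci_meanlog, ci_sdlog = ci_sdlog,
              lod_range = lod_range, miss_lod_rate = miss_lod_rate,
              miss_r2_rate = miss_r2_rate,
              anchor_spacing_cM = anchor_spacing_cM,
              marker_keep_frac = marker_keep_frac,
              stretch_sdlog = stretch_sdlog,
              attrition_fraction = attrition_fraction,
              trait_base_rates = trait_base_rates,
              trait_pair_odds = trait_pair_odds)
  usable <- cfg$chrom_length_cM - 2 * cfg$end_margin_cM
  if (cfg$n_clusters > 1L &&
      usable / (cfg$n_clusters - 1L) < cfg$min_separation) {
    stop("infeasible configuration: too many clusters for the ",
         "chromosome length at the requested separation")
  }
  structure(cfg, class = "simulation_config")
}

#' Sample cluster trait sets with controlled pairwise co-occurrence
#'
#' Each trait is first drawn independently from its base rate; then for
#' each designated (a, b, m) triple, trait b is redrawn conditional on a so
#' that the odds of b given a are m times the base odds while the
#' probability of b given not-a stays at the base rate, making m the exact
#' population odds ratio of the pair. Empty sets are repaired by forcing
#' one trait drawn proportionally to the base rates.
#'
#' @param n number of sets to draw.
#' @param base_rates named per-trait probabilities.
#' @param pair_odds list of `c(a, b, multiplier)` triples.
#' @return n x traits logical matrix.
#' @export
sample_trait_sets <- function(n, base_rates, pair_odds = list()) {
  traits <- names(base_rates)
  draw <- function(n) {
    m <- matrix(stats::runif(n * length(traits)) <
                  rep(base_rates, each = n),
                nrow = n, dimnames = list(NULL, traits))
    for (po in pair_odds) {
      a <- po[[1L]]; b <- po[[2L]]; mult <- as.numeric(po[[3L]])
      pb <- base_rates[[b]]
      odds_b <- pb / (1 - pb)
      p_given_a <- mult * odds_b / (1 + mult * odds_b)
      has_a <- m[, a]
      m[, b] <- ifelse(has_a, stats::runif(n) < p_given_a,
                       stats::runif(n) < pb)
    }
    m
  }
  m <- draw(n)
  # empty sets are resampled wholesale, which preserves the configured
  # rates and odds up to the (mild) conditioning on non-emptiness
  for (round in seq_len(100L)) {
    empty <- rowSums(m) == 0L
    if (!any(empty)) break
    m[empty, ] <- draw(sum(empty))
  }
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    forced <- sample(traits, sum(empty), replace = TRUE,
                     prob = base_rates / sum(base_rates))
    m[cbind(which(empty), match(forced, traits))] <- TRUE
  }
  m
}

#' Generate a synthetic multi-population QTL study
#'
#' Produces a dense reference map, distorted component maps sharing anchor
#' markers with it, a QTL compilation table in component coordinates, and
#' the ground truth (cluster means, per-QTL cluster ids and trait labels,
#' constructed attrition). Component maps are monotone piecewise-linear
#' distortions of the reference with breakpoints at the retained anchors,
#' so anchor-based projection recovers reference coordinates exactly; the
#' configured fraction of QTLs is instead placed beyond the outermost
#' anchor to force projection attrition deterministically.
#'
#' @param config a [simulation_config()].
#' @return list: `reference` (genetic_map), `components` (named list of
#'   genetic_maps keyed by population id), `qtls` (QTL record table),
#'   `truth` (list: `clusters`, `qtl`, `populations`,
#'   `attrition_fraction`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    chroms <- wheat_chromosomes()[seq_len(cfg$n_chromosomes)]
    L <- cfg$chrom_length_cM
    ref_pos <- seq(0, L, by = cfg$anchor_spacing_cM)
    reference <- genetic_map(do.call(rbind, lapply(chroms, function(ch) {
      data.frame(marker = sprintf("m%s_%03d", ch, seq_along(ref_pos)),
                 linkage_group = ch, position_cM = ref_pos,
                 stringsAsFactors = FALSE)
    })), map_id = "reference")

    pops <- data.frame(
      population = sprintf("pop%02d", seq_len(cfg$n_populations)),
      cross_type = ifelse(seq_len(cfg$n_populations) <=
                            round(cfg$dh_fraction * cfg$n_populations),
                          "DH", "RIL"),
      pop_size = sample(seq(cfg$pop_size_range[1L], cfg$pop_size_range[2L]),
                        cfg$n_populations, replace = TRUE),
      stringsAsFactors = FALSE)

    # component maps: retained anchors + monotone per-interval stretches
    components <- list()
    comp_anchor <- list()  # population -> chrom -> data.frame(ref, comp)
    for (p in seq_len(cfg$n_populations)) {
      pid <- pops$population[p]
      rows <- list()
      comp_anchor[[pid]] <- list()
      for (ch in chroms) {
        sub <- reference[reference$linkage_group == ch, , drop = FALSE]
        nref <- nrow(sub)
        keep <- c(1L, which(stats::runif(nref - 2L) <
                              cfg$marker_keep_frac) + 1L, nref)
        keep <- sort(unique(keep))
        rpos <- sub$position_cM[keep]
        stretch <- stats::rlnorm(length(rpos) - 1L, 0, cfg$stretch_sdlog)
        cpos <- c(0, cumsum(diff(rpos) * stretch))
        rows[[ch]] <- data.frame(marker = sub$marker[keep],
                                 linkage_group = ch, position_cM = cpos,
                                 stringsAsFactors = FALSE)
        comp_anchor[[pid]][[ch]] <- data.frame(ref = rpos, comp = cpos)
      }
      components[[pid]] <- genetic_map(do.call(rbind, rows), map_id = pid)
    }

    # true cluster means: evenly spaced with bounded jitter
    jit_max <- if (cfg$n_clusters > 1L) {
      max(0, ((L - 2 * cfg$end_margin_cM) / (cfg$n_clusters - 1L) -
                cfg$min_separation) / 2)
    } else (L - 2 * cfg$end_margin_cM) / 2
    clusters <- do.call(rbind, lapply(chroms, function(ch) {
      base <- if (cfg$n_clusters == 1L) L / 2 else
        seq(cfg$end_margin_cM, L - cfg$end_margin_cM,
            length.out = cfg$n_clusters)
      data.frame(chrom = ch, cluster = seq_len(cfg$n_clusters),
                 mean_cM = base + stats::runif(cfg$n_clusters,
                                               -jit_max, jit_max),
                 stringsAsFactors = FALSE)
    }))

    # cluster trait sets with controlled co-occurrence
    tset <- sample_trait_sets(nrow(clusters), cfg$trait_base_rates,
                              cfg$trait_pair_odds)

    n_qtl <- nrow(clusters) * cfg$members_per_cluster
    qtl_rows <- vector("list", n_qtl)
    truth_rows <- vector("list", n_qtl)
    i <- 0L
    for (cl in seq_len(nrow(clusters))) {
      ch <- clusters$chrom[cl]
      mu <- clusters$mean_cM[cl]
      tr_avail <- colnames(tset)[tset[cl, ]]
      for (memb in seq_len(cfg$members_per_cluster)) {
        i <- i + 1L
        p <- sample.int(cfg$n_populations, 1L)
        width <- stats::rlnorm(1L, cfg$ci_meanlog, cfg$ci_sdlog)
        s <- max(width / CI_TO_SD_FACTOR, 0.05)
        peak <- min(max(stats::rnorm(1L, mu, s), 0.5), L - 0.5)
        ci_lo <- max(peak - width / 2, 0)
        ci_hi <- min(peak + width / 2, L)
        lod <- stats::runif(1L, cfg$lod_range[1L], cfg$lod_range[2L])
        qtl_rows[[i]] <- data.frame(
          qtl_id = sprintf("Q%04d", i),
          trait = sample(tr_avail, 1L),
          population = pops$population[p],
          cross_type = pops$cross_type[p],
          pop_size = pops$pop_size[p],
          chrom = ch, peak_cM = peak, ci_lo_cM = ci_lo, ci_hi_cM = ci_hi,
          lod = lod, r2 = estimate_r2(lod, pops$pop_size[p]),
          stringsAsFactors = FALSE)
        truth_rows[[i]] <- data.frame(
          qtl_id = sprintf("Q%04d", i), chrom = ch,
          cluster = clusters$cluster[cl], outside = FALSE,
          peak_ref_cM = peak, stringsAsFactors = FALSE)
      }
    }
    qtls <- do.call(rbind, qtl_rows)
    truth_qtl <- do.call(rbind, truth_rows)

    # translate reference coordinates into each QTL's component map
    for (k in seq_len(nrow(qtls))) {
      a <- comp_anchor[[qtls$population[k]]][[qtls$chrom[k]]]
      pts <- interpolate_anchor(
        c(qtls$peak_cM[k], qtls$ci_lo_cM[k], qtls$ci_hi_cM[k]),
        a$ref, a$comp)
      qtls$peak_cM[k] <- pts[1L]
      qtls$ci_lo_cM[k] <- pts[2L]
      qtls$ci_hi_cM[k] <- pts[3L]
    }

    # constructed attrition: relocate a fixed count beyond the last anchor
    n_out <- round(cfg$attrition_fraction * n_qtl)
    if (n_out > 0L) {
      out_idx <- sample.int(n_qtl, n_out)
      for (k in out_idx) {
        a <- comp_anchor[[qtls$population[k]]][[qtls$chrom[k]]]
        top <- max(a$comp)
        width <- qtls$ci_hi_cM[k] - qtls$ci_lo_cM[k]
        qtls$peak_cM[k] <- top + 5 + stats::runif(1L, 0, 10)
        qtls$ci_lo_cM[k] <- qtls$peak_cM[k] - width / 2
        qtls$ci_hi_cM[k] <- qtls$peak_cM[k] + width / 2
        truth_qtl$outside[k] <- TRUE
      }
    }

    # blank effect statistics (never both)
    drop_lod <- stats::runif(n_qtl) < cfg$miss_lod_rate
    drop_r2 <- !drop_lod & stats::runif(n_qtl) < cfg$miss_r2_rate
    qtls$lod[drop_lod] <- NA_real_
    qtls$r2[drop_r2] <- NA_real_

    truth_qtl$trait <- qtls$trait
    list(reference = reference, components = components, qtls = qtls,
         truth = list(clusters = clusters, trait_sets = tset,
                      qtl = truth_qtl, populations = pops,
                      attrition_fraction = n_out / n_qtl))
  })
}

# greedy nearest matching of true means to detected positions (1-1)
greedy_match <- function(true_pos, det_pos) {
  pairs <- list()
  tp <- true_pos; dp <- det_pos
  ti <- seq_along(tp); di <- seq_along(dp)
  while (length(tp) && length(dp)) {
    d <- abs(outer(tp, dp, "-"))
    best <- arrayInd(which.min(d), dim(d))
    pairs[[length(pairs) + 1L]] <- c(ti[best[1L]], di[best[2L]])
    tp <- tp[-best[1L]]; dp <- dp[-best[2L]]
    ti <- ti[-best[1L]]; di <- di[-best[2L]]
  }
  do.call(rbind, pairs)
}

#' Score detected meta-QTLs against the generator's ground truth
#'
#' Reports per-chromosome cluster-count correctness, the RMSE between
#' greedily matched true cluster means and detected consensus positions,
#' and the pair-counting (Rand) agreement between true and detected
#' memberships over the QTLs present in both.
#'
#' @param truth the `truth` element of [generate_study()].
#' @param mqtl the `mqtl` table from [run_meta_analysis()].
#' @return list: `k_table` (per-chromosome true/detected K),
#'   `k_accuracy`, `position_rmse`, `membership_agreement`.
#' @export
recovery_report <- function(truth, mqtl) {
  usable <- truth$qtl[!truth$qtl$outside, , drop = FALSE]
  chroms <- sort(unique(usable$chrom))
  if (!all(mqtl$chrom %in% truth$clusters$chrom)) {
    stop("detected MQTLs reference chromosomes absent from the truth")
  }
  k_rows <- list()
  sqerr <- numeric()
  for (ch in chroms) {
    tcl <- sort(unique(usable$cluster[usable$chrom == ch]))
    tmeans <- truth$clusters$mean_cM[truth$clusters$chrom == ch &
                                       truth$clusters$cluster %in% tcl]
    det <- mqtl[mqtl$chrom == ch, , drop = FALSE]
    k_rows[[ch]] <- data.frame(chrom = ch, k_true = length(tmeans),
                               k_detected = nrow(det),
                               stringsAsFactors = FALSE)
    if (length(tmeans) && nrow(det)) {
      mt <- greedy_match(tmeans, det$position_cM)
      sqerr <- c(sqerr, (tmeans[mt[, 1L]] - det$position_cM[mt[, 2L]])^2)
    }
  }
  k_table <- do.call(rbind, k_rows)
  rownames(k_table) <- NULL

  # membership: detected label = which MQTL lists the QTL as a member
  det_label <- rep(NA_character_, nrow(usable))
  members <- strsplit(mqtl$members, ";", fixed = TRUE)
  for (j in seq_along(members)) {
    det_label[usable$qtl_id %in% members[[j]]] <- mqtl$name[j]
  }
  keep <- !is.na(det_label)
  agreement <- NA_real_
  if (sum(keep) >= 2L) {
    tl <- paste(usable$chrom, usable$cluster)[keep]
    dl <- det_label[keep]
    idx <- utils::combn(sum(keep), 2L)
    same_t <- tl[idx[1L, ]] == tl[idx[2L, ]]
    same_d <- dl[idx[1L, ]] == dl[idx[2L, ]]
    agreement <- mean(same_t == same_d)
  }
  list(k_table = k_table, k_accuracy = mean(with(k_table,
                                                 k_true == k_detected)),
       position_rmse = if (length(sqerr)) sqrt(mean(sqerr)) else NA_real_,
       membership_agreement = agreement)
}
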