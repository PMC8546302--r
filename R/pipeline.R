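# Staged pipeline runner and fixture reporting. Stages execute in order
# (simulate -> project -> meta -> distribution -> traits -> overlap), each
# writing a TSV artifact with a provenance header and a row in the run
# manifest.

pipeline_header <- function(seed, inputs = character()) {
  ver <- as.character(utils::packageVersion("mqtlr"))
  sums <- if (length(inputs)) {
    paste(sprintf("%s=%s", basename(inputs),
                  unname(tools::md5sum(inputs))), collapse = " ")
  } else "none"
  c(sprintf("# mqtlr %s", ver), sprintf("# seed: %d", seed),
    sprintf("# inputs: %s", sums))
}

write_stage_tsv <- function(df, path, seed, inputs = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pipeline_header(seed, inputs), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values given in `overrides` win over the file.
#'
#' @param path path to the config file, or NULL for an empty base.
#' @param overrides named list of overriding values.
#' @return named list of configuration values (strings; callers coerce).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) < 2L) stop("malformed config line: ", ln)
      cfg[[trimws(kv[1L])]] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

#' Run the staged meta-QTL pipeline
#'
#' Executes the enabled stages in dependency order, writing one TSV per
#' stage plus a manifest (stage, artifact, rows, md5) into `out_dir`.
#' Every artifact carries a header comment with the package version, the
#' seed and input checksums. Later stages read the artifacts of earlier
#' ones, so a partial rerun with some stages disabled resumes from disk;
#' a stage whose dependency artifact is missing fails with an explicit
#' message.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in every artifact and used for all
#'   randomness.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "project", "meta", "distribution", "traits",
#'   "overlap")`.
#' @param sim_config optional [simulation_config()] for the simulate
#'   stage; defaults to `simulation_config(seed)`.
#' @param qtl_table,map_dir alternative inputs for `project` when
#'   `simulate` is skipped: a QTL TSV and a directory of map TSVs named
#'   `<population>.tsv` plus `reference.tsv`.
#' @param marker_bp,gwas optional marker-physical-position and GWAS-signal
#'   data.frames enabling the `overlap` stage.
#' @param Kmax model-selection cap passed to [run_meta_analysis()].
#' @return list: `manifest` (data.frame) and `artifacts` (named paths).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         stages = c("simulate", "project", "meta",
                                    "distribution", "traits"),
                         sim_config = NULL, qtl_table = NULL,
                         map_dir = NULL, marker_bp = NULL, gwas = NULL,
                         Kmax = 10L) {
  all_stages <- c("simulate", "project", "meta", "distribution", "traits",
                  "overlap")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(out_dir, name)
  manifest <- list()
  log_stage <- function(stage, path, rows) {
    message(sprintf("[%s] wrote %s (%d rows)", stage, path, rows))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = basename(path), rows = rows,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  need <- function(stage, path) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires artifact ", basename(path),
           ": enable the producing stage or provide the file")
    }
    path
  }

  sim <- NULL
  if ("simulate" %in% stages) {
    if (is.null(sim_config)) sim_config <- simulation_config(seed = seed)
    sim <- generate_study(sim_config)
    write_stage_tsv(sim$qtls, art("qtls.tsv"), seed)
    write_genetic_map(sim$reference, art("map_reference.tsv"))
    for (pid in names(sim$components)) {
      write_genetic_map(sim$components[[pid]],
                        art(sprintf("map_%s.tsv", pid)))
    }
    log_stage("simulate", art("qtls.tsv"), nrow(sim$qtls))
  }

  if ("project" %in% stages) {
    if (!is.null(sim)) {
      qtls <- sim$qtls
      maps <- sim$components
      consensus <- sim$reference
    } else if (!is.null(qtl_table)) {
      qtls <- read_qtl_table(qtl_table)$records
      ref_path <- need("project", file.path(map_dir, "reference.tsv"))
      consensus <- read_genetic_map(ref_path, "reference")
      maps <- list()
      for (pid in unique(qtls$population)) {
        maps[[pid]] <- read_genetic_map(
          need("project", file.path(map_dir, paste0(pid, ".tsv"))), pid)
      }
    } else {
      qtls <- read_qtl_table(need("project", art("qtls.tsv")))$records
      consensus <- read_genetic_map(need("project",
                                         art("map_reference.tsv")),
                                    "reference")
      maps <- list()
      for (pid in unique(qtls$population)) {
        maps[[pid]] <- read_genetic_map(
          need("project", art(sprintf("map_%s.tsv", pid))), pid)
      }
    }
    pr <- project_all(qtls, maps, consensus)
    write_stage_tsv(pr$projected, art("projected.tsv"), seed)
    log_stage("project", art("projected.tsv"), nrow(pr$projected))
    consensus_map <- consensus
  }

  if ("meta" %in% stages) {
    proj <- read_stage_tsv(need("meta", art("projected.tsv")))
    consensus <- if (exists("consensus_map", inherits = FALSE))
      consensus_map else if (file.exists(art("map_reference.tsv")))
        read_genetic_map(art("map_reference.tsv"), "reference") else NULL
    meta <- run_meta_analysis(proj, consensus = consensus, seed = seed,
                              Kmax = Kmax)
    write_stage_tsv(meta$mqtl, art("mqtl.tsv"), seed,
                    inputs = art("projected.tsv"))
    log_stage("meta", art("mqtl.tsv"), nrow(meta$mqtl))
    sel <- do.call(rbind, lapply(names(meta$selection), function(ch) {
      cbind(chrom = ch, meta$selection[[ch]])
    }))
    write_stage_tsv(sel, art("model_selection.tsv"), seed)
  }

  if ("distribution" %in% stages) {
    proj <- read_stage_tsv(need("distribution", art("projected.tsv")))
    located <- proj[proj$status == "projected", , drop = FALSE]
    g <- count_by_genome(located$chrom)$counts
    gr <- count_by_group(located$chrom)$counts
    ch <- count_by_chromosome(located$chrom)$counts
    dist <- rbind(
      data.frame(level = "genome", category = names(g),
                 count = as.integer(g), stringsAsFactors = FALSE),
      data.frame(level = "group", category = names(gr),
                 count = as.integer(gr), stringsAsFactors = FALSE),
      data.frame(level = "chromosome", category = names(ch),
                 count = as.integer(ch), stringsAsFactors = FALSE))
    write_stage_tsv(dist, art("distribution.tsv"), seed,
                    inputs = art("projected.tsv"))
    log_stage("distribution", art("distribution.tsv"), nrow(dist))
  }

  if ("traits" %in% stages) {
    mq <- read_stage_tsv(need("traits", art("mqtl.tsv")))
    pm <- build_presence_matrix(mq)
    targets <- intersect(c("GPC", "GZnC", "GFeC", "GY"), colnames(pm))
    rep <- colocalization_report(pm, targets = targets)
    write_stage_tsv(rep, art("colocalization.tsv"), seed,
                    inputs = art("mqtl.tsv"))
    log_stage("traits", art("colocalization.tsv"), nrow(rep))
    pm_df <- data.frame(mqtl = rownames(pm), as.data.frame(pm),
                        check.names = FALSE)
    write_stage_tsv(pm_df, art("presence_matrix.tsv"), seed)
  }

  if ("overlap" %in% stages) {
    if (is.null(marker_bp) || is.null(gwas)) {
      stop("stage 'overlap' requires marker_bp and gwas inputs")
    }
    mq <- read_stage_tsv(need("overlap", art("mqtl.tsv")))
    consensus <- if (file.exists(art("map_reference.tsv")))
      read_genetic_map(art("map_reference.tsv"), "reference") else NULL
    anch <- anchor_mqtl(mq, marker_bp, consensus = consensus)
    ov <- gwas_overlap(anch$intervals, gwas)
    write_stage_tsv(ov, art("gwas_overlap.tsv"), seed,
                    inputs = art("mqtl.tsv"))
    log_stage("overlap", art("gwas_overlap.tsv"), nrow(ov))
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(), artifact = character(),
               rows = integer(), md5 = character(),
               stringsAsFactors = FALSE)
  utils::write.table(manifest, art("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  arts <- stats::setNames(file.path(out_dir, manifest$artifact),
                          manifest$stage)
  list(manifest = manifest, artifacts = arts)
}

#' Summary report over the packaged meta-QTL catalog
#'
#' Recomputes, from the packaged 100-MQTL catalog, the quantities a reader
#' would check first: the mean confidence-interval width, the number of
#' intervals below 1 cM, per-chromosome MQTL counts, per-trait MQTL counts
#' for the grain target traits, and all pairwise co-localization
#' frequencies among those targets.
#'
#' @param targets trait codes summarized individually (default the four
#'   grain target traits).
#' @return list: `n_mqtl`, `mean_ci_cM`, `n_ci_below_1`,
#'   `per_chromosome` (named counts), `trait_counts` (named counts),
#'   `colocalization` (data.frame `trait`, `target`,
#'   `frequency_percent`).
#' @export
fixture_report <- function(targets = c("GPC", "GZnC", "GFeC", "GY")) {
  cat <- mqtl_catalog()
  pm <- build_presence_matrix(cat)
  targets <- intersect(targets, colnames(pm))
  coloc <- list()
  for (tr in targets) {
    for (tg in setdiff(targets, tr)) {
      coloc[[length(coloc) + 1L]] <- data.frame(
        trait = tr, target = tg,
        frequency_percent = colocalization_frequency(pm, tr, tg),
        stringsAsFactors = FALSE)
    }
  }
  list(n_mqtl = nrow(cat),
       mean_ci_cM = mean(cat$ci_cM),
       n_ci_below_1 = sum(cat$ci_cM < 1),
       per_chromosome = count_by_chromosome(cat$chrom)$counts,
       trait_counts = colSums(pm[, targets, drop = FALSE]),
       colocalization = do.call(rbind, coloc))
}
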