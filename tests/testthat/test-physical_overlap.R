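test_that("anchoring spans the flanking markers and records substitutions", {
  marker_bp <- data.frame(
    marker = c("L", "R", "Lsub", "Rsub"),
    chromosome = "5A",
    mb = c(671.39, 702.96, 650.00, 710.00),
    stringsAsFactors = FALSE)
  mq <- data.frame(name = "MQTL_5A_4", chrom = "5A",
                   left_marker = "L", right_marker = "R",
                   ci_lo_cM = 77, ci_hi_cM = 80, stringsAsFactors = FALSE)
  res <- anchor_mqtl(mq, marker_bp)
  expect_equal(res$intervals$start_mb, 671.39)
  expect_equal(res$intervals$end_mb, 702.96)
  expect_identical(res$intervals$substituted, "")
  # a missing left flank substitutes the nearest mapped marker leftward
  cons <- genetic_map(data.frame(
    marker = c("Lsub", "L", "R", "Rsub"), linkage_group = "5A",
    position_cM = c(70, 76, 81, 85)), "cons")
  mq2 <- data.frame(name = "M", chrom = "5A",
                    left_marker = "ghost", right_marker = "R",
                    ci_lo_cM = 71, ci_hi_cM = 80, stringsAsFactors = FALSE)
  res2 <- anchor_mqtl(mq2, marker_bp, consensus = cons)
  expect_equal(res2$intervals$start_mb, 650)
  expect_match(res2$intervals$substituted, "left=Lsub")
  # no mappable marker on one side -> anchoring failure with reason
  res3 <- anchor_mqtl(mq2, marker_bp)
  expect_equal(nrow(res3$intervals), 0)
  expect_identical(res3$failed$reason, "no_mappable_marker")
  # both flanks at the same position give a valid zero-width interval
  mq4 <- data.frame(name = "M0", chrom = "5A",
                    left_marker = "L", right_marker = "L",
                    ci_lo_cM = 76, ci_hi_cM = 76, stringsAsFactors = FALSE)
  res4 <- anchor_mqtl(mq4, marker_bp)
  expect_equal(res4$intervals$start_mb, res4$intervals$end_mb)
})

test_that("GWAS signals overlap on closed same-chromosome intervals", {
  iv <- data.frame(mqtl = "MQTL_5A_4", chrom = "5A",
                   start_mb = 671.39, end_mb = 702.96,
                   stringsAsFactors = FALSE)
  sig <- data.frame(
    snp = c("AX-110458478", "edge", "off_chrom", "outside"),
    chrom = c("5A", "5A", "5B", "5A"),
    mb = c(692.17, 702.96, 692.17, 710.00),
    trait = "GY", stringsAsFactors = FALSE)
  ov <- gwas_overlap(iv, sig)
  expect_setequal(ov$snp, c("AX-110458478", "edge"))
  # trait restriction drops mismatched signals
  sets <- list(MQTL_5A_4 = c("TKW"))
  expect_equal(nrow(gwas_overlap(iv, sig, trait_sets = sets)), 0)
  # monotone: enlarging the interval never removes an overlap
  bigger <- iv
  bigger$start_mb <- 600; bigger$end_mb <- 750
  ov2 <- gwas_overlap(bigger, sig)
  expect_true(all(ov$snp %in% ov2$snp))
})

test_that("every packaged GWAS signal lands in its catalog interval", {
  ov <- gwas_overlap(mqtl_physical_intervals(), gwas_signal_fixture())
  expect_equal(nrow(ov), 21)
  expect_identical(
    sort(unique(ov$mqtl[ov$snp == "AX-110458478"])), "MQTL_5A_4")
  expect_identical(sort(unique(ov$mqtl[ov$trait == "SNS"])),
                   c("MQTL_2B_1", "MQTL_4D_1", "MQTL_7A_1"))
})

test_that("ortholog pairs link interval pairs across species", {
  iv_a <- data.frame(mqtl = "W1", chrom = "7B",
                     start_mb = 568.10, end_mb = 582.66,
                     stringsAsFactors = FALSE)
  iv_b <- data.frame(mqtl = "R1", chrom = "6",
                     start_mb = 28.85, end_mb = 29.52,
                     stringsAsFactors = FALSE)
  pairs <- data.frame(
    gene_a = c("g1", "g2", "g3", "g4"), chr_a = "7B",
    start_a = c(570, 575, 580, 590), end_a = c(570.1, 575.1, 580.1, 590.1),
    gene_b = c("h1", "h2", "h3", "h4"), chr_b = "6",
    start_b = c(29.0, 29.1, 29.2, 29.3), end_b = c(29.01, 29.11, 29.21, 29.31),
    stringsAsFactors = FALSE)
  res <- detect_ormqtl(iv_a, iv_b, pairs)  # g4 outside the wheat interval
  expect_equal(nrow(res), 1)
  expect_equal(res$n_support, 3)
  expect_identical(res$genes, "g1|h1;g2|h2;g3|h3")
  # no pair inside both intervals -> nothing reported
  none <- detect_ormqtl(iv_a, data.frame(
    mqtl = "R2", chrom = "6", start_mb = 1, end_mb = 2), pairs)
  expect_equal(nrow(none), 0)
  expect_warning(detect_ormqtl(iv_a, iv_b, pairs[0, ]), "empty")
})

test_that("detection is symmetric under swapping the two species", {
  iv <- ormqtl_interval_fixture()
  pairs <- ortholog_pair_fixture()
  rice <- iv$partner_species == "rice"
  iv_a <- data.frame(mqtl = iv$wheat_mqtl[rice], chrom = iv$wheat_chr[rice],
                     start_mb = iv$wheat_start_mb[rice],
                     end_mb = iv$wheat_end_mb[rice])
  iv_b <- data.frame(mqtl = iv$partner_mqtl[rice],
                     chrom = iv$partner_chr[rice],
                     start_mb = iv$partner_start_mb[rice],
                     end_mb = iv$partner_end_mb[rice])
  p_rice <- pairs[pairs$species_b == "rice", ]
  fwd <- detect_ormqtl(iv_a, iv_b, p_rice)
  swapped <- p_rice
  names(swapped)[match(c("gene_a", "chr_a", "start_a", "end_a",
                         "gene_b", "chr_b", "start_b", "end_b"),
                       names(swapped))] <-
    c("gene_b", "chr_b", "start_b", "end_b",
      "gene_a", "chr_a", "start_a", "end_a")
  rev <- detect_ormqtl(iv_b, iv_a, swapped)
  expect_setequal(paste(fwd$mqtl_a, fwd$mqtl_b),
                  paste(rev$mqtl_b, rev$mqtl_a))
})

test_that("the packaged interval tables reproduce the published pairing structure", {
  iv <- ormqtl_interval_fixture()
  pairs <- ortholog_pair_fixture()
  found <- list()
  for (sp in c("rice", "maize")) {
    rows <- iv$partner_species == sp
    iv_a <- unique(data.frame(mqtl = iv$wheat_mqtl[rows],
                              chrom = iv$wheat_chr[rows],
                              start_mb = iv$wheat_start_mb[rows],
                              end_mb = iv$wheat_end_mb[rows]))
    iv_b <- data.frame(mqtl = iv$partner_mqtl[rows],
                       chrom = iv$partner_chr[rows],
                       start_mb = iv$partner_start_mb[rows],
                       end_mb = iv$partner_end_mb[rows])
    res <- detect_ormqtl(iv_a, iv_b, pairs[pairs$species_b == sp, ])
    found[[sp]] <- paste(res$mqtl_a, res$mqtl_b)
  }
  want <- paste(iv$wheat_mqtl, iv$partner_mqtl)
  expect_setequal(c(found$rice, found$maize), want)
  # published structure: ten rice links and eight maize links
  expect_equal(length(found$rice), 10)
  expect_equal(length(found$maize), 8)
})

test_that("BED export converts to 0-based half-open bp", {
  iv <- data.frame(mqtl = "M", chrom = "5A", start_mb = 671.39,
                   end_mb = 702.96, stringsAsFactors = FALSE)
  path <- withr_local_tempfile()
  write_intervals_bed(iv, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 671390000 - 1)
  expect_equal(bed$V3, 702960000)
})
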