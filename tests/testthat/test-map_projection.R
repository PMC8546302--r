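test_that("consensus construction is the identity without components", {
  maps <- toy_maps()
  out <- build_consensus_map(maps$consensus, list())
  expect_equal(as.data.frame(out$map), as.data.frame(maps$consensus))
  expect_equal(nrow(out$report), 0)
})

test_that("component-only markers are placed by anchor interpolation", {
  maps <- toy_maps()
  comp <- genetic_map(data.frame(
    marker = c("a1", "new1", "a2", "far"),
    linkage_group = "1A",
    position_cM = c(10, 15, 20, 35)), "c1")
  out <- build_consensus_map(maps$consensus, list(comp))
  # anchors 10->20 and 20->40: component 15 lands at 30
  expect_equal(out$map$position_cM[out$map$marker == "new1"], 30)
  # 35 is beyond the outermost shared anchor pair span (a3 not shared
  # here: comp lacks a3) -> unplaced
  expect_identical(out$report$status[out$report$marker == "far"],
                   "outside_anchors")
})

test_that("multi-component placements average when consistent, conflict otherwise", {
  maps <- toy_maps()
  c1 <- genetic_map(data.frame(marker = c("a1", "x", "a2"),
                               linkage_group = "1A",
                               position_cM = c(10, 15, 20)), "c1")
  # same marker proposed at consensus 30 by c1 and 32 by c2
  c2 <- genetic_map(data.frame(marker = c("a1", "x", "a2"),
                               linkage_group = "1A",
                               position_cM = c(10, 16, 20)), "c2")
  out <- build_consensus_map(maps$consensus, list(c1, c2))
  expect_equal(out$map$position_cM[out$map$marker == "x"], 31)
  # >5 cM apart -> conflicting, unplaced
  c3 <- genetic_map(data.frame(marker = c("a1", "x", "a2"),
                               linkage_group = "1A",
                               position_cM = c(10, 19, 20)), "c3")
  out2 <- build_consensus_map(maps$consensus, list(c1, c3))
  expect_false("x" %in% out2$map$marker)
  expect_true(any(out2$report$status == "conflicting" &
                    out2$report$marker == "x"))
})

test_that("projection maps peak and interval endpoints by the linear anchor rule", {
  maps <- toy_maps()
  q <- data.frame(qtl_id = "q", chrom = "1A", peak_cM = 15,
                  ci_lo_cM = 12, ci_hi_cM = 18)
  pr <- project_qtl(q, maps$component, maps$consensus)
  expect_identical(pr$status, "projected")
  expect_equal(pr$consensus_peak, 30)
  expect_equal(pr$consensus_ci_lo, 24)
  expect_equal(pr$consensus_ci_hi, 36)
  expect_identical(c(pr$left_anchor, pr$right_anchor), c("a1", "a2"))
  # interval width scales by the local anchor ratio (here exactly 2)
  expect_equal(pr$consensus_ci_hi - pr$consensus_ci_lo,
               (q$ci_hi_cM - q$ci_lo_cM) * 2)
})

test_that("projection through identical maps is the identity and exact on anchors", {
  maps <- toy_maps()
  q <- data.frame(qtl_id = "q", chrom = "1A", peak_cM = 47,
                  ci_lo_cM = 41, ci_hi_cM = 55)
  pr <- project_qtl(q, maps$consensus, maps$consensus)
  expect_equal(pr$consensus_peak, q$peak_cM)
  expect_equal(pr$consensus_ci_lo, q$ci_lo_cM)
  expect_equal(pr$consensus_ci_hi, q$ci_hi_cM)
  # a peak sitting exactly on a shared marker lands on its position
  q2 <- data.frame(qtl_id = "q2", chrom = "1A", peak_cM = 20,
                   ci_lo_cM = 15, ci_hi_cM = 25)
  pr2 <- project_qtl(q2, maps$component, maps$consensus)
  expect_equal(pr2$consensus_peak, 40)
})

test_that("projection failure modes are reported as statuses", {
  maps <- toy_maps()
  # outside the outermost shared anchors: no extrapolation
  q <- data.frame(qtl_id = "q", chrom = "1A", peak_cM = 5,
                  ci_lo_cM = 4, ci_hi_cM = 6)
  expect_identical(project_qtl(q, maps$component, maps$consensus)$status,
                   "outside_anchors")
  # fewer than two shared markers
  lonely <- genetic_map(data.frame(marker = c("a1", "z9"),
                                   linkage_group = "1A",
                                   position_cM = c(10, 30)), "c")
  q2 <- data.frame(qtl_id = "q", chrom = "1A", peak_cM = 20,
                   ci_lo_cM = 18, ci_hi_cM = 22)
  expect_identical(project_qtl(q2, lonely, maps$consensus)$status,
                   "no_anchors")
  # anchor order inversion between the maps
  flipped <- genetic_map(data.frame(marker = c("a2", "a1", "a3"),
                                    linkage_group = "1A",
                                    position_cM = c(5, 15, 30)), "c")
  expect_identical(project_qtl(q2, flipped, maps$consensus)$status,
                   "inverted_anchor_order")
  expect_error(project_qtl(data.frame(qtl_id = "q", chrom = "9Z",
                                      peak_cM = 1, ci_lo_cM = 0,
                                      ci_hi_cM = 2),
                           maps$component, maps$consensus), "absent")
})

test_that("projection preserves order through a shared anchor pair", {
  maps <- toy_maps()
  set.seed(42)
  peaks <- sort(runif(25, 10.5, 29.5))
  mapped <- vapply(peaks, function(p) {
    q <- data.frame(qtl_id = "q", chrom = "1A", peak_cM = p,
                    ci_lo_cM = p - 0.5, ci_hi_cM = p + 0.5)
    project_qtl(q, maps$component, maps$consensus)$consensus_peak
  }, numeric(1))
  expect_true(all(diff(mapped) >= 0))
})

test_that("project_all summarizes attrition and unknown maps", {
  maps <- toy_maps()
  qtls <- data.frame(
    qtl_id = c("q1", "q2", "q3"), trait = "GY",
    population = c("popA", "popA", "ghost"),
    cross_type = "RIL", pop_size = 100, chrom = "1A",
    peak_cM = c(15, 5, 15), ci_lo_cM = c(12, 4, 12),
    ci_hi_cM = c(18, 6, 18), lod = 3, r2 = NA,
    stringsAsFactors = FALSE)
  res <- project_all(qtls, list(popA = maps$component), maps$consensus)
  expect_equal(res$summary$n_total, 3)
  expect_equal(res$summary$n_projected, 1)
  expect_equal(unname(res$summary$by_status[["outside_anchors"]]), 1)
  expect_equal(unname(res$summary$by_status[["no_map"]]), 1)
  # empty input
  empty <- project_all(qtls[0, ], list(popA = maps$component),
                       maps$consensus)
  expect_equal(empty$summary$n_total, 0)
})

test_that("genetic map files round-trip", {
  maps <- toy_maps()
  path <- withr_local_tempfile()
  write_genetic_map(maps$consensus, path)
  back <- read_genetic_map(path, "consensus")
  expect_equal(as.data.frame(back), as.data.frame(maps$consensus))
})
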