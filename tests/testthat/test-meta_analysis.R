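test_that("interval-to-sd conversion uses the 95% normal factor with a floor", {
  expect_equal(ci_to_sd(0, 3.92), 1)
  expect_equal(ci_to_sd(10, 10), 0.05)   # zero width -> floor engages
  expect_equal(ci_to_sd(0, 13.73), 3.50255102040816, tolerance = 1e-12)
  expect_error(ci_to_sd(5, 4), "ci_lo <= ci_hi")
})

test_that("single-observation fit is exact", {
  fit <- fit_mixture(5, 0.7, K = 1)
  expect_equal(fit$means, 5)
  expect_equal(fit$weights, 1)
  expect_equal(fit$loglik, dnorm(5, 5, 0.7, log = TRUE))
  expect_identical(fit$assignment, 1L)
})

test_that("two well-separated pairs are recovered as two clusters", {
  y <- c(10, 10, 50, 50)
  s <- rep(1, 4)
  fit <- fit_mixture(y, s, K = 2, seed = 1)
  expect_equal(fit$means, c(10, 50), tolerance = 1e-6)
  expect_identical(fit$assignment, c(1L, 1L, 2L, 2L))
  expect_equal(unname(table(fit$assignment)), c(2L, 2L),
               ignore_attr = TRUE)
})

test_that("maximized likelihood is non-decreasing in K", {
  set.seed(7)
  y <- c(rnorm(5, 10, 1), rnorm(5, 40, 1))
  s <- runif(10, 0.5, 2)
  lls <- vapply(1:10, function(K) fit_mixture(y, s, K, seed = 3)$loglik,
                numeric(1))
  expect_true(all(diff(lls) > -1e-6))
})

test_that("EM with invalid K or mismatched inputs errors", {
  expect_error(fit_mixture(1:3, rep(1, 3), K = 4), "1 <= K")
  expect_error(fit_mixture(1:3, rep(1, 2), K = 2), "same length")
  expect_error(fit_mixture(1:3, c(1, 0, 1), K = 1), "positive")
})

test_that("EM's hard clustering attains the exhaustive-partition optimum", {
  # spot check; the full 100-instance sweep lives with the acceptance suite
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(3:7, 1)
    mu <- sort(runif(sample(1:3, 1), 0, 80))
    s <- exp(rnorm(n, log(2), 0.4))
    y <- rnorm(n, sample(mu, n, replace = TRUE), s)
    for (K in 1:min(n, 3)) {
      fit <- fit_mixture(y, s, K, seed = rep)
      expect_gte(fit$hard_loglik, oracle_best_loglik(y, s, K) - 1e-6)
    }
  }
})

test_that("model selection votes over five criteria with parsimony ties", {
  # coincident observations: every criterion prefers one component
  res <- select_model(c(30, 30), c(1, 1), seed = 1)
  expect_equal(res$final_K, 1)
  # two clusters five sigma apart, five observations each
  set.seed(5)
  y <- c(rnorm(5, 20, 1), rnorm(5, 20 + 5 * 1, 1) + 20)
  s <- rep(1, 10)
  res2 <- select_model(y, s, seed = 2)
  expect_equal(res2$final_K, 2)
  # criterion table is internally consistent with its definitions
  tab <- res2$table
  p <- 2 * tab$K - 1
  expect_equal(tab$AIC, -2 * tab$loglik + 2 * p)
  expect_equal(tab$AIC3, -2 * tab$loglik + 3 * p)
  expect_equal(tab$BIC, -2 * tab$loglik + p * log(10))
  expect_equal(tab$AWE, -2 * tab$loglik + 2 * p * (log(10) + 1.5))
  defined <- 10 - p - 1 > 0
  expect_equal(tab$AICc[defined],
               (tab$AIC + 2 * p * (p + 1) / (10 - p - 1))[defined])
  expect_true(all(is.na(tab$AICc[!defined])))
})

test_that("a single observation selects one component with only K=1 evaluated", {
  res <- select_model(12, 0.5, seed = 1)
  expect_equal(res$final_K, 1)
  expect_equal(nrow(res$table), 1)
  # AICc abstains (n <= p + 1) but the remaining criteria vote
  expect_true(is.na(res$votes[["AICc"]]))
  expect_true(all(res$votes[c("AIC", "AIC3", "BIC", "AWE")] == 1))
})

test_that("cluster summaries pool by inverse variance", {
  # two members at 10 and 14, both s = 1
  mq <- summarize_mqtl(c(10, 14), c(1, 1), chrom = "1A")
  expect_equal(mq$position_cM, 12)
  expect_equal(mq$ci_cM, 2.77185858225127, tolerance = 1e-12)
  # three members at 0 with s = {1, 1, 2}
  mq2 <- summarize_mqtl(c(0, 0, 0), c(1, 1, 2), chrom = "1A")
  expect_equal(mq2$position_cM, 0)
  expect_equal(mq2$ci_cM, 2.61333333333333, tolerance = 1e-12)
  # single member: interval width equals the member's own width
  mq3 <- summarize_mqtl(7, 1.5, chrom = "1A")
  expect_equal(mq3$position_cM, 7)
  expect_equal(mq3$ci_cM, 3.92 * 1.5)
  expect_error(summarize_mqtl(numeric(0), numeric(0), chrom = "1A"),
               "empty")
})

test_that("flanking markers are the nearest at or outside the interval", {
  cons <- genetic_map(data.frame(
    marker = c("m1", "m2", "m3", "m4"), linkage_group = "1A",
    position_cM = c(0, 10, 20, 30)), "cons")
  mq <- summarize_mqtl(c(14, 16), c(1, 1), chrom = "1A", consensus = cons)
  expect_identical(mq$left_marker, "m2")
  expect_identical(mq$right_marker, "m3")
  # interval reaching past the chromosome end clamps to the end markers
  mq2 <- summarize_mqtl(c(29, 31), c(3, 3), chrom = "1A",
                        consensus = cons)
  expect_identical(mq2$right_marker, "m4")
})

test_that("the chromosome-wise analysis names and orders meta-QTLs", {
  proj <- data.frame(
    qtl_id = c("a", "b", "c", "d", "e"),
    trait = c("GY", "TKW", "GY", "GPC", "GPC"),
    chrom = c("2B", "2B", "2B", "2B", "5D"),
    status = "projected",
    consensus_peak = c(80.5, 81, 20, 20.5, 50),
    consensus_ci_lo = c(77, 78, 17, 18, 46),
    consensus_ci_hi = c(84, 84, 23, 23, 54),
    stringsAsFactors = FALSE)
  res <- run_meta_analysis(proj, seed = 1)
  expect_identical(res$mqtl$name,
                   c("MQTL_2B_1", "MQTL_2B_2", "MQTL_5D_1"))
  expect_true(all(diff(res$mqtl$position_cM[res$mqtl$chrom == "2B"]) > 0))
  expect_identical(res$mqtl$members[1], "c;d")
  expect_identical(res$mqtl$traits[1], "GPC;GY")
  # consensus positions stay inside the member span
  expect_true(all(res$mqtl$position_cM >=
                    c(min(20, 20.5), min(80.5, 81), 50) - 1e-9))
  # pooled intervals are narrower than every member interval
  multi <- res$mqtl[res$mqtl$n_qtl > 1, ]
  expect_true(all(multi$ci_cM < 6))
  # determinism: identical inputs and seed give identical output
  res2 <- run_meta_analysis(proj, seed = 1)
  expect_identical(res, res2)
})

test_that("a lone projected QTL yields a singleton meta-QTL", {
  proj <- data.frame(qtl_id = "only", trait = "GY", chrom = "3A",
                     status = "projected", consensus_peak = 42,
                     consensus_ci_lo = 40, consensus_ci_hi = 44,
                     stringsAsFactors = FALSE)
  res <- run_meta_analysis(proj, seed = 9)
  expect_identical(res$mqtl$name, "MQTL_3A_1")
  expect_equal(res$mqtl$n_qtl, 1)
})
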