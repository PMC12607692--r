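# Per-probe and summary-statistics t-tests, direction counting,
# row standardisation and top-table reporting.

labelled <- function(groups) {
  stats::setNames(groups, sprintf("s%02d", seq_along(groups)))
}

test_that("per-probe Welch test matches hand-derived values and conventions", {
  beta <- rbind(flat = rep(0.5, 6),
                shift = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7))
  colnames(beta) <- sprintf("s%02d", 1:6)
  res <- per_probe_ttest(beta, labelled(rep(c("early", "late"), each = 3)))
  flat <- res[res$probe_id == "flat", ]
  expect_equal(flat$delta_beta, 0)
  expect_equal(flat$t_stat, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$direction, "null")
  shift <- res[res$probe_id == "shift", ]
  expect_equal(shift$delta_beta, 0.3)
  expect_equal(shift$t_stat, 3.674, tolerance = 1e-3)
  expect_equal(shift$df, 4, tolerance = 1e-9)
  expect_equal(shift$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(shift$direction, "hyper_in_late")
})

test_that("per-probe tests agree with stats::t.test on random data", {
  set.seed(19)
  beta <- matrix(runif(40 * 11), 40, 11,
                 dimnames = list(sprintf("cg%02d", 1:40), sprintf("s%02d", 1:11)))
  groups <- labelled(rep(c("early", "late"), c(5, 6)))
  for (variant in c("welch", "pooled")) {
    res <- per_probe_ttest(beta, groups, variant = variant)
    for (i in c(1, 7, 23, 40)) {
      ref <- t.test(beta[i, 6:11], beta[i, 1:5],
                    var.equal = (variant == "pooled"))
      expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(res$df[i], unname(ref$parameter), tolerance = 1e-10)
      expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("swapping group labels negates delta and t but keeps p", {
  set.seed(5)
  beta <- matrix(runif(20 * 9), 20, 9,
                 dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%02d", 1:9)))
  g1 <- labelled(rep(c("early", "late"), c(4, 5)))
  g2 <- labelled(rep(c("late", "early"), c(4, 5)))
  r1 <- per_probe_ttest(beta, g1)
  r2 <- per_probe_ttest(beta, g2)
  expect_equal(r1$delta_beta, -r2$delta_beta)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("direction counting partitions the significant set", {
  res <- structure(data.frame(
    probe_id = c("a", "b", "c", "d"),
    delta_beta = c(0.1, -0.1, 0.2, 0),
    p_value = c(1e-4, 1e-5, 0.5, 1e-6)),
    class = c("diff_result", "data.frame"))
  cc <- classify_counts(res, 0.001)
  expect_equal(cc$n_hypo_in_early, 1)   # delta > 0: higher in late
  expect_equal(cc$n_hyper_in_early, 1)  # delta < 0
  expect_equal(cc$n_significant, 3)
  expect_equal(cc$n_zero_delta, 1)
  expect_equal(cc$n_hyper_in_early + cc$n_hypo_in_early + cc$n_zero_delta,
               cc$n_significant)

  empty <- classify_counts(res, 1e-10)
  expect_equal(empty$n_significant, 0)

  # brute-force recount oracle
  set.seed(2)
  big <- structure(data.frame(
    probe_id = sprintf("cg%04d", 1:1000),
    delta_beta = rnorm(1000),
    p_value = runif(1000)), class = c("diff_result", "data.frame"))
  cc <- classify_counts(big, 0.3)
  expect_equal(cc$n_hyper_in_early,
               sum(big$p_value < 0.3 & big$delta_beta < 0))
  expect_equal(cc$n_hypo_in_early,
               sum(big$p_value < 0.3 & big$delta_beta > 0))
})

test_that("summary-statistics test equals the raw-data test on computed summaries", {
  set.seed(9)
  a <- rnorm(15, 0.4, 0.1); b <- rnorm(16, 0.5, 0.12)
  raw <- t.test(b, a)
  st <- summary_ttest(mean(a), sd(a), 15, mean(b), sd(b), 16,
                      dispersion_mode = "sd")
  expect_equal(st$t, unname(raw$statistic), tolerance = 1e-10)
  expect_equal(st$df, unname(raw$parameter), tolerance = 1e-10)
  expect_equal(st$p, raw$p.value, tolerance = 1e-10)
  # sem mode with sd/sqrt(n) is the same test
  st2 <- summary_ttest(mean(a), sd(a) / sqrt(15), 15,
                       mean(b), sd(b) / sqrt(16), 16,
                       dispersion_mode = "sem")
  expect_equal(st2$p, st$p, tolerance = 1e-12)
  # degenerate equal-mean case
  expect_equal(summary_ttest(1, 0, 5, 1, 0, 5)$p, 1)
})

test_that("row standardisation yields zero-mean unit-sd rows", {
  expect_equal(unname(standardize_rows(rbind(c(1, 2, 3)))[1, ]), c(-1, 0, 1))
  expect_equal(unname(standardize_rows(rbind(rep(0.4, 3)))[1, ]), c(0, 0, 0))
  set.seed(13)
  m <- matrix(rnorm(60), 6, 10)
  z <- standardize_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
})

test_that("top table joins importance ranks with test results and annotation", {
  res <- structure(data.frame(
    probe_id = c("cg1", "cg2", "cg3"),
    mean_early = c(0.2, 0.4, 0.6), mean_late = c(0.3, 0.3, 0.7),
    delta_beta = c(0.1, -0.1, 0.1), t_stat = c(2, -2, 1),
    df = c(5, 5, 5), p_value = c(0.01, 0.02, 0.3),
    direction = c("hyper_in_late", "hypo_in_late", "hyper_in_late")),
    class = c("diff_result", "data.frame"))
  imp <- data.frame(variable = c("cg3", "cg1", "cg2"), count = c(5, 3, 1),
                    frequency_pct = c(50, 30, 10), rank = 1:3)
  tt <- top_table(res, imp, k = 2)
  expect_equal(tt$variable, c("cg3", "cg1"))
  expect_equal(tt$delta_beta, c(0.1, 0.1))
  expect_true(all(c("p_value", "frequency_pct") %in% names(tt)))
  expect_equal(nrow(top_table(res, imp, k = 0)), 0)
  expect_warning(top_table(res, imp, k = 5), "truncating")
})
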