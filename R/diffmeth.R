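# Per-probe two-group differential methylation, summary-statistics t-tests,
# row-wise standardisation and top-hit reporting.

#' Per-probe two-group t-tests on a beta matrix
#'
#' For every probe, computes the early- and late-group means, the
#' methylation difference `delta_beta = mean(late) - mean(early)`, and a
#' two-sided two-sample t-test (Welch-Satterthwaite degrees of freedom by
#' default, pooled-variance optionally). Direction is called from the sign
#' of `delta_beta`: positive means hypermethylated in the late group. When
#' both groups have zero variance and equal means the convention is t = 0,
#' p = 1 (constant probes are never significant); with zero variance and
#' unequal means the difference is infinitely many standard errors wide and
#' p = 0. All tests are vectorised across probes.
#'
#' @param beta probes x samples numeric matrix.
#' @param labels group labels aligned with the columns of `beta`: a factor
#'   or character vector with values `"early"` (the reference group) and
#'   `"late"`, or a named vector matched by sample ID.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A data.frame of class `"diff_result"` with columns `probe_id`,
#'   `mean_early`, `mean_late`, `delta_beta`, `t_stat`, `df`, `p_value`,
#'   `direction` (`hyper_in_late` / `hypo_in_late` / `null`).
#' @examples
#' beta <- rbind(cg1 = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7))
#' colnames(beta) <- paste0("S", 1:6)
#' per_probe_ttest(beta, rep(c("early", "late"), each = 3))
#' @export
per_probe_ttest <- function(beta, labels, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(beta))
  labels <- align_labels(labels, colnames(beta), ncol(beta))
  e <- labels == "early"; l <- labels == "late"
  n1 <- sum(e); n2 <- sum(l)
  assert_that(n1 >= 2 && n2 >= 2,
              "each group needs at least 2 samples (got %d early, %d late)",
              n1, n2)
  xe <- beta[, e, drop = FALSE]; xl <- beta[, l, drop = FALSE]
  m1 <- rowMeans(xe); m2 <- rowMeans(xl)
  v1 <- rowSums((xe - m1)^2) / (n1 - 1)
  v2 <- rowSums((xl - m2)^2) / (n2 - 1)
  delta <- m2 - m1
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  t_stat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- se2 == 0
  zero_diff <- degen & delta == 0
  t_stat[zero_diff] <- 0; p[zero_diff] <- 1
  df[degen & !is.finite(df)] <- n1 + n2 - 2
  t_stat[degen & delta != 0] <- sign(delta[degen & delta != 0]) * Inf
  p[degen & delta != 0] <- 0
  structure(data.frame(
    probe_id = rownames(beta) %||% as.character(seq_len(nrow(beta))),
    mean_early = m1, mean_late = m2, delta_beta = delta,
    t_stat = t_stat, df = df, p_value = p,
    direction = ifelse(delta > 0, "hyper_in_late",
                       ifelse(delta < 0, "hypo_in_late", "null")),
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("diff_result", "data.frame"))
}

align_labels <- function(labels, sample_ids, n) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!is.null(names(labels)) && !is.null(sample_ids)) {
    assert_that(all(sample_ids %in% names(labels)),
                "every beta-matrix sample must be labeled")
    labels <- labels[sample_ids]
  }
  assert_that(length(labels) == n,
              "labels length (%d) must match sample count (%d)",
              length(labels), n)
  assert_that(all(labels %in% c("early", "late")),
              "group labels must be 'early' or 'late'")
  labels
}

#' Count significant probes by direction relative to the early group
#'
#' Among probes with `p < p_threshold`, counts those hypermethylated in the
#' early group (`delta_beta < 0`, i.e. hypomethylated in late) and those
#' hypomethylated in early (`delta_beta > 0`). Probes with exactly zero
#' difference are reported separately so the two direction counts partition
#' the significant set. The reference group is stated in the output names.
#'
#' @param results a `"diff_result"` data.frame.
#' @param p_threshold significance threshold (default 0.001).
#' @return Named list: `n_hyper_in_early`, `n_hypo_in_early`,
#'   `n_significant`, `n_zero_delta`.
#' @export
classify_counts <- function(results, p_threshold = 0.001) {
  assert_that(nrow(results) > 0, "empty results")
  sig <- results[results$p_value < p_threshold, , drop = FALSE]
  list(n_hyper_in_early = sum(sig$delta_beta < 0),
       n_hypo_in_early = sum(sig$delta_beta > 0),
       n_significant = nrow(sig),
       n_zero_delta = sum(sig$delta_beta == 0))
}

#' Two-sample t-test from summary statistics
#'
#' Computes the t statistic, degrees of freedom and two-sided p-value from
#' per-group mean, dispersion and sample size, as printed in a cohort
#' characteristics table. In `"sem"` mode the dispersion is taken as the
#' standard error of the group mean; in `"sd"` mode it is a standard
#' deviation and is divided by `sqrt(n)` first. The statistic is oriented
#' as group b minus group a. Both dispersions zero with equal means gives
#' the t = 0, p = 1 convention.
#'
#' @param mean_a,disp_a,n_a group a mean, dispersion and size.
#' @param mean_b,disp_b,n_b group b mean, dispersion and size.
#' @param dispersion_mode `"sem"` or `"sd"`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return Named list with `t`, `df`, `p`.
#' @examples
#' # age row of a 15-vs-16 cohort table, dispersions read as SEMs
#' summary_ttest(8.22, 0.39, 15, 8.86, 0.29, 16)
#' @export
summary_ttest <- function(mean_a, disp_a, n_a, mean_b, disp_b, n_b,
                          dispersion_mode = c("sem", "sd"),
                          variant = c("welch", "pooled")) {
  dispersion_mode <- match.arg(dispersion_mode)
  variant <- match.arg(variant)
  assert_that(n_a >= 2 && n_b >= 2, "group sizes must be at least 2")
  assert_that(disp_a >= 0 && disp_b >= 0, "dispersions must be nonnegative")
  se_a <- if (dispersion_mode == "sem") disp_a else disp_a / sqrt(n_a)
  se_b <- if (dispersion_mode == "sem") disp_b else disp_b / sqrt(n_b)
  v_a <- se_a^2 * n_a; v_b <- se_b^2 * n_b  # implied group variances
  if (variant == "welch") {
    se2 <- se_a^2 + se_b^2
    df <- se2^2 / (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    se2 <- sp2 * (1 / n_a + 1 / n_b)
    df <- n_a + n_b - 2
  }
  if (se2 == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = n_a + n_b - 2, p = 1))
    return(list(t = sign(mean_b - mean_a) * Inf, df = n_a + n_b - 2, p = 0))
  }
  t <- (mean_b - mean_a) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Standardise matrix rows to z-scores
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation 1
#' (n - 1 denominator), the transform behind relative-methylation heatmaps.
#' Constant rows map to all zeros.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape.
#' @examples
#' standardize_rows(rbind(c(1, 2, 3)))  # -1 0 1
#' @export
standardize_rows <- function(m) {
  stopifnot(is.matrix(m))
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  out <- (m - mu) / s
  out[s == 0, ] <- 0
  out
}

#' Top-k report joining importance ranking with differential results
#'
#' Extracts the `k` highest-ranked variables from a SWAG importance table
#' and joins each with its group means, methylation difference, t-test
#' results and (optionally) manifest annotation, preserving the importance
#' order.
#'
#' @param results `"diff_result"` data.frame.
#' @param importance importance table from [variable_importance()].
#' @param k number of top variables (default 10); truncated with a warning
#'   when fewer are available.
#' @param annotation optional annotated probe table (from
#'   [annotate_probes()]) joined by probe ID.
#' @return data.frame in importance order.
#' @export
top_table <- function(results, importance, k = 10, annotation = NULL) {
  if (k > nrow(importance)) {
    warning(sprintf("only %d variables available; truncating k = %d",
                    nrow(importance), k))
    k <- nrow(importance)
  }
  top <- utils::head(importance, k)
  if (k == 0)
    return(cbind(top, results[0, setdiff(names(results), "probe_id"),
                              drop = FALSE]))
  idx <- match(top$variable, results$probe_id)
  out <- cbind(top, results[idx, setdiff(names(results), "probe_id"),
                            drop = FALSE])
  if (!is.null(annotation)) {
    aidx <- match(top$variable, annotation$probe_id)
    out <- cbind(out, annotation[aidx, setdiff(names(annotation), "probe_id"),
                                 drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
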