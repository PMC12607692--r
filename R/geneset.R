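# Gene-set cross-comparison: plain-text gene sets, exact set intersections
# (Venn counts), gene-level p-values and Benjamini-Yekutieli FDR control.

#' Load a plain-text gene set
#'
#' One symbol per line; `#` starts a comment (full-line or trailing);
#' symbols are trimmed, uppercased and deduplicated. The number of
#' duplicates dropped is reported via a message.
#'
#' @param path text file path.
#' @param name label for the set (defaults to the file name).
#' @return A list of class `"gene_set"` with `name` and `symbols`.
#' @export
load_gene_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  symbols <- toupper(trimws(lines))
  symbols <- symbols[nzchar(symbols)]
  assert_that(length(symbols) > 0, "gene set file '%s' contains no symbols",
              path)
  n_dup <- sum(duplicated(symbols))
  if (n_dup > 0)
    message(sprintf("gene set '%s': dropped %d duplicate symbol%s",
                    name %||% basename(path), n_dup,
                    if (n_dup > 1) "s" else ""))
  gene_set(unique(symbols), name %||% basename(path))
}

#' Construct a gene set from symbols
#'
#' @param symbols character gene symbols (uppercased and deduplicated).
#' @param name set label.
#' @return A list of class `"gene_set"`.
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- unique(toupper(symbols))
  assert_that(length(symbols) > 0, "gene set must be nonempty")
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Write a gene set back to a plain-text file
#'
#' @param set a `"gene_set"`.
#' @param path output path.
#' @export
write_gene_set <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$symbols, path)
  invisible(path)
}

#' Cross-compare a study gene list with two reference gene sets
#'
#' Computes the exact intersections behind a three-set Venn diagram: study
#' genes overlapping set A, set B, and both (the triple overlap). When
#' per-gene p-values are supplied, the triple-overlap genes (or the whole
#' significant family, see `by_family`) are adjusted with the
#' Benjamini-Yekutieli procedure.
#'
#' @param study a `"gene_set"` of study genes (e.g. significant
#'   differentially methylated genes).
#' @param a,b reference `"gene_set"` objects (e.g. sleep- and
#'   obesity-associated genes).
#' @param gene_pvals optional named numeric vector of per-gene p-values
#'   (names are uppercase symbols; see [gene_level_p()]).
#' @param by_family family over which BY adjustment runs: `"triple"`
#'   (default, only the triple-overlap genes) or `"all"` (every study gene
#'   with a p-value).
#' @return A list of class `"overlap_report"` with counts `n_a`, `n_b`,
#'   `n_triple`, sorted member lists `in_a`, `in_b`, `in_both`, and, when
#'   p-values are given, a data.frame `triple_pvals` with raw and
#'   BY-adjusted p per triple-overlap gene.
#' @export
intersect_sets <- function(study, a, b, gene_pvals = NULL,
                           by_family = c("triple", "all")) {
  by_family <- match.arg(by_family)
  stopifnot(inherits(study, "gene_set"), inherits(a, "gene_set"),
            inherits(b, "gene_set"))
  in_a <- sort(intersect(study$symbols, a$symbols))
  in_b <- sort(intersect(study$symbols, b$symbols))
  in_both <- sort(intersect(in_a, in_b))
  rep <- list(n_a = length(in_a), n_b = length(in_b),
              n_triple = length(in_both),
              in_a = in_a, in_b = in_b, in_both = in_both,
              set_a = a$name, set_b = b$name)
  if (!is.null(gene_pvals) && length(in_both)) {
    names(gene_pvals) <- toupper(names(gene_pvals))
    fam <- if (by_family == "triple") in_both else
      intersect(study$symbols, names(gene_pvals))
    fam <- fam[fam %in% names(gene_pvals)]
    adj <- benjamini_yekutieli(gene_pvals[fam])
    keep <- in_both[in_both %in% fam]
    rep$triple_pvals <- data.frame(
      gene = keep,
      p = unname(gene_pvals[keep]),
      p_by = unname(adj[match(keep, fam)]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(rep, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Gene-set overlap: %d study genes in '%s', %d in '%s', %d in both\n",
              x$n_a, x$set_a, x$n_b, x$set_b, x$n_triple))
  if (!is.null(x$triple_pvals)) {
    cat("Triple-overlap genes (Benjamini-Yekutieli adjusted):\n")
    print(x$triple_pvals, row.names = FALSE)
  }
  invisible(x)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence: with `m` tests
#' and sorted p-values `p_(1) <= ... <= p_(m)`, the adjusted value for rank
#' `j` is `min over i >= j of p_(i) * m * c(m) / i`, capped at 1, where
#' `c(m) = sum(1/i, i = 1..m)` is the harmonic inflation constant. Output
#' order matches input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values in the input order.
#' @examples
#' benjamini_yekutieli(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
benjamini_yekutieli <- function(p) {
  assert_that(length(p) > 0, "p-value vector is empty")
  assert_that(all(!is.na(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(p)
  out
}

#' Collapse per-probe p-values to gene level
#'
#' A gene typically maps to several CpG probes; this collapses the probe
#' p-values for each gene to a single value, either the minimum over the
#' gene's probes (default) or Fisher's combination
#' (`-2 * sum(log p)` against a chi-squared with `2k` df).
#'
#' @param results `"diff_result"` data.frame with `probe_id` and `p_value`.
#' @param annotated annotated probe table (the `table` element of
#'   [annotate_probes()]) mapping probes to genes.
#' @param method `"min"` or `"fisher"`.
#' @return Named numeric vector of gene-level p-values.
#' @export
gene_level_p <- function(results, annotated, method = c("min", "fisher")) {
  method <- match.arg(method)
  idx <- match(annotated$probe_id, results$probe_id)
  pairs <- do.call(rbind, lapply(which(!is.na(idx)), function(i) {
    g <- annotated$genes[[i]]
    if (!length(g)) return(NULL)
    data.frame(gene = g, p = results$p_value[idx[i]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(stats::setNames(numeric(0), character(0)))
  split_p <- split(pairs$p, pairs$gene)
  vapply(split_p, function(ps) {
    if (method == "min") min(ps)
    else stats::pchisq(-2 * sum(log(pmax(ps, .Machine$double.xmin))),
                       df = 2 * length(ps), lower.tail = FALSE)
  }, numeric(1))
}
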