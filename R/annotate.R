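# Manifest-based probe annotation and genomic-context distributions.

normalize_genes <- function(raw) {
  lapply(raw, function(g) {
    if (is.na(g) || g == "" || g == "~") return(character(0))
    toupper(unique(strsplit(g, ";", fixed = TRUE)[[1]]))
  })
}

normalize_category <- function(x, vocab, missing_value) {
  x[is.na(x) | x == "" | x == "~"] <- missing_value
  bad <- setdiff(unique(x), vocab)
  assert_that(length(bad) == 0,
              "unknown annotation categor%s: %s",
              if (length(bad) > 1) "ies" else "y",
              paste(bad, collapse = ", "))
  x
}

#' Load and normalise an Illumina-style probe manifest
#'
#' Reads a manifest CSV with columns `IlmnID`, `UCSC_RefGene_Name`, `CHR`,
#' `UCSC_RefGene_Group`, `Relation_to_UCSC_CpG_Island`,
#' `Regulatory_Feature_Group`. Gene fields are split on ";", deduplicated
#' preserving order and uppercased; `"~"` and empty fields normalise to the
#' unmapped/unassigned categories; all categorical values are validated
#' against the closed vocabularies.
#'
#' @param path manifest CSV path.
#' @return A data.frame with columns `probe_id`, `genes` (list column of
#'   character vectors), `chromosome`, `refgene_group`, `island_relation`,
#'   `regulatory_feature`.
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("IlmnID", "UCSC_RefGene_Name", "CHR", "UCSC_RefGene_Group",
                "Relation_to_UCSC_CpG_Island", "Regulatory_Feature_Group")
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0,
              "manifest is missing required column%s: %s",
              if (length(missing) > 1) "s" else "",
              paste(missing, collapse = ", "))
  dup <- df$IlmnID[duplicated(df$IlmnID)]
  assert_that(length(dup) == 0, "duplicate probe ID%s in manifest: %s",
              if (length(dup) > 1) "s" else "",
              paste(unique(dup), collapse = ", "))
  out <- data.frame(probe_id = df$IlmnID, stringsAsFactors = FALSE)
  out$genes <- I(normalize_genes(df$UCSC_RefGene_Name))
  out$chromosome <- df$CHR
  out$refgene_group <- normalize_category(df$UCSC_RefGene_Group,
                                          .refgene_vocab, "unmapped")
  out$island_relation <- normalize_category(df$Relation_to_UCSC_CpG_Island,
                                            .island_vocab, "unassigned")
  out$regulatory_feature <- normalize_category(df$Regulatory_Feature_Group,
                                               .regulatory_vocab, "unmapped")
  out
}

#' Annotate a set of probes against a loaded manifest
#'
#' Left-joins the probe IDs onto the manifest; probes absent from the
#' manifest get empty gene lists and unmapped/unassigned categories. Also
#' returns the deduplicated gene symbol list across all input probes, in
#' first-appearance order.
#'
#' @param probe_ids character probe identifiers.
#' @param manifest output of [load_manifest()].
#' @return A list with `table` (one row per input probe, manifest columns)
#'   and `genes` (deduplicated character vector).
#' @export
annotate_probes <- function(probe_ids, manifest) {
  idx <- match(probe_ids, manifest$probe_id)
  tab <- data.frame(probe_id = probe_ids, stringsAsFactors = FALSE)
  genes <- manifest$genes[idx]
  genes[is.na(idx)] <- list(character(0))
  tab$genes <- I(genes)
  tab$chromosome <- ifelse(is.na(idx), "unmapped", manifest$chromosome[idx])
  tab$refgene_group <- ifelse(is.na(idx), "unmapped",
                              manifest$refgene_group[idx])
  tab$island_relation <- ifelse(is.na(idx), "unassigned",
                                manifest$island_relation[idx])
  tab$regulatory_feature <- ifelse(is.na(idx), "unmapped",
                                   manifest$regulatory_feature[idx])
  list(table = tab, genes = unique(unlist(tab$genes)))
}

#' Genomic-context distribution of annotated probes
#'
#' Tabulates one annotation field over its closed vocabulary and reports,
#' for each category, the count plus two percentages: of all input probes,
#' and of annotated probes (those not in the unmapped/unassigned bucket).
#' Both denominators are carried in the result and printed with every
#' percentage, because the two bases can differ substantially.
#'
#' @param annotated annotated probe table (the `table` element of
#'   [annotate_probes()]).
#' @param field one of `"refgene_group"`, `"island_relation"`,
#'   `"regulatory_feature"`.
#' @return A data.frame of class `"context_distribution"` with columns
#'   `category`, `count`, `pct_of_all`, `pct_of_annotated` (NA for the
#'   unmapped/unassigned category itself), plus attributes `n_all`,
#'   `n_annotated` and `field`.
#' @export
context_distribution <- function(annotated,
                                 field = c("refgene_group",
                                           "island_relation",
                                           "regulatory_feature")) {
  field <- match.arg(field)
  assert_that(nrow(annotated) > 0, "annotated table is empty")
  vocab <- switch(field,
                  refgene_group = .refgene_vocab,
                  island_relation = .island_vocab,
                  regulatory_feature = .regulatory_vocab)
  missing_cat <- switch(field,
                        refgene_group = "unmapped",
                        island_relation = "unassigned",
                        regulatory_feature = "unmapped")
  x <- annotated[[field]]
  counts <- as.integer(table(factor(x, levels = vocab)))
  n_all <- length(x)
  n_annot <- sum(x != missing_cat)
  out <- data.frame(category = vocab, count = counts,
                    pct_of_all = 100 * counts / n_all,
                    pct_of_annotated = ifelse(vocab == missing_cat, NA_real_,
                                              100 * counts / n_annot),
                    stringsAsFactors = FALSE)
  structure(out, n_all = n_all, n_annotated = n_annot, field = field,
            class = c("context_distribution", "data.frame"))
}

#' @export
print.context_distribution <- function(x, ...) {
  cat(sprintf("Distribution of %s (n = %d probes, %d annotated):\n",
              attr(x, "field"), attr(x, "n_all"), attr(x, "n_annotated")))
  df <- as.data.frame(x)
  df$pct_of_all <- sprintf("%.1f%% of %d", df$pct_of_all, attr(x, "n_all"))
  df$pct_of_annotated <- ifelse(is.na(x$pct_of_annotated), "-",
                                sprintf("%.1f%% of %d", x$pct_of_annotated,
                                        attr(x, "n_annotated")))
  print(df, row.names = FALSE)
  invisible(x)
}
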