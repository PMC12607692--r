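# Intensity-panel preprocessing: negative-control background normalisation,
# bead/detection probe filters, and beta-value computation.

#' Background-normalise an intensity panel using negative controls
#'
#' Subtracts, per sample, the mean of that sample's negative-control
#' intensities from every methylated and unmethylated signal, flooring at 0.
#' The controls themselves are left untouched so the operation is
#' idempotent only in the trivial zero-background case.
#'
#' @param panel an [intensity_panel()].
#' @return The panel with background-corrected `meth` and `unmeth`.
#' @export
background_normalize <- function(panel) {
  stopifnot(inherits(panel, "intensity_panel"))
  n <- ncol(panel$meth)
  ids <- colnames(panel$meth) %||% as.character(seq_len(n))
  for (j in seq_len(n)) {
    ctrl <- panel$neg_controls[[j]]
    assert_that(length(ctrl) > 0,
                "sample '%s' has no negative-control intensities", ids[j])
  }
  bg <- vapply(panel$neg_controls[seq_len(n)], mean, numeric(1))
  panel$meth <- pmax(sweep(panel$meth, 2, bg), 0)
  panel$unmeth <- pmax(sweep(panel$unmeth, 2, bg), 0)
  panel
}

#' Filter probes on bead counts and detection p-values
#'
#' A probe is excluded when, in any sample, its bead count falls below
#' `bead_min` (default: data from two beads or fewer) or its detection
#' p-value exceeds `detection_max`. This complete-case rule keeps every
#' retained probe observed in every sample, which downstream model fits
#' require.
#'
#' @param panel an [intensity_panel()].
#' @param bead_min minimum acceptable bead count (probes with fewer in any
#'   sample are dropped).
#' @param detection_max maximum acceptable detection p-value.
#' @return A list with `mask` (logical, TRUE = retained, named by probe) and
#'   `report`, a `"qc_report"` tallying exclusions by reason; a probe may
#'   carry both reason codes.
#' @export
filter_probes <- function(panel, bead_min = 3, detection_max = 0.01) {
  stopifnot(inherits(panel, "intensity_panel"))
  low_beads <- apply(panel$beads < bead_min, 1, any)
  high_detp <- apply(panel$detection_p > detection_max, 1, any)
  mask <- !(low_beads | high_detp)
  ids <- rownames(panel$beads) %||% as.character(seq_len(nrow(panel$beads)))
  names(mask) <- ids
  excluded <- which(!mask)
  report <- structure(list(
    n_input_probes = length(mask),
    n_excluded_beads = sum(low_beads),
    n_excluded_detection = sum(high_detp),
    n_retained = sum(mask),
    reasons = data.frame(probe_id = ids[excluded],
                         low_beads = low_beads[excluded],
                         high_detection_p = high_detp[excluded],
                         row.names = NULL, stringsAsFactors = FALSE)
  ), class = "qc_report")
  list(mask = mask, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Probe QC: %d input, %d retained (%d excluded: %d low beads, %d high detection p; reasons may overlap)\n",
              x$n_input_probes, x$n_retained,
              x$n_input_probes - x$n_retained,
              x$n_excluded_beads, x$n_excluded_detection))
  invisible(x)
}

#' Compute beta-values from an intensity panel
#'
#' The methylation fraction of each probe/sample cell is the ratio of
#' methylated intensity to total intensity,
#' `beta = M / (M + U + offset)`. The offset (default 100, the array
#' community's intensity-stabilisation constant) guards low-intensity cells;
#' set it to 0 for the plain ratio. Cells with a zero denominator (possible
#' only at offset 0) are defined as beta = 0.
#'
#' @param panel a background-normalised [intensity_panel()].
#' @param offset nonnegative denominator offset.
#' @return Probes x samples matrix of beta-values in \[0, 1\].
#' @export
compute_beta <- function(panel, offset = 100) {
  stopifnot(inherits(panel, "intensity_panel"))
  assert_that(offset >= 0, "offset must be nonnegative")
  denom <- panel$meth + panel$unmeth + offset
  beta <- panel$meth / denom
  beta[denom == 0] <- 0
  beta
}

#' Preprocess an intensity panel into a QC-filtered beta matrix
#'
#' Chains [background_normalize()], [filter_probes()] and [compute_beta()]:
#' the standard route from raw signals to an analysis-ready beta matrix.
#'
#' @inheritParams filter_probes
#' @inheritParams compute_beta
#' @return A list with `beta` (retained probes only) and the `qc_report`.
#' @examples
#' cfg <- sim_config(n_probes = 50, n_planted = 0, seed = 7)
#' ds <- simulate_dataset(cfg)
#' pp <- preprocess_panel(ds$panel)
#' pp$qc
#' @export
preprocess_panel <- function(panel, bead_min = 3, detection_max = 0.01,
                             offset = 100) {
  panel <- background_normalize(panel)
  flt <- filter_probes(panel, bead_min = bead_min,
                       detection_max = detection_max)
  beta <- compute_beta(panel, offset = offset)
  list(beta = beta[flt$mask, , drop = FALSE], qc = flt$report)
}
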