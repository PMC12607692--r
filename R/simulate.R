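# Synthetic EPIC-like data generator: phenotypes, beta matrices with planted
# group-differential probes, raw intensity panels with QC artifacts, and a
# miniature manifest. Everything is seeded and byte-reproducible.

#' Simulation configuration for synthetic EPIC-like datasets
#'
#' Bundles and validates all knobs of the synthetic data generator. The
#' defaults emulate the study conditions the package targets: a two-group
#' design with 15 early-bedtime and 16 late-bedtime children, a bimodal
#' baseline beta-value profile, and a small set of planted group-differential
#' CpGs whose default effect size (|delta beta| = 0.115) matches a strong
#' array-scale differential methylation signal.
#'
#' @param n_early,n_late samples per group (each at least 2).
#' @param n_probes number of CpG probes.
#' @param n_planted number of probes given a true group-mean shift.
#' @param delta_beta planted shift on the beta scale, in (-1, 1); each
#'   planted probe receives `+delta_beta` or `-delta_beta` (late minus early)
#'   with a randomly drawn sign.
#' @param beta_shape_a,beta_shape_b shape parameters of the baseline Beta
#'   mixture; baselines are drawn from an equal mixture of
#'   `Beta(a, b)` (hypomethylated mode) and `Beta(b, a)` (hypermethylated
#'   mode), then clamped to \[0.05, 0.95\].
#' @param noise_sd_logit per-sample biological/technical noise sd applied on
#'   the logit scale and back-transformed, so values stay inside (0, 1).
#' @param intensity_scale mean total (methylated + unmethylated) intensity.
#' @param intensity_sd per-channel additive intensity noise sd.
#' @param control_mean,control_sd negative-control background intensity
#'   distribution.
#' @param fail_fraction fraction of probe/sample cells given a failing QC
#'   artifact (detection p > 0.01 or bead count <= 2), in \[0, 1).
#' @param confound_strength optional shift (in covariate sd units) added to
#'   the late group's covariates, for robustness experiments; 0 by default so
#'   covariates are not confounded with group.
#' @param seed master integer seed; all stages derive sub-streams from it.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_probes = 200, n_planted = 5, seed = 42)
#' @export
sim_config <- function(n_early = 15, n_late = 16,
                       n_probes = 1000, n_planted = 10,
                       delta_beta = 0.115,
                       beta_shape_a = 2, beta_shape_b = 8,
                       noise_sd_logit = 0.25,
                       intensity_scale = 10000, intensity_sd = 100,
                       control_mean = 300, control_sd = 50,
                       fail_fraction = 0,
                       confound_strength = 0,
                       seed = 1L) {
  assert_that(n_early >= 2 && n_late >= 2,
              "group sizes must be at least 2 (got %d early, %d late)",
              n_early, n_late)
  assert_that(n_probes >= 1, "n_probes must be positive")
  assert_that(n_planted >= 0 && n_planted <= n_probes,
              "n_planted must lie in [0, n_probes]")
  assert_that(abs(delta_beta) < 1, "delta_beta must lie in (-1, 1)")
  assert_that(beta_shape_a > 0 && beta_shape_b > 0,
              "Beta shape parameters must be positive")
  assert_that(noise_sd_logit >= 0, "noise_sd_logit must be nonnegative")
  assert_that(intensity_scale > 0, "intensity_scale must be positive")
  assert_that(control_mean >= 0 && control_sd >= 0,
              "control intensity parameters must be nonnegative")
  assert_that(fail_fraction >= 0 && fail_fraction < 1,
              "fail_fraction must lie in [0, 1)")
  cfg <- list(n_early = as.integer(n_early), n_late = as.integer(n_late),
              n_probes = as.integer(n_probes),
              n_planted = as.integer(n_planted),
              delta_beta = delta_beta,
              beta_shape_a = beta_shape_a, beta_shape_b = beta_shape_b,
              noise_sd_logit = noise_sd_logit,
              intensity_scale = intensity_scale, intensity_sd = intensity_sd,
              control_mean = control_mean, control_sd = control_sd,
              fail_fraction = fail_fraction,
              confound_strength = confound_strength,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic EPIC simulation config: %d early + %d late samples, %d probes (%d planted at |delta beta| = %g), seed %d\n",
              x$n_early, x$n_late, x$n_probes, x$n_planted,
              abs(x$delta_beta), x$seed))
  invisible(x)
}

#' Generate a synthetic phenotype table
#'
#' Produces one row per child with a bedtime group label and anthropometric
#' covariates (age, sex, BMI z-score, waist-circumference z-score,
#' waist-to-height-ratio z-score). The group-wise covariate means and
#' dispersions approximate the pediatric cohort the generator emulates; ages
#' are restricted to the 6-10 year recruitment window. Covariates are not
#' confounded with group unless `confound_strength` is set in the config.
#'
#' @param config a [sim_config()] object.
#' @return A data.frame with columns `sample_id`, `bedtime_group`
#'   (factor early/late), `sex`, `age_years`, `bmi_z`, `wc_z`, `whtr_z`.
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_early + config$n_late
  with_seed(derive_seed(config$seed, "phenotypes"), {
    grp <- factor(rep(c("early", "late"), c(config$n_early, config$n_late)),
                  levels = c("early", "late"))
    late <- as.integer(grp == "late")
    shift <- config$confound_strength * late
    # group means/dispersions chosen to approximate the emulated cohort
    age <- stats::rnorm(n, ifelse(late == 1, 8.86, 8.22), 1.2) + shift * 1.2
    bmi_z <- stats::rnorm(n, ifelse(late == 1, 1.62, 0.91), 1.3) + shift * 1.3
    wc_z <- stats::rnorm(n, ifelse(late == 1, 0.97, 0.84), 0.65) + shift * 0.65
    whtr_z <- stats::rnorm(n, ifelse(late == 1, 0.75, 0.63), 0.68) + shift * 0.68
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      bedtime_group = grp,
      sex = sample(c("M", "F"), n, replace = TRUE),
      age_years = pmin(pmax(age, 6), 10),
      bmi_z = bmi_z, wc_z = wc_z, whtr_z = whtr_z,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic beta matrix with planted differential probes
#'
#' Baseline per-probe methylation fractions are drawn from a two-component
#' Beta mixture (hypo- and hypermethylated modes), mimicking the bimodal
#' array beta-value distribution. Exactly `n_planted` probes receive a
#' late-minus-early group-mean shift of `+/- delta_beta`; baselines for
#' planted probes are drawn so the shifted mean stays inside (0.05, 0.95)
#' without clipping under the default effect sizes (any clipping that does
#' occur is recorded in the truth object). Per-sample noise is applied on
#' the logit scale and back-transformed so all values stay in (0, 1).
#'
#' @param config a [sim_config()] object.
#' @param phenotypes output of [generate_phenotypes()] (supplies sample ids
#'   and group labels).
#' @return A list with elements `beta` (probes x samples numeric matrix with
#'   dimnames) and `truth`, a list of class `"synthetic_truth"` holding
#'   `planted_probe_ids`, `planted_direction` (named "+"/"-" vector, sign of
#'   the late-minus-early shift) and `planted_magnitude` (named numeric).
#' @export
generate_beta_matrix <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(phenotypes) == config$n_early + config$n_late,
              "phenotype table does not match config group sizes")
  p <- config$n_probes
  n <- nrow(phenotypes)
  probe_ids <- sprintf("cg%08d", seq_len(p))
  late <- phenotypes$bedtime_group == "late"
  d <- abs(config$delta_beta)
  with_seed(derive_seed(config$seed, "beta"), {
    mode_hi <- stats::runif(p) < 0.5
    mu <- ifelse(mode_hi,
                 stats::rbeta(p, config$beta_shape_b, config$beta_shape_a),
                 stats::rbeta(p, config$beta_shape_a, config$beta_shape_b))
    mu <- pmin(pmax(mu, 0.05), 0.95)
    planted <- if (config$n_planted > 0) sort(sample.int(p, config$n_planted)) else integer(0)
    dir <- integer(0)
    if (length(planted)) {
      dir <- sample(c(-1L, 1L), length(planted), replace = TRUE)
      lo <- ifelse(dir > 0, 0.10, 0.10 + d)
      hi <- ifelse(dir > 0, 0.90 - d, 0.90)
      bad <- lo >= hi  # very large shifts cannot avoid clipping
      lo[bad] <- 0.10; hi[bad] <- 0.90
      mu[planted] <- stats::runif(length(planted), lo, hi)
    }
    m_early <- mu
    m_late <- mu
    m_late[planted] <- pmin(pmax(mu[planted] + dir * d, 0.02), 0.98)
    # sample-level noise on the logit scale, back-transformed
    target <- outer(m_early, as.numeric(!late)) + outer(m_late, as.numeric(late))
    z <- stats::qlogis(target) +
      matrix(stats::rnorm(p * n, 0, config$noise_sd_logit), p, n)
    beta <- stats::plogis(z)
    dimnames(beta) <- list(probe_ids, phenotypes$sample_id)
    truth <- list(
      planted_probe_ids = probe_ids[planted],
      planted_direction = stats::setNames(ifelse(dir > 0, "+", "-"),
                                          probe_ids[planted]),
      planted_magnitude = stats::setNames(abs(m_late[planted] - m_early[planted]),
                                          probe_ids[planted])
    )
    class(truth) <- "synthetic_truth"
    list(beta = beta, truth = truth)
  })
}

#' Generate a raw intensity panel from a beta matrix
#'
#' Inverts the beta-value computation: methylated intensity
#' `M = beta * T + background + noise` and unmethylated
#' `U = (1 - beta) * T + background + noise`, with total signal `T` equal to
#' the configured intensity scale, cell-level background drawn from the
#' negative-control distribution, and additive channel noise. Negative
#' intensities are floored at 0. Bead counts and detection p-values are
#' generated per cell; a `fail_fraction` of cells is given a failing
#' artifact (detection p > 0.01 or bead count <= 2). Per-sample
#' negative-control probes are drawn from the same background distribution.
#'
#' @param beta probes x samples matrix of methylation fractions in \[0, 1\].
#' @param config a [sim_config()] object.
#' @param n_controls number of negative-control probes per sample.
#' @return A list of class `"intensity_panel"` with elements `meth`,
#'   `unmeth`, `beads`, `detection_p` (all probes x samples matrices) and
#'   `neg_controls` (per-sample list of control intensities).
#' @export
generate_intensities <- function(beta, config, n_controls = 100L) {
  stopifnot(inherits(config, "sim_config"), is.matrix(beta))
  assert_that(all(beta >= 0 & beta <= 1), "beta values must lie in [0, 1]")
  p <- nrow(beta); n <- ncol(beta)
  with_seed(derive_seed(config$seed, "intensities"), {
    tt <- config$intensity_scale
    bg_m <- matrix(stats::rnorm(p * n, config$control_mean, config$control_sd), p, n)
    bg_u <- matrix(stats::rnorm(p * n, config$control_mean, config$control_sd), p, n)
    meth <- pmax(beta * tt + bg_m +
                   matrix(stats::rnorm(p * n, 0, config$intensity_sd), p, n), 0)
    unmeth <- pmax((1 - beta) * tt + bg_u +
                     matrix(stats::rnorm(p * n, 0, config$intensity_sd), p, n), 0)
    beads <- matrix(pmax(stats::rpois(p * n, 14), 3L), p, n)
    detp <- matrix(stats::runif(p * n, 0, 0.005), p, n)
    n_fail <- round(config$fail_fraction * p * n)
    if (n_fail > 0) {
      cells <- sample.int(p * n, n_fail)
      kind <- stats::runif(n_fail) < 0.5
      detp[cells[kind]] <- stats::runif(sum(kind), 0.011, 0.2)
      beads[cells[!kind]] <- sample(1:2, sum(!kind), replace = TRUE)
    }
    dimnames(meth) <- dimnames(unmeth) <- dimnames(beads) <-
      dimnames(detp) <- dimnames(beta)
    ctrls <- lapply(seq_len(n), function(j)
      pmax(stats::rnorm(n_controls, config$control_mean, config$control_sd), 0))
    names(ctrls) <- colnames(beta)
    intensity_panel(meth, unmeth, beads, detp, ctrls)
  })
}

#' Construct and validate an intensity panel
#'
#' @param meth,unmeth,beads,detection_p probes x samples matrices sharing
#'   dimnames: nonnegative intensities, positive integer bead counts, and
#'   detection p-values in \[0, 1\].
#' @param neg_controls per-sample list of nonnegative negative-control
#'   intensities.
#' @return A list of class `"intensity_panel"`.
#' @export
intensity_panel <- function(meth, unmeth, beads, detection_p, neg_controls) {
  dims <- dim(meth)
  assert_that(all(dim(unmeth) == dims) && all(dim(beads) == dims) &&
                all(dim(detection_p) == dims),
              "panel matrices must share dimensions")
  assert_that(all(meth >= 0) && all(unmeth >= 0), "intensities must be >= 0")
  assert_that(all(beads >= 1), "bead counts must be >= 1")
  assert_that(all(detection_p >= 0 & detection_p <= 1),
              "detection p-values must lie in [0, 1]")
  structure(list(meth = meth, unmeth = unmeth, beads = beads,
                 detection_p = detection_p, neg_controls = neg_controls),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat(sprintf("Intensity panel: %d probes x %d samples (M/U/beads/detection p + %s negative controls per sample)\n",
              nrow(x$meth), ncol(x$meth),
              if (length(x$neg_controls)) length(x$neg_controls[[1]]) else 0))
  invisible(x)
}

.refgene_vocab <- c("TSS200", "TSS1500", "5'UTR", "Body", "3'UTR",
                    "1stExon", "intragenic", "unmapped")
.island_vocab <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                   "unassigned")
.regulatory_vocab <- c("promoter-associated", "unclassified", "unmapped")

#' Generate a miniature probe manifest
#'
#' Assigns each probe a gene symbol field (possibly empty, "~", or several
#' ";"-joined symbols), a chromosome, a RefGene group, a CpG island relation
#' and a regulatory feature, drawn from the closed category vocabularies used
#' by Infinium-style manifests. Category frequencies loosely follow a
#' promoter-enriched array design.
#'
#' @param probe_ids unique character probe identifiers.
#' @param config a [sim_config()] object (supplies the seed).
#' @return A data.frame in raw manifest form with columns `IlmnID`,
#'   `UCSC_RefGene_Name`, `CHR`, `UCSC_RefGene_Group`,
#'   `Relation_to_UCSC_CpG_Island`, `Regulatory_Feature_Group`.
#' @export
generate_manifest <- function(probe_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(!anyDuplicated(probe_ids), "probe IDs must be unique")
  p <- length(probe_ids)
  with_seed(derive_seed(config$seed, "manifest"), {
    gene_pool <- sprintf("GENE%04d", seq_len(max(50, ceiling(p / 3))))
    n_genes <- sample(0:2, p, replace = TRUE, prob = c(0.25, 0.6, 0.15))
    genes <- vapply(n_genes, function(k) {
      if (k == 0) sample(c("", "~"), 1)
      else paste(sample(gene_pool, k), collapse = ";")
    }, character(1))
    data.frame(
      IlmnID = probe_ids,
      UCSC_RefGene_Name = genes,
      CHR = sample(c(1:22, "X", "Y"), p, replace = TRUE),
      UCSC_RefGene_Group = sample(.refgene_vocab, p, replace = TRUE,
                                  prob = c(0.15, 0.1, 0.12, 0.3, 0.05, 0.08, 0.08, 0.12)),
      Relation_to_UCSC_CpG_Island = sample(c(.island_vocab[1:5], "~"), p,
                                           replace = TRUE,
                                           prob = c(0.35, 0.09, 0.07, 0.02, 0.03, 0.44)),
      Regulatory_Feature_Group = sample(c("promoter-associated", "unclassified", ""),
                                        p, replace = TRUE,
                                        prob = c(0.24, 0.14, 0.62)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic dataset, optionally writing it to disk
#'
#' Runs the full generator (phenotypes, beta matrix + truth, intensity
#' panel, manifest) under a single master seed. When `dir` is given, writes
#' the standard text artifacts: `beta.tsv`, `phenotypes.csv`,
#' `manifest.csv`, `truth.json`, and intensity TSVs (`meth.tsv`,
#' `unmeth.tsv`, `beads.tsv`, `detection_p.tsv`, `neg_controls.tsv`).
#'
#' @param config a [sim_config()] object.
#' @param dir optional output directory (created if missing).
#' @return A list with `config`, `phenotypes`, `beta`, `truth`, `panel`,
#'   `manifest`, invisibly when writing.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  ph <- generate_phenotypes(config)
  bm <- generate_beta_matrix(config, ph)
  panel <- generate_intensities(bm$beta, config)
  manifest <- generate_manifest(rownames(bm$beta), config)
  out <- list(config = config, phenotypes = ph, beta = bm$beta,
              truth = bm$truth, panel = panel, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_beta_tsv(bm$beta, file.path(dir, "beta.tsv"))
    utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(bm$truth), file.path(dir, "truth.json"),
                         auto_unbox = FALSE, digits = NA)
    write_beta_tsv(panel$meth, file.path(dir, "meth.tsv"))
    write_beta_tsv(panel$unmeth, file.path(dir, "unmeth.tsv"))
    write_beta_tsv(panel$beads, file.path(dir, "beads.tsv"))
    write_beta_tsv(panel$detection_p, file.path(dir, "detection_p.tsv"))
    ctrl <- do.call(cbind, panel$neg_controls)
    utils::write.table(ctrl, file.path(dir, "neg_controls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
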