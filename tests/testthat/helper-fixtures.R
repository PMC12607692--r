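# Shared fixtures: tiny intensity panels, two-group datasets, and the
# exhaustive-enumeration oracle used to validate the SWAG search.

# A hand-sized panel where every matrix entry is chosen explicitly.
toy_panel <- function(meth, unmeth, beads = NULL, detp = NULL,
                      controls = NULL) {
  p <- nrow(meth); n <- ncol(meth)
  dimnames(meth) <- dimnames(unmeth) <-
    list(sprintf("p%02d", seq_len(p)), sprintf("s%02d", seq_len(n)))
  if (is.null(beads)) beads <- matrix(10L, p, n)
  if (is.null(detp)) detp <- matrix(0.001, p, n)
  dimnames(beads) <- dimnames(detp) <- dimnames(meth)
  if (is.null(controls))
    controls <- stats::setNames(rep(list(c(0, 0)), n), colnames(meth))
  intensity_panel(meth, unmeth, beads, detp, controls)
}

# Small two-class dataset with mild effects so every logistic fit converges.
make_clean_dataset <- function(n = 40, p = 8, seed = 1, beta_strength = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("v%02d", 1:p)))
  eta <- beta_strength * (x[, 1] - x[, 2])
  y <- rbinom(n, 1, plogis(eta))
  while (length(unique(y)) < 2) y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}

# Independent oracle: enumerate every subset of size <= dmax, fit each with
# the same elementary fit, keep rankable ones. Mirrors no part of the SWAG
# search loop.
exhaustive_library <- function(y, x, dmax, keep_separated = TRUE) {
  vars <- colnames(x)
  out <- list()
  for (d in seq_len(dmax)) {
    sets <- utils::combn(vars, d, simplify = FALSE)
    for (s in sets) {
      r <- fit_logistic_aic(y, x[, s, drop = FALSE])
      if (r$converged || (keep_separated && r$separated)) out <- c(out, list(r))
    }
  }
  out
}

model_keys <- function(records)
  sort(vapply(records, function(r) paste(sort(r$variables), collapse = "|"),
              character(1)))
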