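# Sparse wrapper model selection (SWAG) over CpG predictors: AIC-scored
# logistic model libraries, post-processing and frequency-based importance.

#' Fit a logistic model and score it by AIC
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (convergence when the deviance change falls below 1e-8, at most
#' 50 iterations). Predictors are standardised internally before fitting —
#' with an intercept this leaves the likelihood and AIC unchanged and makes
#' the separation check scale-free. A fit is flagged as separated when any
#' standardised coefficient exceeds 15 in absolute value or when all fitted
#' probabilities are within 1e-8 of 0 or 1 (perfect separation);
#' `converged` is TRUE only for fully converged, non-separated ML fits.
#'
#' Under separation the ML likelihood is unbounded and its AIC degenerates
#' to the constant `2k`, which would make every model containing a
#' separating variable indistinguishable. Such fits (and IRLS failures) are
#' therefore refit with Firth's bias-reduced logistic regression, whose
#' penalised estimates are always finite; the reported `loglik` is the
#' ordinary log-likelihood evaluated at those finite estimates, so the AIC
#' stays on the `2k - 2 loglik` scale and grades separated models by how
#' decisively they separate.
#'
#' @param y binary response (0/1 numeric, logical, or two-level factor);
#'   both classes must be present.
#' @param X numeric matrix of predictor columns (may be `NULL` for the
#'   intercept-only model); columns must be named.
#' @param forced optional matrix of covariates included in the fit but not
#'   recorded among the model's selected variables (used by
#'   `covariate_mode = "forced"`).
#' @return A model record: list with `variables` (character), `k`
#'   (parameters incl. intercept and forced covariates), `loglik`, `aic`
#'   (= 2k - 2 loglik), `separated` (perfect-separation flag) and
#'   `converged` (IRLS converged and not separated). A separated fit sits at
#'   the boundary of the likelihood: its log-likelihood approaches 0 and its
#'   AIC approaches `2k`.
#' @examples
#' fit_logistic_aic(c(0, 0, 1, 1), NULL)$aic  # 4 - 8 * log(0.5)
#' @export
fit_logistic_aic <- function(y, X = NULL, forced = NULL) {
  y <- as_binary(y)
  assert_that(length(unique(y)) == 2, "response must contain both classes")
  n <- length(y)
  vars <- character(0)
  Xm <- NULL
  if (!is.null(X)) {
    Xm <- as.matrix(X)
    assert_that(!is.null(colnames(Xm)), "predictor columns must be named")
    assert_that(nrow(Xm) == n, "predictor rows must match response length")
    vars <- colnames(Xm)
  }
  design <- cbind(Xm, forced)
  if (!is.null(design) && ncol(design)) {
    sds <- apply(design, 2, stats::sd)
    ok <- is.finite(sds) & sds > 0
    design[, ok] <- scale(design[, ok, drop = FALSE])
  }
  mm <- cbind(`(Intercept)` = rep(1, n), design)
  fit <- suppressWarnings(stats::glm.fit(
    mm, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  mu <- fit$fitted.values
  k <- fit$rank
  co <- fit$coefficients[-1]
  separated <- (length(co) && any(abs(co) > 15, na.rm = TRUE)) ||
    all(pmin(mu, 1 - mu) < 1e-8)
  converged <- isTRUE(fit$converged) && !separated
  if (!converged) {
    ff <- firth_fit(mm, y)
    if (!is.null(ff)) mu <- ff$fitted
  }
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  list(variables = vars, k = as.integer(k), loglik = ll,
       aic = 2 * k - 2 * ll,
       separated = separated,
       converged = converged)
}

# Firth's bias-reduced logistic regression: Newton iterations on the
# Jeffreys-penalised likelihood, with step halving. Estimates are finite
# even under complete separation. Returns NULL if the information matrix
# is numerically singular.
firth_fit <- function(mm, y, maxit = 100, tol = 1e-8) {
  p <- ncol(mm)
  beta <- rep(0, p)
  pll <- function(b) {
    mu <- stats::plogis(drop(mm %*% b))
    info <- crossprod(mm * (mu * (1 - mu)), mm)
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(ll = sum(stats::dbinom(y, 1, mu, log = TRUE)) +
           sum(log(diag(ch))),
         mu = mu, ch = ch)
  }
  cur <- pll(beta)
  if (is.null(cur)) return(NULL)
  for (it in seq_len(maxit)) {
    mu <- cur$mu
    inv <- chol2inv(cur$ch)
    xw <- mm * sqrt(mu * (1 - mu))
    h <- rowSums((xw %*% inv) * xw)  # hat-matrix diagonal
    score <- crossprod(mm, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% score)
    new_beta <- beta + step
    nxt <- pll(new_beta)
    halvings <- 0
    while ((is.null(nxt) || nxt$ll < cur$ll) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- pll(new_beta)
      halvings <- halvings + 1
    }
    if (is.null(nxt)) return(NULL)
    done <- max(abs(score)) < tol || max(abs(step)) < tol
    beta <- new_beta
    cur <- nxt
    if (done) break
  }
  list(coefficients = stats::setNames(beta, colnames(mm)),
       fitted = cur$mu, penalized_loglik = cur$ll)
}

# Which records enter the AIC ranking. Separated fits are perfect in-sample
# classifiers: a wrapper search must retain them (at their finite
# Firth-based AIC) or it discards exactly the strongest predictors.
# `keep_separated = FALSE` restores the strict converged-only rule.
rankable <- function(records, keep_separated = TRUE) {
  Filter(function(r) {
    is.finite(r$aic) &&
      (r$converged || (keep_separated && isTRUE(r$separated)))
  }, records)
}

# Coerce a response to 0/1; for factors/characters the second sorted level
# is the positive class (e.g. early/late -> late = 1).
as_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lv <- sort(unique(y))
    assert_that(length(lv) <= 2, "response has more than two levels")
    y <- as.integer(y == lv[length(lv)])
  }
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "response must be binary (0/1)")
  y
}

# Order model records by (AIC, lexicographic variable key) and keep the
# ceiling(alpha * K) best. Records must already be converged-only.
retain_best <- function(records, alpha) {
  if (!length(records)) return(records)
  aics <- vapply(records, `[[`, 0, "aic")
  keys <- vapply(records, function(r) paste(r$variables, collapse = "|"),
                 character(1))
  ord <- order(aics, keys, method = "radix")
  n_keep <- ceiling(alpha * length(records))
  records[ord[seq_len(n_keep)]]
}

#' Screen single-variable models (SWAG dimension 1)
#'
#' Fits all one-variable logistic models, drops failed fits, and retains
#' the `ceiling(alpha * K)` lowest-AIC models among the `K` rankable ones
#' (ties broken by lexicographic variable ID). The union of retained
#' variables is the screened set from which all higher-dimensional models
#' are built. By default, perfectly separating fits stay in the ranking at
#' their finite Firth-based AIC (they are the strongest classifiers in the
#' pool); set `keep_separated = FALSE` to restrict the ranking to fully
#' converged ML fits.
#'
#' @param y binary response.
#' @param X predictor matrix (samples x variables, named columns).
#' @param alpha screening proportion in (0, 1\].
#' @param forced optional forced-covariate matrix (see [swag()]).
#' @param keep_separated whether separated fits enter the AIC ranking.
#' @return List with `retained` (model records) and `screened` (sorted
#'   character vector of surviving variable names).
#' @export
screen_dimension_one <- function(y, X, alpha = 0.05, forced = NULL,
                                 keep_separated = TRUE) {
  assert_that(ncol(X) >= 1, "at least one predictor is required")
  fits <- lapply(colnames(X), function(v)
    fit_logistic_aic(y, X[, v, drop = FALSE], forced = forced))
  fits <- rankable(fits, keep_separated)
  assert_that(length(fits) > 0, "no single-variable model could be ranked")
  retained <- retain_best(fits, alpha)
  screened <- sort(unique(unlist(lapply(retained, `[[`, "variables"))))
  list(retained = retained, screened = screened)
}

#' Extend a SWAG library to the next dimension
#'
#' Candidates at dimension `d` are every retained (d-1)-variable model
#' augmented with every screened variable it does not already contain,
#' deduplicated as variable sets. When more than `m_per_dim` candidates
#' exist, `m_per_dim` are sampled uniformly without replacement from the
#' seeded stream. All candidates are fitted, unrankable fits dropped (see
#' [screen_dimension_one()] for the separated-fit rule), and the
#' `ceiling(alpha * K)` best by AIC retained (lexicographic tie-break on
#' the sorted variable key).
#'
#' @param prev_retained retained model records at dimension d-1.
#' @param screened screened variable names from dimension 1.
#' @param y,X response and predictor matrix.
#' @param d target dimension (>= 2).
#' @param alpha screening proportion.
#' @param m_per_dim candidate cap (may be `Inf`).
#' @param seed integer seed for candidate subsampling.
#' @param forced optional forced-covariate matrix.
#' @param keep_separated whether separated fits enter the AIC ranking.
#' @return List of retained model records at dimension `d` (possibly empty).
#' @export
extend_dimension <- function(prev_retained, screened, y, X, d,
                             alpha = 0.05, m_per_dim = Inf, seed = 1L,
                             forced = NULL, keep_separated = TRUE) {
  assert_that(d >= 2, "extension starts at dimension 2")
  if (!length(prev_retained)) return(list())
  cand <- new.env(parent = emptyenv())
  for (r in prev_retained) {
    for (v in setdiff(screened, r$variables)) {
      key <- paste(sort(c(r$variables, v)), collapse = "|")
      assign(key, TRUE, envir = cand)
    }
  }
  keys <- sort(ls(cand))
  if (!length(keys)) return(list())
  if (is.finite(m_per_dim) && length(keys) > m_per_dim) {
    keys <- with_seed(derive_seed(seed, paste0("swag-dim", d)),
                      sort(sample(keys, m_per_dim)))
  }
  fits <- lapply(keys, function(k) {
    vars <- strsplit(k, "|", fixed = TRUE)[[1]]
    fit_logistic_aic(y, X[, vars, drop = FALSE], forced = forced)
  })
  fits <- rankable(fits, keep_separated)
  retain_best(fits, alpha)
}

#' SWAG: sparse wrapper model selection with AIC-scored logistic models
#'
#' Builds a library of low-dimensional logistic classification models by
#' screening all single-variable models, then greedily extending the
#' retained models one variable at a time up to `dmax`, keeping the lowest
#' `alpha` proportion (by AIC) of converged candidates at every dimension.
#' The result is a *collection* of sparse models rather than a single fit;
#' how often each variable appears across the library measures its
#' importance for separating the two classes.
#'
#' Phenotype covariates can enter the candidate pool alongside the probes
#' (`covariate_mode = "pooled"`, the default), be forced into every fitted
#' model without counting towards its dimension (`"forced"`), or be ignored
#' (`"excluded"`).
#'
#' @param x numeric predictor matrix, samples in rows, named variables
#'   (e.g. CpG probes) in columns.
#' @param y binary response: 0/1, logical, or a two-level factor whose
#'   second sorted level is treated as the positive class.
#' @param alpha proportion of converged models retained per dimension.
#' @param dmax maximum model dimension.
#' @param m_per_dim cap on candidate models fitted per dimension (`Inf` for
#'   exhaustive extension).
#' @param delta_aic post-processing window: models within `delta_aic` of the
#'   library's minimum AIC form the `selected` set (see [select_models()]).
#' @param covariates optional data.frame/matrix of phenotype covariates
#'   aligned with the rows of `x`.
#' @param covariate_mode how covariates participate: `"pooled"`, `"forced"`
#'   or `"excluded"`.
#' @param keep_separated whether perfectly separating fits stay in the AIC
#'   ranking at their finite Firth-based AIC (default) or are dropped. At
#'   small sample sizes the strongest predictors routinely separate the
#'   groups; dropping them biases the library against exactly the variables
#'   the search is meant to find.
#' @param seed integer seed controlling candidate subsampling (the
#'   procedure is otherwise deterministic).
#' @return An object of class `"swag"`: a list with `library` (per-dimension
#'   lists of model records), `screened`, `selected` (delta-AIC window),
#'   `pruned` (sub-model-improvement post-processing, see
#'   [prune_by_submodels()]), `importance` (Akaike-weighted importance over
#'   the pruned set, see [variable_importance()]), `best` (minimum-AIC model
#'   refit on the original scale), `params`, and the response/labels needed
#'   by methods.
#' @seealso [select_models()], [variable_importance()], [predict.swag()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("v", 1:6)))
#' y <- rbinom(40, 1, plogis(1.5 * x[, 1] - x[, 2]))
#' fit <- swag(x, y, alpha = 1, dmax = 2)
#' fit
#' head(variable_importance(fit))
#' @export
swag <- function(x, y, alpha = 0.05, dmax = 3, m_per_dim = Inf,
                 delta_aic = 2, covariates = NULL,
                 covariate_mode = c("pooled", "forced", "excluded"),
                 keep_separated = TRUE, seed = 1L) {
  covariate_mode <- match.arg(covariate_mode)
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  assert_that(dmax >= 1, "dmax must be at least 1")
  assert_that(delta_aic >= 0, "delta_aic must be nonnegative")
  x <- as.matrix(x)
  assert_that(!is.null(colnames(x)), "predictor columns must be named")
  yb <- as_binary(y)
  assert_that(length(yb) >= 4, "at least 4 samples are required")
  assert_that(nrow(x) == length(yb), "x rows must match response length")

  forced <- NULL
  if (!is.null(covariates) && covariate_mode != "excluded") {
    cm <- covariate_matrix(covariates)
    assert_that(nrow(cm) == length(yb),
                "covariate rows must match response length")
    if (covariate_mode == "pooled") x <- cbind(x, cm) else forced <- cm
  }

  scr <- screen_dimension_one(yb, x, alpha = alpha, forced = forced,
                              keep_separated = keep_separated)
  library <- list(`1` = scr$retained)
  d <- 2
  while (d <= dmax) {
    ret <- extend_dimension(library[[as.character(d - 1)]], scr$screened,
                            yb, x, d, alpha = alpha, m_per_dim = m_per_dim,
                            seed = seed, forced = forced,
                            keep_separated = keep_separated)
    if (!length(ret)) break
    library[[as.character(d)]] <- ret
    d <- d + 1
  }
  flat <- unlist(library, recursive = FALSE, use.names = FALSE)
  selected <- select_models(flat, delta_aic)
  pruned <- prune_by_submodels(flat, yb, x, forced = forced)
  # on null data no model may beat the intercept-only fit; score the
  # delta-window selection instead so importance is always defined
  importance <- variable_importance(if (length(pruned)) pruned else selected,
                                    weight = "akaike")

  aics <- vapply(flat, `[[`, 0, "aic")
  best_rec <- flat[[which.min(aics)]]
  best_fit <- refit_model(x, yb, best_rec$variables, forced)

  structure(list(
    library = library,
    screened = scr$screened,
    selected = selected,
    pruned = pruned,
    importance = importance,
    best = list(variables = best_rec$variables, aic = best_rec$aic,
                loglik = best_rec$loglik, k = best_rec$k,
                coefficients = best_fit$coefficients,
                fitted = best_fit$fitted),
    params = list(alpha = alpha, dmax = dmax, m_per_dim = m_per_dim,
                  delta_aic = delta_aic, covariate_mode = covariate_mode,
                  keep_separated = keep_separated,
                  seed = as.integer(seed)),
    y = yb, y_levels = if (is.factor(y)) levels(y) else
      sort(unique(as.character(y))),
    n = length(yb),
    call = match.call()
  ), class = "swag")
}

# Refit a chosen model on the original predictor scale (for coef/predict),
# falling back to Firth estimates when ML degenerates.
refit_model <- function(x, yb, vars, forced = NULL) {
  mm <- cbind(`(Intercept)` = rep(1, length(yb)),
              x[, vars, drop = FALSE], forced)
  fit <- suppressWarnings(stats::glm.fit(
    mm, yb, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  mu <- fit$fitted.values
  if (!isTRUE(fit$converged) || all(pmin(mu, 1 - mu) < 1e-8)) {
    ff <- firth_fit(mm, yb)
    if (!is.null(ff))
      return(list(coefficients = ff$coefficients, fitted = ff$fitted))
  }
  list(coefficients = fit$coefficients, fitted = mu)
}

covariate_matrix <- function(covariates) {
  if (is.data.frame(covariates)) {
    num <- lapply(covariates, function(col) {
      if (is.numeric(col)) col else as.numeric(factor(col)) - 1
    })
    cm <- do.call(cbind, num)
    colnames(cm) <- names(covariates)
    cm
  } else as.matrix(covariates)
}

#' Post-process a SWAG library into the selected model set
#'
#' Keeps every retained model whose AIC lies within `delta_aic` of the
#' library-wide minimum. `delta_aic = Inf` returns the whole library;
#' `delta_aic = 0` keeps only the minimum-AIC model(s), including exact
#' ties.
#'
#' @param library a `"swag"` object or a flat list of model records.
#' @param delta_aic nonnegative AIC window (may be `Inf`).
#' @return A flat list of selected model records.
#' @export
select_models <- function(library, delta_aic = 2) {
  records <- flatten_library(library)
  assert_that(length(records) > 0, "model library is empty")
  assert_that(delta_aic >= 0, "delta_aic must be nonnegative")
  if (!is.finite(delta_aic)) return(records)
  aics <- vapply(records, `[[`, 0, "aic")
  records[aics <= min(aics) + delta_aic]
}

flatten_library <- function(library) {
  if (inherits(library, "swag"))
    return(unlist(library$library, recursive = FALSE, use.names = FALSE))
  if (length(library) && is.list(library[[1]]) &&
      !is.null(library[[1]]$aic)) return(library)
  unlist(library, recursive = FALSE, use.names = FALSE)
}

#' Variable importance over a model library
#'
#' For each variable, reports the number of models in the collection that
#' contain it (`count`), that count as a percentage of the number of models
#' (`frequency_pct`), and the variable's share of Akaike weight
#' (`akaike_weight`): the summed model weights `w_m = exp(-(AIC_m -
#' min AIC)/2)` over models containing the variable, normalised by the total
#' weight of the collection. Ranking is by descending Akaike weight by
#' default (with lexicographic tie-breaks, so the ranking is total and
#' deterministic); `weight = "none"` ranks by raw frequency instead.
#'
#' Weighted and frequency rankings coincide whenever all models score
#' equally; they differ exactly when the collection mixes strong and weak
#' models, where raw frequency credits a variable for every model it sits
#' in regardless of that model's quality — including models where it is an
#' uninformative passenger next to one strong variable.
#'
#' @param models a `"swag"` object (its full library is used) or a flat
#'   list of model records, e.g. from [select_models()] or
#'   [prune_by_submodels()].
#' @param weight `"akaike"` (default) or `"none"` — the ranking basis.
#' @return A data.frame with columns `variable`, `count`, `frequency_pct`,
#'   `akaike_weight`, `rank`, ordered by rank.
#' @export
variable_importance <- function(models, weight = c("akaike", "none")) {
  weight <- match.arg(weight)
  records <- flatten_library(models)
  assert_that(length(records) > 0, "model collection is empty")
  aics <- vapply(records, `[[`, 0, "aic")
  w <- exp(-(aics - min(aics)) / 2)
  vars_per_model <- lapply(records, `[[`, "variables")
  all_vars <- unlist(vars_per_model)
  tab <- table(all_vars)
  wsum <- vapply(names(tab), function(v)
    sum(w[vapply(vars_per_model, function(vs) v %in% vs, logical(1))]),
    numeric(1))
  df <- data.frame(variable = names(tab),
                   count = as.integer(tab),
                   frequency_pct = 100 * as.integer(tab) / length(records),
                   akaike_weight = unname(wsum / sum(w)),
                   stringsAsFactors = FALSE)
  key <- if (weight == "akaike") df$akaike_weight else df$frequency_pct
  ord <- order(-key, df$variable, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Prune a model library to models that improve on all their sub-models
#'
#' Post-processes a library so that every variable in every retained model
#' earns its place: a model is kept only if its AIC is strictly below the
#' AIC of each of its drop-one sub-models and of the intercept-only model.
#' Sub-models absent from the library are fitted on demand (and cached), so
#' the rule is exact. This removes "passenger" models — a strong classifier
#' plus a variable that adds nothing — which a greedy wrapper otherwise
#' retains in large numbers because their scores are indistinguishable from
#' the strong model alone.
#'
#' @param library a `"swag"` object or flat list of model records.
#' @param y,x the response and predictor matrix the library was fit on.
#' @param forced optional forced-covariate matrix used in the original fits.
#' @return A flat list of admissible model records.
#' @export
prune_by_submodels <- function(library, y, x, forced = NULL) {
  records <- flatten_library(library)
  assert_that(length(records) > 0, "model library is empty")
  y <- as_binary(y)
  cache <- new.env(parent = emptyenv())
  for (r in records)
    assign(paste(sort(r$variables), collapse = "|"), r$aic, envir = cache)
  null_aic <- fit_logistic_aic(y, NULL, forced = forced)$aic
  get_aic <- function(vars) {
    if (!length(vars)) return(null_aic)
    key <- paste(sort(vars), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    a <- fit_logistic_aic(y, x[, vars, drop = FALSE], forced = forced)$aic
    assign(key, a, envir = cache)
    a
  }
  keep <- vapply(records, function(r) {
    v <- r$variables
    subs <- if (length(v) <= 1) list(character(0)) else
      lapply(seq_along(v), function(i) v[-i])
    r$aic < min(vapply(subs, get_aic, numeric(1)))
  }, logical(1))
  records[keep]
}

#' @export
print.swag <- function(x, ...) {
  sizes <- vapply(x$library, length, integer(1))
  cat("SWAG model library (logistic regression, AIC-scored)\n")
  cat(sprintf("  samples: %d   screened variables: %d   alpha: %g   dmax: %d\n",
              x$n, length(x$screened), x$params$alpha, x$params$dmax))
  cat(sprintf("  retained models by dimension: %s (total %d)\n",
              paste(sprintf("d%s=%d", names(sizes), sizes), collapse = ", "),
              sum(sizes)))
  cat(sprintf("  selected within delta AIC %g of minimum: %d models\n",
              x$params$delta_aic, length(x$selected)))
  cat(sprintf("  post-processed (sub-model-improving) models: %d\n",
              length(x$pruned)))
  cat(sprintf("  best model: {%s}, AIC = %.3f\n",
              paste(x$best$variables, collapse = ", "), x$best$aic))
  invisible(x)
}

#' @export
summary.swag <- function(object, top = 10, ...) {
  structure(list(fit = object,
                 top = utils::head(object$importance, top)),
            class = "summary.swag")
}

#' @export
print.summary.swag <- function(x, ...) {
  print(x$fit)
  cat("\nTop variables by selection frequency across the selected models:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.swag <- function(object, ...) object$best$coefficients

#' Predict from the best model of a SWAG library
#'
#' Uses the minimum-AIC model of the library, refit on the original
#' predictor scale.
#'
#' @param object a `"swag"` object.
#' @param newx matrix/data.frame containing at least the best model's
#'   variables as columns; omitted to return in-sample predictions.
#' @param type `"response"` (probability of the positive class), `"link"`,
#'   or `"class"`.
#' @param ... unused.
#' @export
predict.swag <- function(object, newx = NULL,
                         type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newx)) {
    p <- object$best$fitted
  } else {
    vars <- object$best$variables
    newx <- as.matrix(as.data.frame(newx)[, vars, drop = FALSE])
    co <- object$best$coefficients
    if (length(co) != length(vars) + 1)
      stop("prediction with forced covariates requires newx to carry them; refit with covariate_mode = 'pooled'")
    eta <- drop(cbind(1, newx) %*% co)
    p <- stats::plogis(eta)
  }
  switch(type,
         response = p,
         link = stats::qlogis(p),
         class = {
           lv <- object$y_levels
           if (length(lv) == 2) lv[(p > 0.5) + 1] else as.integer(p > 0.5)
         })
}

#' @export
residuals.swag <- function(object, ...) object$y - object$best$fitted

#' Plot variable importance of a SWAG library
#'
#' Horizontal bar plot of the top `k` variables by selection frequency.
#'
#' @param x a `"swag"` object.
#' @param k number of variables shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.swag <- function(x, k = 10, ...) {
  imp <- utils::head(x$importance, k)
  graphics::barplot(rev(imp$frequency_pct), names.arg = rev(imp$variable),
                    horiz = TRUE, las = 1,
                    xlab = "selection frequency (% of selected models)",
                    main = "SWAG variable importance", ...)
  invisible(x)
}
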