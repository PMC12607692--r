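# SWAG core: elementary logistic fits, screening, extension, selection,
# importance, and equivalence with exhaustive enumeration.

test_that("logistic AIC matches closed-form null log-likelihoods", {
  r4 <- fit_logistic_aic(c(0, 0, 1, 1), NULL)
  expect_equal(r4$loglik, 4 * log(0.5), tolerance = 1e-8)
  expect_equal(r4$aic, 2 - 8 * log(0.5), tolerance = 1e-8)  # 7.54518
  expect_equal(r4$k, 1L)
  expect_true(r4$converged)

  r2 <- fit_logistic_aic(c(0, 1), NULL)
  expect_equal(r2$aic, 2 - 4 * log(0.5), tolerance = 1e-8)  # 4.77259
})

test_that("AIC identity 2k - 2*loglik holds against an independent likelihood", {
  ds <- make_clean_dataset(n = 50, p = 5, seed = 11)
  for (vars in list("v01", c("v02", "v03"), c("v01", "v04", "v05"))) {
    r <- fit_logistic_aic(ds$y, ds$x[, vars, drop = FALSE])
    expect_true(r$converged)
    expect_equal(r$aic, 2 * r$k - 2 * r$loglik, tolerance = 1e-10)
    # independent route: glm() on the same data
    df <- data.frame(y = ds$y, ds$x[, vars, drop = FALSE])
    g <- glm(y ~ ., data = df, family = binomial())
    expect_equal(r$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
    expect_equal(r$k, attr(logLik(g), "df"))
  }
})

test_that("perfect separation is flagged and refit with finite Firth estimates", {
  r <- fit_logistic_aic(c(0, 0, 1, 1),
                        matrix(c(0, 0, 1, 1), 4, dimnames = list(NULL, "x")))
  expect_false(r$converged)
  expect_true(r$separated)
  expect_true(is.finite(r$aic))
  expect_lt(r$loglik, 0)  # finite ordinary likelihood at Firth estimates
  expect_error(fit_logistic_aic(c(1, 1, 1, 1), NULL), "both classes")
})

test_that("Firth refit grades separated models by separation strength", {
  # a wide-margin separator should outrank a knife-edge separator
  set.seed(4)
  y <- rep(c(0, 1), each = 8)
  wide <- matrix(c(rnorm(8, -3, 0.2), rnorm(8, 3, 0.2)), 16,
                 dimnames = list(NULL, "w"))
  narrow <- matrix(c(seq(-0.8, -0.1, length.out = 8),
                     seq(0.1, 0.8, length.out = 8)), 16,
                   dimnames = list(NULL, "n"))
  rw <- fit_logistic_aic(y, wide)
  rn <- fit_logistic_aic(y, narrow)
  expect_true(rw$separated && rn$separated)
  expect_lt(rw$aic, rn$aic)
})

test_that("dimension-one screening retains ceiling(alpha*K) with lexicographic ties", {
  # engineered predictors with strictly ordered single-variable AICs:
  # identical columns tie exactly and must resolve lexicographically
  set.seed(7)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = y + rnorm(n, sd = 0.8),
             b = y + rnorm(n, sd = 1.8),
             c = 0, d = rnorm(n))
  x[, "c"] <- x[, "b"]  # exact tie between b and c
  scr_all <- screen_dimension_one(y, x, alpha = 1)
  expect_length(scr_all$retained, 4)
  scr_half <- screen_dimension_one(y, x, alpha = 0.5)
  expect_length(scr_half$retained, 2)
  kept <- vapply(scr_half$retained, function(r) r$variables, character(1))
  expect_equal(sort(kept), c("a", "b"))  # b beats identical c on name
  expect_equal(scr_half$screened, c("a", "b"))
})

test_that("screening is monotone in alpha", {
  ds <- make_clean_dataset(n = 50, p = 10, seed = 21)
  keys <- lapply(c(0.2, 0.5, 1), function(a)
    model_keys(screen_dimension_one(ds$y, ds$x, alpha = a)$retained))
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("dimension extension enumerates, deduplicates and samples deterministically", {
  ds <- make_clean_dataset(n = 40, p = 4, seed = 3)
  prev <- list(list(variables = "v01", aic = 10, converged = TRUE),
               list(variables = "v02", aic = 11, converged = TRUE))
  ret <- extend_dimension(prev, c("v01", "v02", "v03"), ds$y, ds$x, d = 2,
                          alpha = 1)
  expect_equal(model_keys(ret), c("v01|v02", "v01|v03", "v02|v03"))
  # candidate cap: same seed, same subsample
  r1 <- extend_dimension(prev, c("v01", "v02", "v03"), ds$y, ds$x, d = 2,
                         alpha = 1, m_per_dim = 2, seed = 42)
  r2 <- extend_dimension(prev, c("v01", "v02", "v03"), ds$y, ds$x, d = 2,
                         alpha = 1, m_per_dim = 2, seed = 42)
  expect_identical(model_keys(r1), model_keys(r2))
  expect_length(r1, 2)
})

test_that("exhaustive alpha=1 search reproduces all-subsets enumeration", {
  ds <- make_clean_dataset(n = 60, p = 5, seed = 13)
  fit <- swag(ds$x, ds$y, alpha = 1, dmax = 2, delta_aic = Inf)
  # 5 singletons + 10 pairs when everything converges
  expect_length(fit$library[["1"]], 5)
  expect_length(fit$library[["2"]], 10)
  oracle <- exhaustive_library(ds$y, ds$x, dmax = 2)
  flat <- unlist(fit$library, recursive = FALSE, use.names = FALSE)
  expect_identical(model_keys(flat), model_keys(oracle))
  # and the best model agrees with brute force exactly
  best_oracle <- oracle[[which.min(vapply(oracle, `[[`, 0, "aic"))]]
  expect_identical(sort(fit$best$variables), sort(best_oracle$variables))
  expect_equal(fit$best$aic, best_oracle$aic, tolerance = 1e-10)
})

test_that("the search is deterministic and seed-independent when exhaustive", {
  ds <- make_clean_dataset(n = 40, p = 6, seed = 17)
  f1 <- swag(ds$x, ds$y, alpha = 0.5, dmax = 3, seed = 1)
  f2 <- swag(ds$x, ds$y, alpha = 0.5, dmax = 3, seed = 99)
  # no candidate subsampling is exercised, so the seed cannot matter
  expect_identical(f1$library, f2$library)
  expect_identical(f1$importance, f2$importance)
  # byte-identical serialization under the same inputs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_swag_library(unlist(f1$library, FALSE, FALSE), p1)
  write_swag_library(unlist(f2$library, FALSE, FALSE), p2)
  expect_identical(readLines(p1), readLines(p2))
  rt <- read_swag_library(p1)
  expect_identical(model_keys(rt),
                   model_keys(unlist(f1$library, FALSE, FALSE)))
})

test_that("model selection windows the library by AIC", {
  lib <- list(list(variables = "a", aic = 10, converged = TRUE),
              list(variables = "b", aic = 11, converged = TRUE),
              list(variables = "c", aic = 12.5, converged = TRUE),
              list(variables = "d", aic = 10, converged = TRUE))
  expect_length(select_models(lib, 2), 3)
  expect_length(select_models(lib, 0), 2)    # exact ties at the minimum
  expect_length(select_models(lib, Inf), 4)
})

test_that("variable importance counts selection frequencies with total ranking", {
  mods <- lapply(list(c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C")),
                 function(v) list(variables = v, aic = 0, converged = TRUE))
  imp <- variable_importance(mods)
  expect_equal(imp$variable, c("A", "B", "C", "D"))
  expect_equal(imp$frequency_pct, c(75, 50, 50, 25))
  expect_equal(imp$rank, 1:4)
  expect_equal(sum(imp$count), sum(lengths(lapply(mods, `[[`, "variables"))))

  single <- variable_importance(list(list(variables = "A", aic = 1,
                                          converged = TRUE)))
  expect_equal(single$frequency_pct, 100)

  # independent tallying oracle on random libraries
  set.seed(31)
  for (i in 1:25) {
    vars <- sprintf("x%02d", 1:8)
    mods <- lapply(1:20, function(j)
      list(variables = sample(vars, sample(1:3, 1)), aic = 0,
           converged = TRUE))
    imp <- variable_importance(mods)
    manual <- sapply(imp$variable, function(v)
      sum(vapply(mods, function(m) v %in% m$variables, logical(1))))
    expect_equal(imp$count, unname(manual))
    expect_equal(imp$frequency_pct, unname(100 * manual / 20))
  }
})

test_that("sub-model pruning drops passengers and keeps jointly informative models", {
  set.seed(61)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(s1 = y + rnorm(n, sd = 0.4),      # dominant signal
             s2 = y + rnorm(n, sd = 0.9),      # complementary signal
             nz = rnorm(n))                    # pure noise
  recs <- list(fit_logistic_aic(y, x[, "s1", drop = FALSE]),
               fit_logistic_aic(y, x[, "s2", drop = FALSE]),
               fit_logistic_aic(y, x[, "nz", drop = FALSE]),
               fit_logistic_aic(y, x[, c("s1", "nz")]),
               fit_logistic_aic(y, x[, c("s1", "s2")]))
  pruned <- prune_by_submodels(recs, y, x)
  keys <- model_keys(pruned)
  expect_true("s1" %in% keys)             # informative singleton survives
  expect_false("nz" %in% keys)            # noise does not beat the null model
  expect_false("nz|s1" %in% keys)         # passenger model pruned
  # joint model survives iff it genuinely improves on both margins
  aic_s1 <- recs[[1]]$aic
  aic_s1s2 <- recs[[5]]$aic
  expect_equal("s1|s2" %in% keys, aic_s1s2 < min(aic_s1, recs[[2]]$aic))
})

test_that("Akaike-weighted importance demotes passengers of dominant models", {
  # one excellent model {A}; B appears twice but only in poor models
  mods <- list(list(variables = "A", aic = 10, converged = TRUE),
               list(variables = c("A", "B"), aic = 30, converged = TRUE),
               list(variables = c("B", "C"), aic = 30, converged = TRUE))
  imp <- variable_importance(mods, weight = "akaike")
  expect_equal(imp$variable[1], "A")
  expect_gt(imp$akaike_weight[imp$variable == "A"],
            imp$akaike_weight[imp$variable == "B"])
  # frequency ranking would have tied A and B at 2/3 each
  freq <- variable_importance(mods, weight = "none")
  expect_equal(freq$frequency_pct[freq$variable %in% c("A", "B")], c(200/3, 200/3))
  # with equal AICs the two rankings coincide
  eq <- lapply(list("A", c("A", "B"), c("B", "C")), function(v)
    list(variables = v, aic = 5, converged = TRUE))
  expect_identical(variable_importance(eq, "akaike")$variable,
                   variable_importance(eq, "none")$variable)
})

test_that("covariates can be pooled, forced, or excluded", {
  ds <- make_clean_dataset(n = 50, p = 4, seed = 23)
  covs <- data.frame(age = rnorm(50), sex = sample(c("M", "F"), 50, TRUE))
  pooled <- swag(ds$x, ds$y, alpha = 1, dmax = 1, covariates = covs,
                 covariate_mode = "pooled")
  expect_length(pooled$library[["1"]], 6)  # 4 probes + 2 covariates
  forced <- swag(ds$x, ds$y, alpha = 1, dmax = 1, covariates = covs,
                 covariate_mode = "forced")
  expect_length(forced$library[["1"]], 4)
  # forced covariates raise every model's parameter count by 2
  expect_true(all(vapply(forced$library[["1"]], `[[`, 0L, "k") == 4L))
  excluded <- swag(ds$x, ds$y, alpha = 1, dmax = 1, covariates = covs,
                   covariate_mode = "excluded")
  expect_length(excluded$library[["1"]], 4)
  expect_true(all(vapply(excluded$library[["1"]], `[[`, 0L, "k") == 2L))
})

test_that("swag object methods expose the best model coherently", {
  ds <- make_clean_dataset(n = 60, p = 5, seed = 29, beta_strength = 1.5)
  fit <- swag(ds$x, ds$y, alpha = 1, dmax = 2)
  expect_s3_class(fit, "swag")
  expect_output(print(fit), "SWAG model library")
  expect_output(print(summary(fit)), "selection frequency")
  co <- coef(fit)
  expect_equal(length(co), length(fit$best$variables) + 1)
  pr <- predict(fit)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(unname(predict(fit, newx = ds$x)), unname(pr),
               tolerance = 1e-8)
  cls <- predict(fit, newx = ds$x, type = "class")
  expect_true(all(cls %in% c("0", "1")))
  expect_equal(unname(residuals(fit)), unname(ds$y - pr), tolerance = 1e-12)
})
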