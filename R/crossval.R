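#' Model specification for cross-validation
#'
#' Wraps one of the five built-in genomic-prediction models (or any
#' user-supplied fit/predict pair) in the interface [kfold_accuracy()]
#' expects. Fit functions draw from the ambient RNG, so the
#' cross-validation master seed controls every stochastic step, including
#' Gibbs chains and SVR tuning subsets.
#'
#' @param model One of `"rrblup"`, `"bayesA"`, `"bayesB"`, `"blasso"`,
#'   `"svrlin"`.
#' @param cfg [sampler_config()] for the Bayesian models (its `seed` is
#'   ignored inside cross-validation).
#' @param pi_zero Prior exclusion probability for Bayes B.
#' @param grid [svr_grid()] for the SVR model.
#' @return A list with elements `tag`, `fit(g, y)` and
#'   `predict(fit, g)`.
#' @export
gs_model <- function(model = c("rrblup", "bayesA", "bayesB", "blasso",
                               "svrlin"),
                     cfg = sampler_config(), pi_zero = 0.5,
                     grid = svr_grid()) {
  model <- match.arg(model)
  cfg$seed <- NULL # randomness flows from the caller's RNG state
  fit_fun <- switch(model,
    rrblup = function(g, y) fit_rrblup(g, y),
    bayesA = function(g, y) fit_bayes_a(g, y, cfg),
    bayesB = function(g, y) fit_bayes_b(g, y, cfg, pi_zero = pi_zero),
    blasso = function(g, y) fit_bayesian_lasso(g, y, cfg),
    svrlin = function(g, y) fit_svr_linear(g, y, grid)
  )
  list(tag = model, fit = fit_fun,
       predict = function(fit, g) predict(fit, g))
}

#' Repeated k-fold cross-validation accuracy of a genomic-prediction model
#'
#' Per repetition, samples a fresh random partition into `n_folds`
#' near-equal folds, refits the model on each training split (including
#' any hyperparameter tuning, so no test-fold information leaks into
#' fitting), pools the out-of-fold predictions and scores the repetition
#' by the Pearson correlation between pooled predictions and observed
#' phenotypes. Folds are simple random partitions without stratification.
#'
#' @param model A model tag accepted by [gs_model()], a `gs_model()`
#'   result, or any list with `fit(g, y)` and `predict(fit, g)` elements.
#' @param g Complete genotype matrix (samples x markers).
#' @param y Phenotype vector aligned to rows of `g`.
#' @param n_folds Number of folds (default 10).
#' @param n_reps Number of repetitions (default 500).
#' @param seed Master seed controlling fold draws and model randomness.
#' @return A list of class `cv_result` with `model`, `n_folds`, `n_reps`,
#'   `seed`, `accuracies` (one per repetition), `mean`, `sd` and
#'   `flagged` (repetitions with undefined correlation).
#' @export
kfold_accuracy <- function(model, g, y, n_folds = 10L, n_reps = 500L,
                           seed = NULL) {
  stopifnot(is.matrix(g))
  if (is.character(model)) model <- gs_model(model)
  stopifnot(is.function(model$fit), is.function(model$predict))
  y <- .align_phenotype(g, y)
  n <- nrow(g)
  if (n < 2L * n_folds) stop("need at least 2 samples per fold")
  if (!is.null(seed)) set.seed(seed)
  accuracies <- numeric(n_reps)
  flagged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    pred <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- model$fit(g[tr, , drop = FALSE], y[tr])
      pred[!tr] <- model$predict(fit, g[!tr, , drop = FALSE])
    }
    if (sd(pred) == 0 || sd(y) == 0) {
      accuracies[r] <- NA_real_
      flagged[r] <- TRUE
    } else {
      accuracies[r] <- cor(pred, y)
    }
  }
  structure(
    list(model = model$tag %||% "custom", n_folds = n_folds,
         n_reps = n_reps, seed = seed, accuracies = accuracies,
         mean = mean(accuracies, na.rm = TRUE),
         sd = sd(accuracies, na.rm = TRUE), flagged = flagged),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d x %d-fold CV [%s]: mean accuracy %.3f (sd %.3f)\n",
    x$n_reps, x$n_folds, x$model, x$mean, x$sd
  ))
  invisible(x)
}

#' Write a cross-validation result to CSV (+ JSON summary)
#'
#' @param cv A `cv_result`.
#' @param path CSV path (one row per repetition); a `.json` summary with
#'   the same stem is written alongside.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  write.csv(data.frame(repetition = seq_along(cv$accuracies),
                       accuracy = cv$accuracies, flagged = cv$flagged),
            path, row.names = FALSE)
  summary_path <- sub("\\.csv$", ".json", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(model = cv$model, n_folds = cv$n_folds, n_reps = cv$n_reps,
         seed = cv$seed, mean_accuracy = cv$mean, sd_accuracy = cv$sd),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
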