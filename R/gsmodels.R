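#' Ridge-regression BLUP with REML ridge parameter
#'
#' Fits the whole-genome ridge model `y = mu + Z u + e` with
#' `u ~ N(0, sigma2_u I)`, equivalent to a single-kernel GBLUP with kernel
#' `K = Zc Zc'` (`Zc` the column-centred genotype matrix). The ridge
#' parameter `lambda = sigma2_e / sigma2_u` is estimated by maximizing the
#' REML log-likelihood, evaluated through one eigendecomposition of the
#' projected kernel so that each candidate `lambda` costs O(n); the 1-D
#' search runs in log-lambda over `[1e-6, 1e6]` with Brent refinement to
#' 1e-8. Marker effects are recovered as
#' `u = Zc' (K + lambda I)^{-1} (y - mu)` with `mu` the GLS intercept.
#' Markers are centred only (no variance standardization).
#'
#' @param g Complete genotype matrix (samples x markers).
#' @param y Phenotype vector aligned to rows of `g`.
#' @param lambda Optional fixed ridge parameter, bypassing REML (used for
#'   algebraic checks).
#' @return An object of class `gs_fit` with elements `model`, `mu`,
#'   `effects`, `centering`, `lambda`, `sigma2_u`, `sigma2_e`,
#'   `degenerate`.
#' @export
fit_rrblup <- function(g, y, lambda = NULL) {
  stopifnot(is.matrix(g))
  if (anyNA(g)) stop("genotype matrix contains missing codes; impute first")
  y <- .align_phenotype(g, y)
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 samples")
  centering <- colMeans(g)
  gc <- sweep(g, 2L, centering)
  if (sd(y) == 0) {
    return(.gs_fit("rrblup", mu = y[1L],
                   effects = setNames(numeric(ncol(g)), colnames(g)),
                   centering = centering, lambda = Inf,
                   sigma2_u = 0, sigma2_e = 0, degenerate = TRUE))
  }
  K <- tcrossprod(gc)
  if (is.null(lambda)) {
    S <- diag(n) - 1 / n
    ed <- eigen(S %*% K %*% S, symmetric = TRUE)
    theta <- pmax(ed$values[seq_len(n - 1L)], 0)
    eta <- as.vector(crossprod(ed$vectors[, seq_len(n - 1L)], y))
    negll <- function(loglam) {
      d <- exp(loglam)
      s2 <- sum(eta^2 / (theta + d)) / (n - 1L)
      0.5 * ((n - 1L) * log(s2) + sum(log(theta + d)))
    }
    opt <- optimize(negll, c(log(1e-6), log(1e6)), tol = 1e-8)
    lambda <- exp(opt$minimum)
    sigma2_u <- sum(eta^2 / (theta + lambda)) / (n - 1L)
    sigma2_e <- lambda * sigma2_u
  } else {
    if (lambda <= 0) stop("lambda must be > 0")
    sigma2_u <- NA_real_
    sigma2_e <- NA_real_
  }
  Vinv <- solve(K + lambda * diag(n))
  mu <- sum(Vinv %*% y) / sum(Vinv)
  effects <- as.vector(crossprod(gc, Vinv %*% (y - mu)))
  .gs_fit("rrblup", mu = mu,
          effects = setNames(effects, colnames(g)),
          centering = centering, lambda = lambda,
          sigma2_u = sigma2_u, sigma2_e = sigma2_e, degenerate = FALSE)
}

.gs_fit <- function(model, mu, effects, centering, ...) {
  structure(
    c(list(model = model, mu = mu, effects = effects,
           centering = centering), list(...)),
    class = "gs_fit"
  )
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit [%s]: %d marker effects, intercept %.4g\n",
              x$model, length(x$effects), x$mu))
  invisible(x)
}

#' Predict phenotypes from a fitted genomic-selection model
#'
#' `yhat = mu + (G_new - centering) u`, using the centring constants
#' stored in the fit.
#'
#' @param object A `gs_fit`.
#' @param newdata Genotype matrix with the same markers as the fit.
#' @param ... Unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != length(object$effects)) {
    stop("marker count mismatch between fit and new data")
  }
  if (!is.null(colnames(newdata)) && !is.null(names(object$effects)) &&
      !identical(colnames(newdata), names(object$effects))) {
    stop("marker names of new data do not match the fit")
  }
  gc <- sweep(newdata, 2L, object$centering)
  as.vector(object$mu + gc %*% object$effects)
}

#' Gibbs sampler settings for the Bayesian whole-genome regressions
#'
#' @param n_iter Total Gibbs iterations (default 3000).
#' @param burn_in Discarded initial iterations (default 500).
#' @param thinning Keep every `thinning`-th post-burn-in draw (default 5).
#' @param seed Optional integer seed; `NULL` uses the ambient RNG state
#'   (so callers such as cross-validation control reproducibility).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 3000L, burn_in = 500L, thinning = 5L,
                           seed = NULL) {
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thinning < 1L) stop("thinning must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thinning = thinning,
                 seed = seed),
            class = "sampler_config")
}

.bayes_priors <- function(gc, y, pi_zero = 0, df0 = 5, dfe = 5, r2 = 0.5) {
  vy <- var(y)
  msx <- sum(apply(gc, 2L, var))
  s0 <- if (msx > 0) vy * r2 / msx * (df0 + 2) else 0
  if (pi_zero > 0) s0 <- s0 / (1 - pi_zero)
  list(df0 = df0, s0 = s0, dfe = dfe, se = vy * (1 - r2) * (dfe + 2))
}

.fit_bayes <- function(model, g, y, cfg, pi_zero = 0.5) {
  stopifnot(is.matrix(g), inherits(cfg, "sampler_config"))
  if (anyNA(g)) stop("genotype matrix contains missing codes; impute first")
  y <- .align_phenotype(g, y)
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  centering <- colMeans(g)
  gc <- sweep(g, 2L, centering)
  if (sd(y) == 0) {
    return(.gs_fit(model, mu = y[1L],
                   effects = setNames(numeric(ncol(g)), colnames(g)),
                   centering = centering, sampler = unclass(cfg),
                   sigma2_e = 0, degenerate = TRUE))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pr <- .bayes_priors(gc, y, pi_zero = if (model == "bayesB") pi_zero else 0)
  res <- switch(model,
    bayesA = bayes_a_cpp(gc, y, cfg$n_iter, cfg$burn_in, cfg$thinning,
                         pr$df0, pr$s0, pr$dfe, pr$se),
    bayesB = bayes_b_cpp(gc, y, cfg$n_iter, cfg$burn_in, cfg$thinning,
                         pr$df0, pr$s0, pr$dfe, pr$se, pi_zero),
    blasso = blasso_cpp(gc, y, cfg$n_iter, cfg$burn_in, cfg$thinning,
                        pr$dfe, pr$se, 1.0, 1e-3),
    stop("unknown Bayesian model: ", model)
  )
  .gs_fit(model, mu = res$mu,
          effects = setNames(as.vector(res$effects), colnames(g)),
          centering = centering, sampler = unclass(cfg),
          sigma2_e = res$sigma2e, n_samples = res$n_samples,
          pi_zero = if (model == "bayesB") pi_zero else NULL,
          inclusion = if (model == "bayesB") as.vector(res$inclusion)
                      else NULL,
          degenerate = FALSE)
}

#' Bayesian whole-genome regressions via Gibbs sampling
#'
#' Three shrinkage priors on marker effects, all fitted by Gibbs sampling
#' with posterior-mean effects taken over post-burn-in thinned draws:
#'
#' * **Bayes A** (`fit_bayes_a`): marker-specific effect variances with
#'   scaled-inverse-chi-square priors (df 5, scale set so the prior
#'   explains half the phenotypic variance).
#' * **Bayes B** (`fit_bayes_b`): the same, mixed with a point mass at
#'   zero; prior exclusion probability `pi_zero` (default 0.5) with
#'   inclusion indicators sampled from the marginal likelihood ratio.
#' * **Bayesian Lasso** (`fit_bayesian_lasso`): double-exponential prior
#'   through its exponential scale mixture, with a gamma hyperprior on the
#'   squared regularization parameter.
#'
#' @param g Complete genotype matrix (samples x markers).
#' @param y Phenotype vector aligned to rows of `g`.
#' @param cfg A [sampler_config()].
#' @param pi_zero Prior probability that a marker has zero effect
#'   (Bayes B only).
#' @return A `gs_fit` with posterior-mean intercept and effects; Bayes B
#'   fits also carry per-marker posterior inclusion probabilities in
#'   `$inclusion`.
#' @export
fit_bayes_a <- function(g, y, cfg = sampler_config()) {
  .fit_bayes("bayesA", g, y, cfg)
}

#' @rdname fit_bayes_a
#' @export
fit_bayes_b <- function(g, y, cfg = sampler_config(), pi_zero = 0.5) {
  if (pi_zero < 0 || pi_zero >= 1) stop("pi_zero must be in [0, 1)")
  .fit_bayes("bayesB", g, y, cfg, pi_zero = pi_zero)
}

#' @rdname fit_bayes_a
#' @export
fit_bayesian_lasso <- function(g, y, cfg = sampler_config()) {
  .fit_bayes("blasso", g, y, cfg)
}

#' Hyperparameter grid for linear support-vector regression
#'
#' @param cost Candidate cost values (default `2^1 .. 2^6`).
#' @param epsilon Candidate epsilon values (default `0, 0.1, ..., 0.9`).
#' @param tuning_fraction Fraction of the training data used for the grid
#'   search (default 0.10).
#' @return A list of class `svr_grid`; `expand.grid` of the candidates is
#'   available via `$pairs`.
#' @export
svr_grid <- function(cost = 2^(1:6), epsilon = seq(0, 0.9, by = 0.1),
                     tuning_fraction = 0.10) {
  if (length(cost) == 0L || length(epsilon) == 0L) stop("empty grid")
  if (tuning_fraction <= 0 || tuning_fraction >= 1) {
    stop("tuning_fraction must be in (0, 1)")
  }
  structure(
    list(cost = cost, epsilon = epsilon, tuning_fraction = tuning_fraction,
         pairs = expand.grid(cost = cost, epsilon = epsilon,
                             KEEP.OUT.ATTRS = FALSE)),
    class = "svr_grid"
  )
}

#' Linear epsilon-insensitive support-vector regression
#'
#' Tunes cost and epsilon by exhaustive grid search (all
#' `length(cost) x length(epsilon)` pairs) with 5-fold cross-validated
#' mean-squared error on a seeded random subset (default 10%) of the
#' training data, then refits on all training data with the winning pair.
#' The linear weights are exposed as marker effects so [predict.gs_fit()]
#' applies unchanged. If the tuning subset is too small for internal CV
#' the grid search falls back to the full training data with a warning.
#'
#' @param g Complete genotype matrix (samples x markers).
#' @param y Phenotype vector aligned to rows of `g`.
#' @param grid An [svr_grid()].
#' @param seed Optional seed for the tuning subset and fold draws.
#' @return A `gs_fit` with `cost`, `epsilon` and `tuning_mse` recorded.
#' @export
fit_svr_linear <- function(g, y, grid = svr_grid(), seed = NULL) {
  stopifnot(is.matrix(g), inherits(grid, "svr_grid"))
  if (anyNA(g)) stop("genotype matrix contains missing codes; impute first")
  y <- .align_phenotype(g, y)
  n <- nrow(g)
  centering <- colMeans(g)
  gc <- sweep(g, 2L, centering)
  if (sd(y) == 0) {
    return(.gs_fit("svrlin", mu = y[1L],
                   effects = setNames(numeric(ncol(g)), colnames(g)),
                   centering = centering, cost = NA_real_,
                   epsilon = NA_real_, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n_sub <- ceiling(grid$tuning_fraction * n)
  if (n_sub < 10L) {
    warning("tuning subset too small for internal CV; ",
            "tuning on the full training data")
    sub <- seq_len(n)
  } else {
    sub <- sample.int(n, n_sub)
  }
  xs <- gc[sub, , drop = FALSE]
  ys <- y[sub]
  folds <- sample(rep(seq_len(5L), length.out = length(sub)))
  mse <- vapply(seq_len(nrow(grid$pairs)), function(i) {
    sq_err <- 0
    for (f in seq_len(5L)) {
      tr <- folds != f
      if (sum(tr) < 2L || sd(ys[tr]) == 0) return(Inf)
      m <- e1071::svm(xs[tr, , drop = FALSE], ys[tr],
                      type = "eps-regression", kernel = "linear",
                      cost = grid$pairs$cost[i],
                      epsilon = grid$pairs$epsilon[i], scale = FALSE)
      pr <- predict(m, xs[!tr, , drop = FALSE])
      sq_err <- sq_err + sum((pr - ys[!tr])^2)
    }
    sq_err / length(sub)
  }, numeric(1))
  best <- which.min(mse)
  model <- e1071::svm(gc, y, type = "eps-regression", kernel = "linear",
                      cost = grid$pairs$cost[best],
                      epsilon = grid$pairs$epsilon[best], scale = FALSE)
  w <- as.vector(crossprod(model$SV, model$coefs))
  .gs_fit("svrlin", mu = -model$rho,
          effects = setNames(w, colnames(g)),
          centering = centering,
          cost = grid$pairs$cost[best], epsilon = grid$pairs$epsilon[best],
          tuning_mse = mse[best], degenerate = FALSE)
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores the model tag, intercept, marker effects, centring constants and
#' hyperparameters in a plain JSON artifact.
#'
#' @param fit A `gs_fit`.
#' @param path Output/input file path.
#' @return `read_gs_fit` returns a `gs_fit`; `write_gs_fit` returns
#'   `path` invisibly.
#' @export
write_gs_fit <- function(fit, path) {
  stopifnot(inherits(fit, "gs_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gs_fit
#' @export
read_gs_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$effects <- unlist(x$effects)
  x$centering <- unlist(x$centering)
  class(x) <- "gs_fit"
  x
}
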