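test_that("marker-effect and kernel GBLUP formulations agree", {
  g <- make_geno(40, 120, seed = 1)
  set.seed(2)
  y <- rnorm(40) + g[, 3] * 0.8
  gc <- sweep(g, 2, colMeans(g))
  K <- tcrossprod(gc)
  for (lam in c(0.5, 10, 300)) {
    fit <- fit_rrblup(g, y, lambda = lam)
    pred_marker <- predict(fit, g)
    # independent kernel route: ghat = K (K + lam I)^-1 (y - mu)
    Vinv <- solve(K + lam * diag(40))
    pred_kernel <- fit$mu + as.vector(K %*% Vinv %*% (y - fit$mu))
    expect_equal(pred_marker, pred_kernel, tolerance = 1e-8)
  }
})

test_that("fixed-lambda effects match the primal ridge solution", {
  g <- matrix(c(0, 1, 2, 2, 0, 1), 3, 2,
              dimnames = list(NULL, c("m1", "m2")))
  y <- c(1.0, 2.5, 2.0)
  fit <- fit_rrblup(g, y, lambda = 1)
  gc <- sweep(g, 2, colMeans(g))
  # oracle: dual->primal identity u = (Gc'Gc + lam I_p)^-1 Gc' (y - mu)
  u_oracle <- solve(crossprod(gc) + diag(2), crossprod(gc, y - fit$mu))
  expect_equal(unname(fit$effects), as.vector(u_oracle), tolerance = 1e-10)
})

test_that("extreme shrinkage collapses to the mean, none interpolates", {
  g <- make_geno(30, 10, seed = 3)
  set.seed(4)
  beta <- rnorm(10)
  y <- as.vector(g %*% beta) + 2
  heavy <- fit_rrblup(g, y, lambda = 1e12)
  expect_lt(max(abs(heavy$effects)), 1e-6)
  expect_equal(predict(heavy, g), rep(mean(y), 30), tolerance = 1e-4)
  light <- fit_rrblup(g, y, lambda = 1e-8)
  expect_equal(predict(light, g), y, tolerance = 1e-5) # noiseless, n > p
})

test_that("the ridge norm decreases monotonically in lambda", {
  g <- make_geno(25, 40, seed = 5)
  set.seed(6)
  y <- rnorm(25)
  norms <- sapply(10^seq(-2, 4), function(l) {
    sqrt(sum(fit_rrblup(g, y, lambda = l)$effects^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("REML lambda maximizes the profiled likelihood it reports", {
  g <- make_geno(50, 80, seed = 7)
  set.seed(8)
  y <- as.vector(g %*% rnorm(80, sd = 0.2)) + rnorm(50)
  fit <- fit_rrblup(g, y)
  expect_gt(fit$lambda, 0)
  expect_gt(fit$sigma2_u, 0)
  expect_equal(fit$sigma2_e / fit$sigma2_u, fit$lambda, tolerance = 1e-6)
  # constant phenotype degenerates cleanly
  flat <- fit_rrblup(g, rep(1, 50))
  expect_true(flat$degenerate)
  expect_equal(unname(flat$effects), rep(0, 80))
  expect_equal(predict(flat, g), rep(1, 50))
})

test_that("predictions are invariant to consistent marker permutation", {
  g <- make_geno(30, 20, seed = 9)
  set.seed(10)
  y <- rnorm(30)
  fit <- fit_rrblup(g, y, lambda = 5)
  perm <- sample(20)
  fit_p <- fit_rrblup(g[, perm], y, lambda = 5)
  expect_equal(predict(fit_p, g[, perm]), predict(fit, g),
               tolerance = 1e-10)
  # an all-reference row predicts mu minus the centering contribution
  zero_row <- matrix(0, 1, 20, dimnames = list(NULL, colnames(g)))
  expect_equal(predict(fit, zero_row),
               fit$mu - sum(fit$centering * fit$effects),
               tolerance = 1e-10)
  expect_error(predict(fit, g[, 1:5]), "mismatch")
})

test_that("Gibbs samplers are seed-deterministic and handle null data", {
  g <- make_geno(40, 60, seed = 11)
  set.seed(12)
  y <- as.vector(g %*% rnorm(60, sd = 0.3)) + rnorm(40)
  cfg <- sampler_config(400, 100, 2, seed = 99)
  for (fitter in list(fit_bayes_a, fit_bayes_b, fit_bayesian_lasso)) {
    f1 <- fitter(g, y, cfg)
    f2 <- fitter(g, y, cfg)
    expect_identical(f1$effects, f2$effects)
    expect_identical(f1$mu, f2$mu)
    flat <- fitter(g, rep(2, 40), cfg)
    expect_true(flat$degenerate)
    expect_equal(unname(flat$effects), rep(0, 60))
  }
  expect_error(sampler_config(100, 100), "burn_in")
  expect_error(fit_bayes_b(g, y, cfg, pi_zero = 1), "pi_zero")
})

test_that("Bayes B concentrates posterior mass on true sparse QTL", {
  cfg <- sim_config(n_genotypes = 150, n_markers = 300, n_qtl = 5,
                    target_h2 = 0.9, var_ratio_gc_over_g = 0, seed = 13)
  x <- simulate_population(cfg)
  ph <- simulate_phenotypes(x, cfg)
  g <- collapse_tetraploid(x)
  y <- tapply(ph$phenotypes$value, ph$phenotypes$progeny, mean)
  fit <- fit_bayes_b(g, y[rownames(g)],
                     sampler_config(1500, 300, 5, seed = 14))
  top <- order(abs(fit$effects), decreasing = TRUE)[1:15] # top 5%
  expect_gte(length(intersect(ph$truth$qtl, top)), 4)
  # posterior inclusion tracks the same markers
  expect_gt(mean(fit$inclusion[ph$truth$qtl]),
            mean(fit$inclusion[-ph$truth$qtl]))
})

test_that("Bayes A and the Bayesian Lasso recover strong signal directions", {
  g <- make_geno(100, 150, seed = 15)
  set.seed(16)
  beta <- numeric(150)
  beta[c(10, 80, 140)] <- c(2, -2, 1.5)
  y <- as.vector(g %*% beta) + rnorm(100, sd = 0.8)
  cfg <- sampler_config(1200, 300, 3, seed = 17)
  for (fitter in list(fit_bayes_a, fit_bayesian_lasso)) {
    fit <- fitter(g, y, cfg)
    expect_gt(cor(fit$effects, beta), 0.6)
    preds <- predict(fit, g)
    expect_gt(cor(preds, y), 0.8)
  }
})

test_that("doubling the chain length leaves posterior means stable", {
  g <- make_geno(50, 40, seed = 18)
  set.seed(19)
  y <- as.vector(g %*% rnorm(40, sd = 0.4)) + rnorm(50, sd = 0.5)
  f_short <- fit_bayes_a(g, y, sampler_config(2000, 500, 2, seed = 20))
  f_long <- fit_bayes_a(g, y, sampler_config(4000, 500, 2, seed = 21))
  # Monte Carlo tolerance: a small fraction of the effect scale
  tol <- 0.1 * max(sd(f_long$effects), 1e-3)
  expect_lt(max(abs(f_short$effects - f_long$effects)), 4 * tol)
  expect_gt(cor(f_short$effects, f_long$effects), 0.95)
})

test_that("the SVR grid enumerates 60 pairs and fits linear signal", {
  grid <- svr_grid()
  expect_identical(nrow(grid$pairs), 60L)
  expect_setequal(unique(grid$pairs$cost), 2^(1:6))
  expect_equal(sort(unique(grid$pairs$epsilon)), seq(0, 0.9, 0.1))

  g <- make_geno(40, 8, seed = 22)
  set.seed(23)
  y <- as.vector(g %*% rnorm(8))
  fit <- suppressWarnings(fit_svr_linear(g, y, seed = 24))
  expect_gt(cor(predict(fit, g), y), 0.999)
  flat <- fit_svr_linear(g, rep(3, 40))
  expect_true(flat$degenerate)
  expect_equal(predict(flat, g), rep(3, 40))
})

test_that("large-n SVR tunes on its 10% subset without warning", {
  g <- make_geno(120, 15, seed = 25)
  set.seed(26)
  y <- as.vector(g %*% rnorm(15)) + rnorm(120, sd = 0.5)
  expect_no_warning(fit <- fit_svr_linear(g, y, seed = 27))
  expect_true(fit$cost %in% 2^(1:6))
  expect_true(fit$epsilon %in% seq(0, 0.9, 0.1))
})

test_that("fits serialize to JSON and back without losing predictions", {
  g <- make_geno(25, 12, seed = 28)
  set.seed(29)
  y <- rnorm(25)
  fit <- fit_rrblup(g, y)
  path <- file.path(tempdir(), "fit.json")
  write_gs_fit(fit, path)
  back <- read_gs_fit(path)
  expect_equal(back$model, "rrblup")
  expect_equal(predict(back, g), predict(fit, g), tolerance = 1e-12)
})
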