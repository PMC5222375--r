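test_that("balanced variance components match a hand EMS oracle", {
  set.seed(1)
  g <- rnorm(4, sd = 2)
  ge <- matrix(rnorm(8, sd = 1), 4, 2)
  attr(ge, "k") <- 3L
  tab <- balanced_pheno(g, ge, sd_e = 1, seed = 2)
  vc <- fit_variance_components(tab)
  # independent oracle: mean squares from stats::aov
  fit <- aov(value ~ condition + progeny + progeny:condition, data = tab)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  k <- 3
  cc <- 2
  expect_equal(vc$sigma2_e, ms[["Residuals"]], tolerance = 1e-10)
  expect_equal(vc$sigma2_ge,
               max((ms[["condition:progeny"]] - ms[["Residuals"]]) / k, 0),
               tolerance = 1e-10)
  expect_equal(vc$sigma2_g,
               max((ms[["progeny"]] - ms[["condition:progeny"]]) / (cc * k),
                   0),
               tolerance = 1e-10)
})

test_that("EMS and REML agree on balanced data", {
  set.seed(3)
  g <- rnorm(30, sd = 1.5)
  ge <- matrix(rnorm(90, sd = 1), 30, 3)
  attr(ge, "k") <- 3L
  tab <- balanced_pheno(g, ge, sd_e = 1, seed = 4)
  vc <- fit_variance_components(tab)
  fit <- lme4::lmer(
    value ~ condition + (1 | progeny) + (1 | progeny:condition),
    data = tab, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                optCtrl = list(rhoend = 1e-12))
  )
  reml <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma2_g, reml$vcov[reml$grp == "progeny"],
               tolerance = 1e-6)
  expect_equal(vc$sigma2_ge, reml$vcov[reml$grp == "progeny:condition"],
               tolerance = 1e-6)
  expect_equal(vc$sigma2_e, reml$vcov[reml$grp == "Residual"],
               tolerance = 1e-6)
})

test_that("zero-variance phenotypes give all-zero components", {
  g <- rep(0, 5)
  ge <- matrix(0, 5, 3)
  attr(ge, "k") <- 2L
  tab <- balanced_pheno(g, ge, sd_e = 0)
  vc <- fit_variance_components(tab)
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_ge, 0)
  expect_equal(vc$sigma2_e, 0)
  expect_error(heritability_broad(vc), "undefined")
})

test_that("single condition and degenerate tables are rejected", {
  g <- rnorm(4)
  ge <- matrix(0, 4, 1)
  attr(ge, "k") <- 3L
  tab <- balanced_pheno(g, ge, sd_e = 1, seed = 5)
  expect_error(fit_variance_components(tab), "single condition")
})

test_that("CVg arithmetic", {
  expect_equal(cv_g(4, 40), 5)
  expect_equal(cv_g(0, 10), 0)
  expect_equal(cv_g(1, 1), 100)
  expect_error(cv_g(1, 0), "nonzero")
  expect_error(cv_g(-1, 1), ">= 0")
})

test_that("broad-sense heritability formula and monotonicity", {
  vc <- list(sigma2_g = 1, sigma2_ge = 1, sigma2_e = 1, c = 3, k = 3)
  expect_equal(heritability_broad(vc), 1 / (1 + 1 / 3 + 1 / 9),
               tolerance = 1e-12)
  expect_equal(heritability_broad(list(sigma2_g = 0, sigma2_ge = 1,
                                       sigma2_e = 1, c = 3, k = 3)), 0)
  expect_equal(heritability_broad(list(sigma2_g = 2, sigma2_ge = 0,
                                       sigma2_e = 0, c = 3, k = 3)), 1)
  # monotone in sigma2_g, c and k
  h <- function(vg, cc, k) {
    heritability_broad(list(sigma2_g = vg, sigma2_ge = 0.5, sigma2_e = 1,
                            c = cc, k = k))
  }
  expect_true(all(diff(sapply(seq(0.1, 3, by = 0.1), h, cc = 3, k = 3)) > 0))
  expect_true(all(diff(sapply(1:8, function(cc) h(1, cc, 3))) > 0))
  expect_true(all(diff(sapply(1:8, function(k) h(1, 3, k))) > 0))
})

test_that("type-B genetic correlation, including the truncation cap", {
  expect_equal(as.numeric(genetic_correlation(0.5, 0.5, 0.5)), 1)
  expect_equal(as.numeric(genetic_correlation(0, 0.4, 0.7)), 0)
  capped <- genetic_correlation(0.9, 0.5, 0.5)
  expect_equal(as.numeric(capped), 1)
  expect_equal(attr(capped, "raw"), 1.8)
  expect_equal(as.numeric(genetic_correlation(-0.9, 0.5, 0.5)), -1)
  expect_error(genetic_correlation(0.5, 0, 0.5), "\\(0, 1\\]")
  expect_error(genetic_correlation(1.5, 0.5, 0.5), "r_p")
})

test_that("BLUPs shrink progeny means toward the grand mean", {
  set.seed(6)
  g <- rnorm(20, sd = 1)
  ge <- matrix(rnorm(60, sd = 0.6), 20, 3)
  attr(ge, "k") <- 3L
  tab <- balanced_pheno(g, ge, sd_e = 1.5, seed = 7)
  adj <- progeny_blups(tab)
  blup <- attr(adj, "blup")
  raw <- attr(adj, "raw_means")
  expect_equal(sum(blup), 0, tolerance = 1e-9)
  expect_true(all(abs(blup) <= abs(raw - mean(raw)) + 1e-12))
  # balanced shrinkage factor equals h2_B
  vc <- fit_variance_components(tab)
  expect_equal(as.numeric(blup / (raw - mean(raw))),
               rep(heritability_broad(vc), 20), tolerance = 1e-9)
})

test_that("no genetic signal means full shrinkage to the grand mean", {
  # progeny means identical by construction -> sigma2_g truncates to 0
  g <- rep(0, 6)
  ge <- matrix(0, 6, 2)
  attr(ge, "k") <- 2L
  tab <- balanced_pheno(g, ge, sd_e = 0)
  tab$value <- rep(c(1, 2, 3, 4), length.out = nrow(tab)) # replicate noise
  adj <- progeny_blups(tab)
  expect_equal(unname(as.numeric(adj)), rep(mean(tab$value), 6),
               tolerance = 1e-9)
})

test_that("REML BLUPs on unbalanced data rank truth better than raw means", {
  set.seed(8)
  cors <- replicate(30, {
    g <- rnorm(25)
    ge <- matrix(rnorm(75, sd = 0.5), 25, 3)
    attr(ge, "k") <- 3L
    tab <- balanced_pheno(g, ge, sd_e = 2)
    # unbalance: drop one replicate in a random third of the cells
    cells <- unique(tab[, c("progeny", "condition")])
    drop_cells <- cells[sample(nrow(cells), nrow(cells) %/% 3), ]
    drop_idx <- vapply(seq_len(nrow(drop_cells)), function(i) {
      which(tab$progeny == drop_cells$progeny[i] &
              tab$condition == drop_cells$condition[i])[1L]
    }, integer(1))
    tab <- tab[-drop_idx, ]
    adj <- suppressWarnings(progeny_blups(tab))
    raw <- tapply(tab$value, tab$progeny, mean)
    c(blup = cor(as.numeric(adj), g[as.integer(sub("P", "", names(adj)))]),
      raw = cor(raw, g[as.integer(sub("P", "", names(raw)))]))
  })
  cors <- cors[, colSums(is.na(cors)) == 0, drop = FALSE]
  expect_gt(mean(cors[1, ]), mean(cors[2, ]) - 1e-9)
})

test_that("phenotypic correlations behave as Pearson on progeny vectors", {
  x <- setNames(rnorm(30), sprintf("P%02d", 1:30))
  m <- phenotypic_correlations(a = x, b = -x, c = x * 2)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["a", "b"], -1)
  expect_equal(m["a", "c"], 1)
  expect_true(isSymmetric(m))
  expect_warning(phenotypic_correlations(a = x, b = x * 0), "constant")
})

test_that("traits sharing half their QTL are positively correlated", {
  cfg <- sim_config(n_genotypes = 150, n_markers = 60, seed = 9)
  x <- simulate_population(cfg)
  set.seed(10)
  beta_shared <- rnorm(20)
  g_a <- as.vector(x[, 1:20] %*% beta_shared + x[, 21:40] %*% rnorm(20))
  g_b <- as.vector(x[, 1:20] %*% beta_shared + x[, 41:60] %*% rnorm(20))
  y_a <- g_a + rnorm(150, sd = sd(g_a))
  y_b <- g_b + rnorm(150, sd = sd(g_b))
  r <- phenotypic_correlations(a = y_a, b = y_b)["a", "b"]
  expect_gt(r, 3 / sqrt(150)) # positive at 3 SE of a null correlation
})
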