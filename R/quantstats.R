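#' Variance components of a replicated multi-condition half-sib trial
#'
#' Decomposes trait variation into progeny (genetic, `sigma2_g`),
#' progeny-by-condition interaction (`sigma2_ge`) and plot error
#' (`sigma2_e`), treating conditions as fixed and progeny and interaction
#' as random. For balanced data the estimates are method-of-moments
#' solutions of the expected mean squares:
#' \deqn{MS_P = \sigma^2_e + k\,\sigma^2_{ge} + ck\,\sigma^2_g, \quad
#'       MS_{PC} = \sigma^2_e + k\,\sigma^2_{ge}, \quad
#'       MS_E = \sigma^2_e}
#' Unbalanced data fall back to REML (via \pkg{lme4}) with a warning.
#' Negative estimates are truncated to zero and flagged. Per-condition
#' genetic variances (one-way ANOVA within condition) are returned for
#' genetic coefficients of variation and condition-specific heritability.
#'
#' @param pheno Long phenotype table with columns `progeny`, `condition`,
#'   `replicate`, `trait`, `value`.
#' @param trait Trait id to analyse (default: the only trait present).
#' @return A list of class `variance_components` with elements `sigma2_g`,
#'   `sigma2_ge`, `sigma2_e`, `c`, `k`, `n_progeny`, `grand_mean`,
#'   `progeny_means`, `per_condition` (data frame: condition, sigma2_g,
#'   sigma2_e, mean), `truncated` (logical flags) and `method`.
#' @export
fit_variance_components <- function(pheno, trait = NULL) {
  pheno <- .check_pheno(pheno, trait)
  prog <- factor(pheno$progeny)
  cond <- factor(pheno$condition)
  n_p <- nlevels(prog)
  cc <- nlevels(cond)
  if (n_p < 2L) stop("need >= 2 progenies")
  if (cc < 2L) stop("sigma2_ge is undefined with a single condition")
  counts <- table(prog, cond)
  k <- counts[1L]
  balanced <- all(counts == k) && k >= 2L
  if (any(counts < 2L)) stop("need >= 2 replicates per progeny x condition")

  y <- pheno$value
  grand <- mean(y)
  if (balanced) {
    cell <- tapply(y, list(prog, cond), mean)       # n_p x c cell means
    m_p <- rowMeans(cell)
    m_c <- colMeans(cell)
    ss_p <- cc * k * sum((m_p - grand)^2)
    ss_pc <- k * sum((sweep(sweep(cell, 1, m_p), 2, m_c) + grand)^2)
    ss_e <- sum((y - cell[cbind(prog, cond)])^2)
    ms_p <- ss_p / (n_p - 1)
    ms_pc <- ss_pc / ((n_p - 1) * (cc - 1))
    ms_e <- ss_e / (n_p * cc * (k - 1))
    s2e <- ms_e
    s2ge_raw <- (ms_pc - ms_e) / k
    s2g_raw <- (ms_p - ms_pc) / (cc * k)
    method <- "ems"
  } else {
    warning("unbalanced design: falling back to REML variance components")
    fit <- lme4::lmer(
      value ~ condition + (1 | progeny) + (1 | progeny:condition),
      data = pheno, REML = TRUE
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2g_raw <- vc$vcov[vc$grp == "progeny"]
    s2ge_raw <- vc$vcov[vc$grp == "progeny:condition"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    k <- mean(counts)
    method <- "reml"
  }
  truncated <- c(sigma2_g = s2g_raw < 0, sigma2_ge = s2ge_raw < 0)

  per_condition <- do.call(rbind, lapply(levels(cond), function(cn) {
    sub <- pheno[cond == cn, ]
    pf <- factor(sub$progeny)
    kk <- mean(table(pf))
    pm <- tapply(sub$value, pf, mean)
    ms_between <- kk * sum((pm - mean(sub$value))^2) / (nlevels(pf) - 1)
    ms_within <- sum((sub$value - pm[pf])^2) /
      (length(sub$value) - nlevels(pf))
    data.frame(
      condition = cn,
      sigma2_g = max((ms_between - ms_within) / kk, 0),
      sigma2_e = ms_within,
      mean = mean(sub$value)
    )
  }))

  progeny_means <- tapply(y, prog, mean)
  structure(
    list(
      sigma2_g = max(s2g_raw, 0), sigma2_ge = max(s2ge_raw, 0),
      sigma2_e = s2e, c = cc, k = as.numeric(k), n_progeny = n_p,
      grand_mean = grand, progeny_means = progeny_means,
      per_condition = per_condition, truncated = truncated, method = method
    ),
    class = "variance_components"
  )
}

.check_pheno <- function(pheno, trait = NULL) {
  need <- c("progeny", "condition", "replicate", "trait", "value")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(trait)) {
    traits <- unique(pheno$trait)
    if (length(traits) != 1L) {
      stop("several traits present; specify `trait`")
    }
    trait <- traits
  }
  out <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(out) == 0L) stop("trait not found: ", trait)
  if (any(!is.finite(out$value))) stop("non-finite trait values")
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s): sigma2_g = %.4g, sigma2_ge = %.4g, sigma2_e = %.4g\n",
    x$method, x$sigma2_g, x$sigma2_ge, x$sigma2_e
  ))
  cat(sprintf("  %d progenies, %d conditions, %.3g replicates; h2_B = %.3f\n",
              x$n_progeny, x$c, x$k, heritability_broad(x)))
  invisible(x)
}

#' Genetic coefficient of variation
#'
#' `CVg = 100 * sqrt(sigma2_g) / mean`, the genetic standard deviation as a
#' percentage of the trait mean, usually computed per growing condition.
#'
#' @param sigma2_g Genetic variance (>= 0).
#' @param trait_mean Trait mean (nonzero).
#' @return CVg in percent.
#' @export
#' @examples
#' cv_g(4, 40) # 5%
cv_g <- function(sigma2_g, trait_mean) {
  if (any(sigma2_g < 0)) stop("sigma2_g must be >= 0")
  if (any(trait_mean == 0)) stop("trait_mean must be nonzero")
  100 * sqrt(sigma2_g) / trait_mean
}

#' Broad-sense heritability on a progeny-mean basis
#'
#' `h2_B = sigma2_g / (sigma2_g + sigma2_ge / c + sigma2_e / (c k))`, the
#' fraction of progeny-mean variance across `c` conditions with `k`
#' replicates that is genetic.
#'
#' @param vc A `variance_components` object, or a list with elements
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, `c`, `k`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability_broad <- function(vc) {
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$c + vc$sigma2_e / (vc$c * vc$k)
  if (denom == 0) stop("all variance components are zero: h2 undefined")
  vc$sigma2_g / denom
}

#' Condition-specific broad-sense heritability
#'
#' Progeny-mean heritability within a single condition,
#' `sigma2_g / (sigma2_g + sigma2_e / k)`.
#'
#' @param sigma2_g,sigma2_e Within-condition variance components.
#' @param k Number of replicates.
#' @return Heritability in `[0, 1]`.
#' @export
heritability_single <- function(sigma2_g, sigma2_e, k) {
  denom <- sigma2_g + sigma2_e / k
  if (any(denom == 0)) stop("zero variance: h2 undefined")
  sigma2_g / denom
}

#' Type-B genetic correlation across two conditions
#'
#' `r_g = r_p / sqrt(h2_i * h2_j)`, the phenotypic correlation of progeny
#' means across two conditions divided by the geometric mean of the two
#' condition-specific heritabilities. Raw values outside `[-1, 1]` (common
#' with modest heritabilities) are truncated and reported as capped; the
#' untruncated value is kept in attribute `"raw"`.
#'
#' @param r_p Phenotypic correlation between progeny means in the two
#'   conditions, in `[-1, 1]`.
#' @param h2_i,h2_j Condition-specific heritabilities in `(0, 1]`.
#' @return Genetic correlation truncated into `[-1, 1]`.
#' @export
genetic_correlation <- function(r_p, h2_i, h2_j) {
  if (any(h2_i <= 0) || any(h2_j <= 0) || any(h2_i > 1) || any(h2_j > 1)) {
    stop("heritabilities must be in (0, 1]")
  }
  if (any(abs(r_p) > 1)) stop("r_p must be in [-1, 1]")
  raw <- r_p / sqrt(h2_i * h2_j)
  out <- pmin(pmax(raw, -1), 1)
  attr(out, "raw") <- raw
  out
}

#' BLUP-adjusted progeny phenotypes
#'
#' Fits the half-sib model with condition fixed and progeny and
#' progeny-by-condition random, and returns, per progeny, the grand mean
#' plus the BLUP of its genetic effect. For balanced data this equals the
#' progeny mean deviation shrunk by the progeny-mean heritability `h2_B`;
#' unbalanced data use REML BLUPs from \pkg{lme4}. These adjusted values
#' are the phenotypes used for GWAS and genomic prediction.
#'
#' @inheritParams fit_variance_components
#' @return Named numeric vector (one value per progeny) of class
#'   `adjusted_phenotypes`, with the shrinkage deviations in attribute
#'   `"blup"` (zero mean) and the raw progeny means in `"raw_means"`.
#' @export
progeny_blups <- function(pheno, trait = NULL) {
  pheno <- .check_pheno(pheno, trait)
  vc <- suppressWarnings(fit_variance_components(pheno))
  if (vc$method == "ems") {
    denom <- vc$sigma2_g + vc$sigma2_ge / vc$c + vc$sigma2_e / (vc$c * vc$k)
    shrink <- if (denom > 0) vc$sigma2_g / denom else 0
    dev <- vc$progeny_means - vc$grand_mean
    blup <- shrink * dev
  } else {
    fit <- lme4::lmer(
      value ~ condition + (1 | progeny) + (1 | progeny:condition),
      data = pheno, REML = TRUE
    )
    re <- lme4::ranef(fit)$progeny
    blup <- setNames(re[[1L]], rownames(re))
    blup <- blup[names(vc$progeny_means)]
  }
  out <- vc$grand_mean + blup
  structure(setNames(as.numeric(out), names(vc$progeny_means)),
            blup = blup - mean(blup),
            raw_means = vc$progeny_means,
            class = "adjusted_phenotypes")
}

#' Phenotypic correlations between traits
#'
#' Pearson correlations between BLUP-adjusted (or otherwise per-progeny)
#' trait vectors sharing a progeny set. Constant traits produce `NA`
#' entries and a warning.
#'
#' @param ... Named numeric vectors (one per trait, aligned by progeny
#'   names), or a single list/data frame of them.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
phenotypic_correlations <- function(...) {
  args <- list(...)
  if (length(args) == 1L && (is.list(args[[1L]]) || is.data.frame(args[[1L]]))) {
    args <- as.list(args[[1L]])
  }
  if (length(args) < 2L) stop("need at least two traits")
  ids <- names(args[[1L]])
  mat <- sapply(args, function(v) {
    if (!is.null(ids) && !is.null(names(v))) v <- v[ids]
    as.numeric(v)
  })
  if (any(apply(mat, 2, sd) == 0)) {
    warning("constant trait: correlation undefined (NA)")
  }
  suppressWarnings(cor(mat))
}
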