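#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic study design in one validated list.
#' Defaults reproduce the design the package targets: 154 tetraploid
#' parent genotypes scored at ~10^4 biallelic GBS markers, each parent
#' phenotyped through half-sib progeny means in 3 growing conditions with
#' 3 replicates, moderate progeny-mean heritability and modest
#' genotype-by-condition interaction.
#'
#' @param n_genotypes Number of parent genotypes (samples).
#' @param n_markers Number of biallelic markers.
#' @param maf_range Length-2 numeric, range of minor-allele frequencies
#'   markers are drawn from (uniform).
#' @param mean_depth Expected sequencing depth per sample x marker cell.
#' @param depth_dispersion Negative-binomial size parameter for depth;
#'   `Inf` collapses to Poisson.
#' @param n_qtl Number of markers with nonzero additive effect. `NULL`
#'   (default) means all markers are causal (polygenic architecture).
#' @param target_h2 Target narrow-sense heritability at the progeny-mean
#'   level, in `[0, 1]`.
#' @param var_ratio_gc_over_g Ratio of genotype-by-condition interaction
#'   variance to genetic variance (sigma2_ge / sigma2_g).
#' @param n_conditions Number of growing conditions.
#' @param n_reps Number of replicates per condition.
#' @param condition_means Numeric vector of condition means (trait units);
#'   defaults to zeros (traits are treated as standardized quantities).
#' @param seed Integer seed; every downstream draw is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 20, n_markers = 50, seed = 1)
sim_config <- function(n_genotypes = 154L,
                       n_markers = 10000L,
                       maf_range = c(0.05, 0.45),
                       mean_depth = 30,
                       depth_dispersion = 2,
                       n_qtl = NULL,
                       target_h2 = 0.5,
                       var_ratio_gc_over_g = 0.25,
                       n_conditions = 3L,
                       n_reps = 3L,
                       condition_means = NULL,
                       seed = NULL) {
  n_genotypes <- as.integer(n_genotypes)
  n_markers <- as.integer(n_markers)
  if (n_genotypes < 1L) stop("n_genotypes must be >= 1")
  if (n_markers < 0L) stop("n_markers must be >= 0")
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair of proportions in [0, 0.5]")
  }
  if (!is.finite(mean_depth) || mean_depth <= 0) {
    stop("mean_depth must be > 0")
  }
  if (depth_dispersion <= 0) stop("depth_dispersion must be > 0")
  if (is.null(n_qtl)) n_qtl <- n_markers
  n_qtl <- as.integer(n_qtl)
  if (n_qtl < 0L || n_qtl > n_markers) {
    stop("n_qtl must be between 0 and n_markers")
  }
  if (target_h2 < 0 || target_h2 > 1) stop("target_h2 must be in [0, 1]")
  if (var_ratio_gc_over_g < 0) stop("var_ratio_gc_over_g must be >= 0")
  n_conditions <- as.integer(n_conditions)
  n_reps <- as.integer(n_reps)
  if (n_conditions < 1L || n_reps < 1L) {
    stop("n_conditions and n_reps must be >= 1")
  }
  if (is.null(condition_means)) condition_means <- rep(0, n_conditions)
  if (length(condition_means) != n_conditions) {
    stop("condition_means must have one entry per condition")
  }
  structure(
    list(
      n_genotypes = n_genotypes, n_markers = n_markers,
      maf_range = as.numeric(maf_range), mean_depth = mean_depth,
      depth_dispersion = depth_dispersion, n_qtl = n_qtl,
      target_h2 = target_h2, var_ratio_gc_over_g = var_ratio_gc_over_g,
      n_conditions = n_conditions, n_reps = n_reps,
      condition_means = as.numeric(condition_means), seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate an unstructured autotetraploid population
#'
#' Draws, per marker, a major-allele frequency from the configured range and
#' then samples each genotype's allele dosage (copies of the major allele,
#' 0..4) independently from Binomial(4, frequency). The population is
#' panmictic with no subpopulation structure and no linkage disequilibrium,
#' giving a controllable null for downstream association and prediction
#' tests.
#'
#' @param config A [sim_config()].
#' @return An integer matrix (genotypes x markers) of allele dosages with
#'   sample/marker ids in dimnames and the per-marker major-allele
#'   frequencies in attribute `"major_freq"`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genotypes
  p <- config$n_markers
  sample_ids <- sprintf("G%03d", seq_len(n))
  marker_ids <- if (p > 0) sprintf("M%05d", seq_len(p)) else character(0)
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  major_freq <- 1 - maf
  dosage <- matrix(
    rbinom(n * p, size = 4L, prob = rep(major_freq, each = n)),
    nrow = n, ncol = p, dimnames = list(sample_ids, marker_ids)
  )
  storage.mode(dosage) <- "integer"
  attr(dosage, "major_freq") <- setNames(major_freq, marker_ids)
  dosage
}

#' Simulate GBS allele read counts over a dosage matrix
#'
#' Total depth per cell is negative binomial with the given mean and
#' dispersion (Poisson in the infinite-dispersion limit); major-allele reads
#' are Binomial(depth, dosage / 4). Zero-depth cells are allowed and end up
#' missing after genotype calling.
#'
#' @param genos Dosage matrix from [simulate_population()].
#' @param mean_depth Expected depth per cell (> 0).
#' @param depth_dispersion Negative-binomial size; `Inf` for Poisson.
#' @param seed Optional integer seed.
#' @return A list of class `read_counts` with integer matrices `major` and
#'   `minor` (same dimnames as `genos`).
#' @export
simulate_read_counts <- function(genos, mean_depth = 30,
                                 depth_dispersion = Inf, seed = NULL) {
  if (!is.matrix(genos)) stop("genos must be a matrix")
  if (!is.finite(mean_depth) || mean_depth <= 0) {
    stop("mean_depth must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  n_cells <- length(genos)
  depth <- if (is.finite(depth_dispersion)) {
    rnbinom(n_cells, size = depth_dispersion, mu = mean_depth)
  } else {
    rpois(n_cells, lambda = mean_depth)
  }
  major <- rbinom(n_cells, size = depth, prob = as.vector(genos) / 4)
  rc <- list(
    major = matrix(as.integer(major), nrow = nrow(genos),
                   dimnames = dimnames(genos)),
    minor = matrix(as.integer(depth - major), nrow = nrow(genos),
                   dimnames = dimnames(genos))
  )
  class(rc) <- "read_counts"
  rc
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("GBS read counts: %d samples x %d markers, mean depth %.2f\n",
              nrow(x$major), ncol(x$major), mean(x$major + x$minor)))
  invisible(x)
}

#' Simulate replicated multi-condition half-sib phenotypes with known truth
#'
#' The trait follows the classic half-sib decomposition
#' `y_icr = mu_c + g_i + ge_ic + e_icr`: a fixed condition mean, an additive
#' genetic value `g_i` built from the chosen QTL dosages, a
#' genotype-by-condition deviation and a plot error. Variance components are
#' calibrated analytically: the genetic variance implied by the drawn allele
#' frequencies and effects fixes `sigma2_g`, `sigma2_ge` is set from the
#' configured ratio, and `sigma2_e` is solved so the progeny-mean
#' heritability `sigma2_g / (sigma2_g + sigma2_ge/c + sigma2_e/(c k))`
#' equals `target_h2` in expectation.
#'
#' @param genos Dosage matrix from [simulate_population()].
#' @param config A [sim_config()].
#' @param qtl_markers Optional integer or character index of causal markers,
#'   overriding the random choice of `config$n_qtl` markers.
#' @param trait Trait identifier stored in the output table.
#' @return A list with `phenotypes` (long data frame: progeny, condition,
#'   replicate, trait, value) and `truth` (list: `beta`, `breeding_values`,
#'   `qtl`, `var_components`).
#' @export
simulate_phenotypes <- function(genos, config, qtl_markers = NULL,
                                trait = "trait1") {
  stopifnot(inherits(config, "sim_config"), is.matrix(genos))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(genos)
  p <- ncol(genos)
  if (config$n_qtl > p) stop("n_qtl exceeds the number of markers")
  beta <- numeric(p)
  names(beta) <- colnames(genos)
  if (is.null(qtl_markers)) {
    qtl <- if (config$n_qtl == p) seq_len(p) else
      sort(sample.int(p, config$n_qtl))
  } else {
    qtl <- if (is.character(qtl_markers)) {
      match(qtl_markers, colnames(genos))
    } else {
      as.integer(qtl_markers)
    }
    if (anyNA(qtl) || any(qtl < 1L) || any(qtl > p)) {
      stop("qtl_markers must index markers of `genos`")
    }
  }
  beta[qtl] <- rnorm(length(qtl))

  g <- as.vector(genos %*% beta)
  g <- g - mean(g)

  # analytic genetic variance under Binomial(4, f) dosages
  freq <- attr(genos, "major_freq")
  var_g <- if (!is.null(freq)) {
    sum(beta^2 * 4 * freq * (1 - freq))
  } else {
    sum(beta^2 * apply(genos, 2, var))
  }
  if (length(qtl) == 0L || var_g == 0) var_g <- 0

  cc <- config$n_conditions
  k <- config$n_reps
  h2 <- config$target_h2
  rho <- config$var_ratio_gc_over_g
  var_ge <- rho * var_g
  if (h2 == 0) {
    if (var_g > 0) stop("target_h2 = 0 requires n_qtl = 0")
    var_e <- 1
  } else {
    # h2 = vg / (vg + vge/c + ve/(c k))  =>  ve = c k (vg (1/h2 - 1) - vge/c)
    var_e <- cc * k * (var_g * (1 / h2 - 1) - var_ge / cc)
    if (var_e < -1e-12) {
      stop("target_h2 unreachable: interaction variance alone exceeds the ",
           "allowed non-genetic share; lower var_ratio_gc_over_g")
    }
    var_e <- max(var_e, 0)
  }

  progeny <- rownames(genos)
  conditions <- sprintf("C%d", seq_len(cc))
  tab <- expand.grid(
    replicate = sprintf("R%d", seq_len(k)),
    condition = conditions,
    progeny = progeny,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("progeny", "condition", "replicate")]
  ge <- matrix(rnorm(n * cc, sd = sqrt(var_ge)), nrow = n,
               dimnames = list(progeny, conditions))
  idx_p <- match(tab$progeny, progeny)
  idx_c <- match(tab$condition, conditions)
  tab$trait <- trait
  tab$value <- config$condition_means[idx_c] + g[idx_p] +
    ge[cbind(idx_p, idx_c)] + rnorm(nrow(tab), sd = sqrt(var_e))

  list(
    phenotypes = tab,
    truth = list(
      beta = beta,
      breeding_values = setNames(g, progeny),
      qtl = qtl,
      var_components = c(sigma2_g = var_g, sigma2_ge = var_ge,
                         sigma2_e = var_e)
    )
  )
}
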