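#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: stage
#' toggles, per-stage settings and the master seed from which every stage
#' seed is derived deterministically. The configuration can also be
#' loaded from a YAML file (see [read_pipeline_config()]).
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Master seed.
#' @param stages Character vector of enabled stages, in pipeline order.
#' @param sim [sim_config()] for the synthetic-data stage.
#' @param thresholds [calling_thresholds()].
#' @param impute_k Neighbour count for imputation.
#' @param gwas_threshold Association-score significance threshold.
#' @param gs_models Model tags fitted in the genomic-selection stage.
#' @param cv_folds,cv_reps Cross-validation settings.
#' @param sampler [sampler_config()] used by the Bayesian models.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("tetrags_run_"),
                            seed = 1L,
                            stages = c("simulate", "call", "filter",
                                       "impute", "quantstats", "gwas",
                                       "gs", "cv"),
                            sim = sim_config(),
                            thresholds = calling_thresholds(),
                            impute_k = 4L,
                            gwas_threshold = 3.0,
                            gs_models = "rrblup",
                            cv_folds = 10L,
                            cv_reps = 10L,
                            sampler = sampler_config()) {
  known <- c("simulate", "call", "filter", "impute", "quantstats", "gwas",
             "gs", "cv")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         sim = sim, thresholds = thresholds, impute_k = impute_k,
         gwas_threshold = gwas_threshold, gs_models = gs_models,
         cv_folds = cv_folds, cv_reps = cv_reps, sampler = sampler),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Only keys present in the file override [pipeline_config()] defaults;
#' nested keys configure the corresponding stage objects.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("out_dir", "seed", "stages", "impute_k", "gwas_threshold",
                "gs_models", "cv_folds", "cv_reps")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$thresholds)) {
    args$thresholds <- do.call(calling_thresholds, raw$thresholds)
  }
  if (!is.null(raw$sampler)) {
    args$sampler <- do.call(sampler_config, raw$sampler)
  }
  do.call(pipeline_config, args)
}

# deterministic stage seeds below 2^31, derived from the master seed
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11, call = 23, filter = 31, impute = 47,
            quantstats = 59, gwas = 67, gs = 83, cv = 97)
  as.integer((as.numeric(seed) * 2654435 + offs[[stage]]) %% 2147483647)
}

# tiny polynomial rolling hash of the config for artifact provenance
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-to-results pipeline
#'
#' Executes the enabled stages in order — simulate, call, filter, impute,
#' quantstats, gwas, gs, cv — writing every intermediate artifact under
#' `out_dir` and a YAML run manifest recording seeds, the configuration
#' hash, marker/sample counts at each stage, the genomic-control lambda
#' and cross-validation summaries. Re-running the same configuration
#' reproduces identical outputs. When a stage's input is invalid (e.g.
#' GWAS with missing genotypes because imputation was disabled) the
#' pipeline aborts naming the stage.
#'
#' @param config A `pipeline_config` or path to a YAML file.
#' @return Invisibly, a list with the manifest and in-memory artifacts
#'   (`genotypes`, `phenotypes`, `adjusted`, `gwas`, `fits`, `cv`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  on_stage <- function(s) s %in% config$stages
  log_path <- file.path(config$out_dir, "pipeline.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  manifest <- list(config_hash = hash, master_seed = config$seed,
                   stages = config$stages, counts = list())
  art <- list()

  run_stage <- function(stage, expr) {
    logline("stage %s: start", stage)
    tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED (%s)", stage, conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (on_stage("simulate")) {
    run_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- .stage_seed(config$seed, "simulate")
      dosages <- simulate_population(cfg)
      rc <- simulate_read_counts(dosages, cfg$mean_depth,
                                 cfg$depth_dispersion,
                                 seed = cfg$seed + 1L)
      ph <- simulate_phenotypes(dosages, cfg)
      art$dosages <- dosages
      art$read_counts <- rc
      art$phenotypes <- ph$phenotypes
      art$truth <- ph$truth
      write_read_counts(rc, file.path(config$out_dir, "read_counts.tsv"))
      write_phenotypes(ph$phenotypes,
                       file.path(config$out_dir, "phenotypes.csv"))
      write.csv(data.frame(marker = names(ph$truth$beta),
                           beta = ph$truth$beta),
                file.path(config$out_dir, "truth_effects.csv"),
                row.names = FALSE)
      manifest$counts$simulated <-
        list(samples = nrow(dosages), markers = ncol(dosages))
    })
  }

  if (on_stage("call")) {
    run_stage("call", {
      geno <- call_genotypes(art$read_counts, config$thresholds)
      art$genotypes <- geno
      manifest$counts$called <-
        list(markers = ncol(geno),
             missing_fraction = round(mean(is.na(geno)), 4))
    })
  }

  if (on_stage("filter")) {
    run_stage("filter", {
      geno <- suppressMessages(filter_markers_by_callrate(
        art$genotypes, config$thresholds$max_missing_rate
      ))
      manifest$counts$filtered <-
        list(markers = ncol(geno), removed = attr(geno, "n_removed"))
      art$genotypes <- geno
    })
  }

  if (on_stage("impute")) {
    run_stage("impute", {
      art$genotypes <- knn_impute(art$genotypes, k = config$impute_k)
      write_genotypes(art$genotypes,
                      file.path(config$out_dir, "genotypes_imputed.tsv"))
    })
  }

  if (on_stage("quantstats")) {
    run_stage("quantstats", {
      vc <- fit_variance_components(art$phenotypes)
      adj <- progeny_blups(art$phenotypes)
      art$var_components <- vc
      art$adjusted <- adj
      write.csv(data.frame(progeny = names(adj), adjusted = as.numeric(adj)),
                file.path(config$out_dir, "adjusted_phenotypes.csv"),
                row.names = FALSE)
      manifest$h2_broad <- round(heritability_broad(vc), 4)
    })
  }

  if (on_stage("gwas")) {
    run_stage("gwas", {
      if (anyNA(art$genotypes)) {
        stop("genotype matrix still contains missing codes; ",
             "enable the impute stage first")
      }
      res <- gwas_scan(art$genotypes, art$adjusted,
                       threshold = config$gwas_threshold)
      art$gwas <- res
      write.table(res, file.path(config$out_dir, "gwas_records.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$gwas <- list(lambda = round(attr(res, "lambda"), 4),
                             n_significant = sum(res$significant,
                                                 na.rm = TRUE))
    })
  }

  if (on_stage("gs")) {
    run_stage("gs", {
      if (anyNA(art$genotypes)) {
        stop("genotype matrix still contains missing codes; ",
             "enable the impute stage first")
      }
      set.seed(.stage_seed(config$seed, "gs"))
      fits <- lapply(config$gs_models, function(tag) {
        mdl <- gs_model(tag, cfg = config$sampler)
        fit <- mdl$fit(art$genotypes, art$adjusted)
        write_gs_fit(fit, file.path(config$out_dir,
                                    paste0("fit_", tag, ".json")))
        fit
      })
      names(fits) <- config$gs_models
      art$fits <- fits
      manifest$gs <- lapply(fits, function(f) {
        list(model = f$model,
             lambda = if (!is.null(f$lambda)) round(f$lambda, 4))
      })
    })
  }

  if (on_stage("cv")) {
    run_stage("cv", {
      cvs <- lapply(config$gs_models, function(tag) {
        cv <- kfold_accuracy(gs_model(tag, cfg = config$sampler),
                             art$genotypes, art$adjusted,
                             n_folds = config$cv_folds,
                             n_reps = config$cv_reps,
                             seed = .stage_seed(config$seed, "cv"))
        write_cv_result(cv, file.path(config$out_dir,
                                      paste0("cv_", tag, ".csv")))
        cv
      })
      names(cvs) <- config$gs_models
      art$cv <- cvs
      manifest$cv <- lapply(cvs, function(x) {
        list(mean_accuracy = round(x$mean, 4), sd = round(x$sd, 4))
      })
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  logline("pipeline complete; manifest at %s", manifest_path)
  invisible(c(list(manifest = manifest), art))
}
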