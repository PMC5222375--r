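# shared fixtures built in code

# complete diploid-coded genotype matrix (no read-depth noise)
make_geno <- function(n, p, maf = c(0.1, 0.4), seed = NULL) {
  cfg <- sim_config(n_genotypes = n, n_markers = p, maf_range = maf,
                    seed = seed)
  collapse_tetraploid(simulate_population(cfg))
}

# balanced long phenotype table from explicit component draws
balanced_pheno <- function(g, ge, sd_e, trait = "t", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_p <- length(g)
  cc <- ncol(ge)
  k <- attr(ge, "k") %||% 3L
  progeny <- sprintf("P%03d", seq_len(n_p))
  tab <- expand.grid(
    replicate = sprintf("R%d", seq_len(k)),
    condition = sprintf("C%d", seq_len(cc)),
    progeny = progeny,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, 3:1]
  ip <- match(tab$progeny, progeny)
  ic <- as.integer(sub("C", "", tab$condition))
  tab$trait <- trait
  tab$value <- g[ip] + ge[cbind(ip, ic)] + rnorm(nrow(tab), 0, sd_e)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
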