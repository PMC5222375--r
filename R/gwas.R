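#' Single-marker association scan
#'
#' Regresses the phenotype on each marker's `{0, 1, 2}` code separately
#' (no missing genotypes allowed; run after imputation). The squared
#' t-statistic of the slope is converted to a 1-df chi-square statistic —
#' exactly, through the F(1, n-2) tail quantile map, so the statistics are
#' chi-square(1) under the null at any sample size — the natural input for
#' genomic control. Monomorphic markers are flagged and excluded from
#' p-value computation.
#'
#' @param g Complete genotype matrix (samples x markers, codes 0/1/2).
#' @param y Phenotype vector aligned to the rows of `g`; if both are
#'   named, names must match.
#' @return Data frame with one row per marker: `marker`, `effect` (trait
#'   units per code unit), `statistic` (1-df chi-square), `p` (raw),
#'   `r2`, `monomorphic`.
#' @export
marker_scan <- function(g, y) {
  stopifnot(is.matrix(g))
  if (anyNA(g)) stop("genotype matrix contains missing codes; impute first")
  y <- .align_phenotype(g, y)
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 samples")
  yc <- y - mean(y)
  gc <- scale(g, center = TRUE, scale = FALSE)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  syy <- sum(yc^2)
  mono <- sxx == 0
  effect <- ifelse(mono, NA_real_, sxy / sxx)
  ssr <- ifelse(mono, NA_real_, effect * sxy)
  sse <- syy - ssr
  t2 <- ifelse(mono | sse <= 0, ifelse(mono, NA_real_, Inf),
               ssr * (n - 2) / sse)
  # exact conversion of the squared t to a 1-df chi-square: map through
  # the F(1, n-2) tail so the statistic is chi-square(1) under the null
  # at any sample size (the asymptotic t^2 = chi^2 identity made exact)
  p <- pmax(stats::pf(t2, 1, n - 2, lower.tail = FALSE), 1e-300)
  stat <- ifelse(is.na(t2), NA_real_, qchisq(p, df = 1, lower.tail = FALSE))
  r2 <- ifelse(mono | syy == 0, NA_real_, ssr / syy)
  data.frame(
    marker = colnames(g) %||% paste0("m", seq_len(ncol(g))),
    effect = effect, statistic = stat, p = p, r2 = r2,
    monomorphic = mono, row.names = NULL
  )
}

.align_phenotype <- function(g, y) {
  if (!is.null(names(y)) && !is.null(rownames(g))) {
    if (!all(rownames(g) %in% names(y))) {
      stop("phenotype is missing samples present in the genotype matrix")
    }
    y <- y[rownames(g)]
  } else if (length(y) != nrow(g)) {
    stop("phenotype length does not match the number of samples")
  }
  as.numeric(y)
}

#' Genomic-control adjustment of association statistics
#'
#' Estimates the inflation factor `lambda` as the ratio of the median
#' observed 1-df chi-square statistic to the null median (0.4549), floored
#' at 1 so that deflated scans are never made more significant, and divides
#' all statistics by it. Rank order of p-values is preserved.
#'
#' @param statistics Vector of 1-df chi-square statistics (`NA` allowed
#'   for monomorphic markers).
#' @param min_markers Minimum number of statistics for a stable median.
#' @return List with `lambda`, `adjusted_statistic` and `adjusted_p`.
#' @export
genomic_control <- function(statistics, min_markers = 50L) {
  ok <- is.finite(statistics)
  if (!any(ok)) stop("no finite association statistics")
  if (sum(ok) < min_markers) {
    warning("fewer than ", min_markers,
            " markers: genomic-control lambda may be unstable")
  }
  lambda <- max(median(statistics[ok]) / qchisq(0.5, df = 1), 1)
  adj <- statistics / lambda
  list(
    lambda = lambda,
    adjusted_statistic = adj,
    adjusted_p = pchisq(adj, df = 1, lower.tail = FALSE)
  )
}

#' Association score
#'
#' `-log10(p)`, with the conventional significance flag at a score of 3.0
#' (p < 0.001).
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param threshold Significance threshold on the score scale.
#' @return Numeric score(s) with logical attribute `"significant"`.
#' @export
#' @examples
#' association_score(0.001) # 3, significant
association_score <- function(p, threshold = 3.0) {
  if (any(p <= 0, na.rm = TRUE) || any(p > 1, na.rm = TRUE)) {
    stop("p-values must be in (0, 1]")
  }
  score <- -log10(p)
  attr(score, "significant") <- score >= threshold
  score
}

#' Per-marker coefficient of determination
#'
#' Squared Pearson correlation between a marker's codes and the phenotype.
#'
#' @param codes Genotype codes of one (polymorphic) marker.
#' @param y Phenotype vector.
#' @return R-squared in `[0, 1]`.
#' @export
marker_r2 <- function(codes, y) {
  if (sd(codes) == 0 || sd(y) == 0) stop("constant input: r2 undefined")
  cor(codes, y)^2
}

#' Classify a marker position relative to annotated genes
#'
#' Assigns each marker one of four gene contexts: `C` (within an exon),
#' `I` (within the gene span but not in an exon, i.e. intronic), `F`
#' (outside the gene span but strictly closer than `flank_bp` to it) or
#' `0` (intergenic). For `C`/`I`/`F` the nearest gene is reported; when a
#' marker falls in the flanking window of several genes the one with the
#' nearest span boundary wins, exact ties going to the lexicographically
#' smaller gene id. All coordinates are 1-based inclusive and
#' strand-agnostic.
#'
#' @param positions Data frame with columns `marker`, `chrom`, `pos`
#'   (1-based bp); `NA` positions (unaligned markers) come back as
#'   context `0` with no gene.
#' @param annotation A `gene_annotation` object from
#'   [read_gene_annotation()] or [gene_annotation()].
#' @param flank_bp Flanking-window width (strict `<` comparison).
#' @return `positions` with added columns `context` (factor C/I/F/0) and
#'   `gene`.
#' @export
annotate_gene_context <- function(positions, annotation, flank_bp = 3000) {
  stopifnot(inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  exons <- annotation$exons
  context <- rep("0", nrow(positions))
  gene_hit <- rep(NA_character_, nrow(positions))
  for (i in seq_len(nrow(positions))) {
    pos <- positions$pos[i]
    chrom <- positions$chrom[i]
    if (is.na(pos) || is.na(chrom)) next
    cand <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0L) next
    inside <- cand$start <= pos & pos <= cand$end
    if (any(inside)) {
      hit <- cand[inside, , drop = FALSE]
      hit <- hit[order(hit$gene_id), , drop = FALSE][1L, ]
      ex <- exons[exons$gene_id == hit$gene_id, , drop = FALSE]
      in_exon <- nrow(ex) > 0L && any(ex$start <= pos & pos <= ex$end)
      context[i] <- if (in_exon) "C" else "I"
      gene_hit[i] <- hit$gene_id
    } else {
      dist <- pmax(cand$start - pos, pos - cand$end)
      near <- dist < flank_bp
      if (any(near)) {
        sel <- which(near)
        sel <- sel[order(dist[sel], cand$gene_id[sel])][1L]
        context[i] <- "F"
        gene_hit[i] <- cand$gene_id[sel]
      }
    }
  }
  positions$context <- factor(context, levels = c("C", "I", "F", "0"))
  positions$gene <- gene_hit
  positions
}

#' Build a gene annotation object
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   every exon must lie within its gene span.
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons) {
  need <- c("gene_id", "chrom", "start", "end")
  stopifnot(all(need %in% names(genes)), all(need %in% names(exons)))
  if (any(genes$start > genes$end) || any(exons$start > exons$end)) {
    stop("malformed annotation: span start exceeds end")
  }
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (anyNA(span$gene_id) ||
      any(exons$start < span$start | exons$end > span$end)) {
    stop("malformed annotation: exon outside its gene span")
  }
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' Read gene and exon features from a GFF3 file
#'
#' Uses \pkg{rtracklayer} to import the file and extracts `gene` and
#' `exon` features; exons are attached to genes either directly through
#' their `Parent` attribute or via an intermediate mRNA feature.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation` object.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package rtracklayer is required to read GFF3 annotation")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  id_of <- function(x) vapply(x, function(v) v[1L] %||% NA_character_,
                              character(1))
  is_gene <- df$type == "gene"
  genes <- data.frame(
    gene_id = as.character(df$ID[is_gene]),
    chrom = as.character(df$seqnames[is_gene]),
    start = df$start[is_gene], end = df$end[is_gene],
    stringsAsFactors = FALSE
  )
  parent <- id_of(as.list(df$Parent))
  # map mRNA ids to their parent gene
  is_rna <- df$type %in% c("mRNA", "transcript")
  rna2gene <- setNames(parent[is_rna], as.character(df$ID[is_rna]))
  is_exon <- df$type == "exon"
  exon_parent <- parent[is_exon]
  exon_gene <- ifelse(exon_parent %in% names(rna2gene),
                      rna2gene[exon_parent], exon_parent)
  exons <- data.frame(
    gene_id = as.character(exon_gene),
    chrom = as.character(df$seqnames[is_exon]),
    start = df$start[is_exon], end = df$end[is_exon],
    stringsAsFactors = FALSE
  )
  gene_annotation(genes, exons)
}

#' Order GWAS records for a Manhattan plot
#'
#' Sorts records by chromosome then position; markers without an alignment
#' (missing chromosome/position) are collected on a pseudo-chromosome
#' placed after all real ones, ordered by their original marker index —
#' the "fictitious chromosome" convention for unaligned GBS tags.
#'
#' @param records Data frame with at least `marker`, `chrom`, `pos`.
#' @param pseudo_chrom Label for the pseudo-chromosome (default "9").
#' @param threshold Significance threshold recorded in attribute
#'   `"threshold"`.
#' @return The sorted data frame with `chrom` filled in for unaligned
#'   markers and a `plot_index` column.
#' @export
manhattan_table <- function(records, pseudo_chrom = "9", threshold = 3.0) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(records)))
  unaligned <- is.na(records$chrom) | is.na(records$pos)
  records$chrom <- as.character(records$chrom)
  records$chrom[unaligned] <- pseudo_chrom
  aligned <- records[!unaligned, , drop = FALSE]
  aligned <- aligned[order(aligned$chrom, aligned$pos,
                           seq_len(nrow(aligned))), , drop = FALSE]
  out <- rbind(aligned, records[unaligned, , drop = FALSE])
  out$plot_index <- seq_len(nrow(out))
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' Marker alignment bookkeeping
#'
#' Summarizes how many markers aligned to the reference genome and the
#' share they represent; unaligned markers go to the pseudo-chromosome.
#'
#' @param n_markers Total retained polymorphic markers.
#' @param n_aligned Markers aligned to the reference genome.
#' @return List with `pct_aligned` (percent, 1 decimal), `n_unaligned`.
#' @export
#' @examples
#' marker_alignment_stats(11450, 8494) # 74.2% aligned, 2956 unaligned
marker_alignment_stats <- function(n_markers, n_aligned) {
  if (n_aligned > n_markers) stop("n_aligned exceeds n_markers")
  list(
    pct_aligned = round(100 * n_aligned / n_markers, 1),
    n_unaligned = as.integer(n_markers - n_aligned)
  )
}

#' Mean sequencing reads per sample
#'
#' @param total_reads Total reads in the run.
#' @param n_samples Number of samples.
#' @return Mean reads per sample, rounded to the nearest read.
#' @export
reads_per_sample <- function(total_reads, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  round(total_reads / n_samples)
}

#' Full GWAS: scan, genomic control, scores and annotation
#'
#' Convenience wrapper chaining [marker_scan()], [genomic_control()],
#' [association_score()] and optionally [annotate_gene_context()] and
#' [manhattan_table()].
#'
#' @inheritParams marker_scan
#' @param positions Optional data frame (`marker`, `chrom`, `pos`) of
#'   marker alignments; markers absent from it are treated as unaligned.
#' @param annotation Optional `gene_annotation` for gene context.
#' @param flank_bp Flanking window for gene context.
#' @param threshold Association-score significance threshold.
#' @return Data frame of GWAS records (one per marker) ordered for
#'   plotting, with attributes `"lambda"` and `"threshold"`.
#' @export
gwas_scan <- function(g, y, positions = NULL, annotation = NULL,
                      flank_bp = 3000, threshold = 3.0) {
  scan <- marker_scan(g, y)
  gc <- genomic_control(scan$statistic)
  scan$p_adjusted <- gc$adjusted_p
  scan$score <- ifelse(is.na(scan$p_adjusted), NA_real_,
                       -log10(scan$p_adjusted))
  scan$significant <- !is.na(scan$score) & scan$score >= threshold
  if (is.null(positions)) {
    scan$chrom <- NA_character_
    scan$pos <- NA_real_
  } else {
    idx <- match(scan$marker, positions$marker)
    scan$chrom <- positions$chrom[idx]
    scan$pos <- positions$pos[idx]
  }
  if (!is.null(annotation)) {
    scan <- annotate_gene_context(scan, annotation, flank_bp = flank_bp)
  }
  out <- manhattan_table(scan, threshold = threshold)
  attr(out, "lambda") <- gc$lambda
  out
}
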