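test_that("a constructed causal marker attains the top statistic", {
  g <- make_geno(80, 50, seed = 1)
  set.seed(2)
  y <- g[, 17] * 2 + rnorm(80, sd = 0.3)
  scan <- marker_scan(g, y)
  expect_identical(which.max(scan$statistic), 17L)
  expect_gt(scan$effect[17], 1.5)
})

test_that("monomorphic markers are flagged and excluded from p-values", {
  g <- make_geno(40, 10, seed = 3)
  g[, 4] <- 1L
  scan <- marker_scan(g, rnorm(40))
  expect_true(scan$monomorphic[4])
  expect_true(is.na(scan$p[4]))
  expect_true(is.na(scan$effect[4]))
  expect_false(any(scan$monomorphic[-4]))
})

test_that("raw p-values are uniform under permuted phenotypes", {
  g <- make_geno(80, 100, seed = 4)
  set.seed(5)
  y <- rnorm(80)
  p <- unlist(lapply(1:50, function(i) marker_scan(g, sample(y))$p))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("sample alignment is enforced", {
  g <- make_geno(20, 5, seed = 6)
  expect_error(marker_scan(g, rnorm(19)), "length")
  y <- setNames(rnorm(20), paste0("X", 1:20))
  expect_error(marker_scan(g, y), "missing samples")
})

test_that("genomic control scales by the chi-square median and floors at 1", {
  null_median <- qchisq(0.5, 1)
  stats <- c(0.1, 0.3, null_median, 1.2, 5) # median exactly at the null
  gc <- genomic_control(stats, min_markers = 1)
  expect_equal(gc$lambda, 1)
  expect_equal(gc$adjusted_statistic, stats)
  # doubling all statistics doubles lambda and restores adjusted values
  gc2 <- genomic_control(stats * 2, min_markers = 1)
  expect_equal(gc2$lambda, 2, tolerance = 1e-12)
  expect_equal(gc2$adjusted_statistic, stats, tolerance = 1e-12)
  # deflation never inflates significance
  gc3 <- genomic_control(stats / 2, min_markers = 1)
  expect_equal(gc3$lambda, 1)
  expect_equal(gc3$adjusted_statistic, stats / 2)
  expect_error(genomic_control(rep(NA_real_, 10)), "no finite")
})

test_that("genomic control preserves the p-value rank order", {
  set.seed(7)
  stats <- rchisq(500, 1) * 1.4
  gc <- genomic_control(stats)
  expect_gt(gc$lambda, 1)
  expect_identical(order(pchisq(stats, 1, lower.tail = FALSE)),
                   order(gc$adjusted_p))
})

test_that("association scores are -log10 p with a threshold flag", {
  s <- association_score(0.001)
  expect_equal(as.numeric(s), 3)
  expect_true(attr(s, "significant"))
  expect_equal(as.numeric(association_score(1)), 0)
  expect_equal(as.numeric(association_score(0.05)), 1.30103,
               tolerance = 1e-5)
  expect_false(attr(association_score(0.0011), "significant"))
  expect_error(association_score(0), "\\(0, 1\\]")
})

test_that("marker r2 is the squared code-phenotype correlation", {
  g <- make_geno(154, 1, seed = 8)
  codes <- g[, 1]
  expect_equal(marker_r2(codes, codes), 1)
  expect_error(marker_r2(rep(1, 10), rnorm(10)), "constant")
  # independent phenotype: r2 rarely exceeds 0.05
  set.seed(9)
  null_r2 <- replicate(40, marker_r2(codes, rnorm(154)))
  expect_gte(mean(null_r2 < 0.05), 0.9)
  # noise tuned to a population correlation of 0.45 -> r2 ~ 0.2
  sims <- replicate(60, {
    noise_sd <- sd(codes) * sqrt(1 / 0.45^2 - 1)
    marker_r2(codes, codes + rnorm(154, sd = noise_sd))
  })
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - 0.2025), 3 * se + 0.01)
})

test_that("gene context partitions into C/I/F/0 with strict boundaries", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("1", "1"),
    start = c(1000L, 20000L), end = c(5000L, 24000L)
  )
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"), chrom = "1",
    start = c(1000L, 3000L, 20000L), end = c(1500L, 3500L, 24000L)
  )
  ann <- gene_annotation(genes, exons)
  pos <- data.frame(
    marker = paste0("m", 1:6), chrom = "1",
    pos = c(1200L,   # exon of gA -> C
            2000L,   # inside gA, not exon -> I
            7999L,   # 2999 bp downstream of gA end -> F
            8000L,   # exactly 3000 bp -> 0
            10000L,  # 5000 bp from both genes -> 0
            17500L)  # 2500 bp upstream of gB -> F
  )
  out <- annotate_gene_context(pos, ann, flank_bp = 3000)
  expect_equal(as.character(out$context),
               c("C", "I", "F", "0", "0", "F"))
  expect_equal(out$gene, c("gA", "gA", "gA", NA, NA, "gB"))
  # exhaustive and mutually exclusive by construction of the factor
  expect_false(anyNA(out$context))
})

test_that("flanking ambiguity resolves to the nearest gene, ties to lower id", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "2",
    start = c(100L, 3000L), end = c(1000L, 4000L)
  )
  ann <- gene_annotation(genes, genes[0, ])
  near_b <- annotate_gene_context(
    data.frame(marker = "m", chrom = "2", pos = 2500L), ann
  )
  expect_equal(near_b$gene, "gB") # 500 bp to gB vs 1500 to gA
  tie <- annotate_gene_context(
    data.frame(marker = "m", chrom = "2", pos = 2000L), ann
  )
  expect_equal(tie$gene, "gA") # 1000 bp to both: lower gene id
  expect_error(
    gene_annotation(data.frame(gene_id = "g", chrom = "1", start = 10L,
                               end = 5L), genes[0, ]),
    "malformed"
  )
})

test_that("GFF3 annotation round-trips through rtracklayer", {
  skip_if_not_installed("rtracklayer")
  gff <- file.path(tempdir(), "mini.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t5000\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t1000\t5000\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr1\ttest\texon\t1000\t1500\t.\t+\t.\tID=ex1;Parent=rna1",
    "chr1\ttest\texon\t4000\t5000\t.\t+\t.\tID=ex2;Parent=rna1",
    "chr1\ttest\tgene\t9000\t9500\t.\t-\t.\tID=gene2",
    "chr1\ttest\texon\t9000\t9200\t.\t-\t.\tID=ex3;Parent=gene2"
  ), gff)
  ann <- read_gene_annotation(gff)
  expect_setequal(ann$genes$gene_id, c("gene1", "gene2"))
  expect_identical(nrow(ann$exons), 3L)
  expect_setequal(ann$exons$gene_id, c("gene1", "gene2"))
  out <- annotate_gene_context(
    data.frame(marker = c("a", "b", "c"), chrom = "chr1",
               pos = c(1100L, 2000L, 9100L)), ann
  )
  expect_equal(as.character(out$context), c("C", "I", "C"))
})

test_that("manhattan tables sort aligned markers and append the pseudo-chromosome", {
  rec <- data.frame(
    marker = paste0("m", 1:7),
    chrom = c("2", NA, "1", "8", NA, "1", "3"),
    pos = c(50, NA, 900, 10, NA, 20, 5)
  )
  out <- manhattan_table(rec)
  # oracle ordering of the aligned block
  aligned <- rec[!is.na(rec$chrom), ]
  oracle <- aligned[order(aligned$chrom, aligned$pos), "marker"]
  expect_equal(out$marker, c(oracle, c("m2", "m5")))
  expect_equal(out$chrom[6:7], c("9", "9"))
  expect_equal(attr(out, "threshold"), 3.0)
  all_aligned <- manhattan_table(rec[!is.na(rec$chrom), ])
  expect_false("9" %in% all_aligned$chrom)
})

test_that("the full scan wrapper ties the pieces together", {
  g <- make_geno(60, 120, seed = 10)
  set.seed(11)
  y <- g[, 5] + rnorm(60, sd = 0.5)
  pos <- data.frame(marker = colnames(g)[1:100],
                    chrom = rep(c("1", "2"), 50),
                    pos = seq_len(100) * 1000)
  res <- gwas_scan(g, y, positions = pos)
  expect_true(is.numeric(attr(res, "lambda")))
  expect_gte(attr(res, "lambda"), 1)
  expect_true(all(res$chrom[101:120] == "9"))
  expect_identical(res$marker[which.max(res$score)], colnames(g)[5])
})
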