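#' Read and write allele read-count tables
#'
#' Read counts travel as long-format TSV with columns `sample`, `marker`,
#' `major_reads`, `minor_reads`.
#'
#' @param rc A `read_counts` object.
#' @param path File path.
#' @return `read_read_counts` returns a `read_counts` object;
#'   the writer returns `path` invisibly.
#' @export
write_read_counts <- function(rc, path) {
  stopifnot(inherits(rc, "read_counts"))
  df <- data.frame(
    sample = rep(rownames(rc$major), times = ncol(rc$major)),
    marker = rep(colnames(rc$major), each = nrow(rc$major)),
    major_reads = as.vector(rc$major),
    minor_reads = as.vector(rc$minor)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "marker", "major_reads", "minor_reads")
  if (!all(need %in% names(df))) {
    stop("read-count TSV needs columns: ", paste(need, collapse = ", "))
  }
  samples <- unique(df$sample)
  markers <- unique(df$marker)
  shape <- list(samples, markers)
  idx <- cbind(match(df$sample, samples), match(df$marker, markers))
  major <- matrix(NA_integer_, length(samples), length(markers),
                  dimnames = shape)
  minor <- major
  major[idx] <- as.integer(df$major_reads)
  minor[idx] <- as.integer(df$minor_reads)
  structure(list(major = major, minor = minor), class = "read_counts")
}

#' Read and write diploid-coded genotype matrices as TSV
#'
#' Wide format: one row per sample, first column `sample`, one column per
#' marker, codes `{0, 1, 2}` with `NA` for missing.
#'
#' @param m Genotype matrix.
#' @param path File path.
#' @return `read_genotypes` returns the integer matrix; the writer
#'   returns `path` invisibly.
#' @export
write_genotypes <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(sample = rownames(m) %||% paste0("S", seq_len(nrow(m))),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Read and write long-format phenotype tables as CSV
#'
#' Columns: `progeny`, `condition`, `replicate`, `trait`, `value`.
#'
#' @param pheno Phenotype data frame.
#' @param path File path.
#' @return `read_phenotypes` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_pheno(df, trait = unique(df$trait)[1L])
  df
}

#' Write genotypes (and optional read counts) as VCF
#'
#' Encodes the major allele as REF and the minor as ALT, so diploid codes
#' map to genotypes as `2 -> 0/0`, `1 -> 0/1`, `0 -> 1/1` and missing to
#' `./.`. When a matching `read_counts` object is supplied, per-cell
#' allele depths are emitted in the `AD` FORMAT field. Synthetic markers
#' without coordinates are placed on contig `chrUn` at their column index.
#'
#' @param m Genotype matrix (samples x markers).
#' @param path Output VCF path.
#' @param read_counts Optional `read_counts` with identical dimensions.
#' @param chrom,pos Optional per-marker coordinates.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(m, path, read_counts = NULL, chrom = NULL,
                               pos = NULL) {
  stopifnot(is.matrix(m))
  n <- nrow(m)
  p <- ncol(m)
  if (is.null(chrom)) chrom <- rep("chrUn", p)
  if (is.null(pos)) pos <- seq_len(p)
  samples <- rownames(m) %||% paste0("S", seq_len(n))
  markers <- colnames(m) %||% paste0("M", seq_len(p))
  gt <- matrix("./.", n, p)
  gt[!is.na(m) & m == 2L] <- "0/0"
  gt[!is.na(m) & m == 1L] <- "0/1"
  gt[!is.na(m) & m == 0L] <- "1/1"
  fmt <- "GT"
  if (!is.null(read_counts)) {
    stopifnot(inherits(read_counts, "read_counts"),
              all(dim(read_counts$major) == dim(m)))
    gt <- matrix(paste0(gt, ":", read_counts$major, ",",
                        read_counts$minor), n, p)
    fmt <- "GT:AD"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrags",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(read_counts)) {
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
             "\"Allele read depths (major,minor)\">")
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(p), function(j) {
    paste(c(chrom[j], pos[j], markers[j], "A", "C", ".", "PASS", ".", fmt,
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix (and allele depths) from a VCF
#'
#' Uses \pkg{vcfR}. Genotypes are recoded onto the major-allele scale
#' (`0/0 -> 2`, `0/1 -> 1`, `1/1 -> 0`, `./. -> NA`); if an `AD` FORMAT
#' field is present the allele depths are returned as a `read_counts`
#' object in attribute `"read_counts"`.
#'
#' @param path VCF file path.
#' @return Integer genotype matrix (samples x markers).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package vcfR is required to read VCF")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 2L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 0L
  m <- t(code) # samples x markers
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    field <- function(x, i) {
      out <- rep(NA_integer_, length(x))
      ok <- !is.na(x)
      out[ok] <- as.integer(vapply(strsplit(x[ok], ","),
                                   `[`, character(1), i))
      out
    }
    major <- t(matrix(field(as.vector(ad), 1L), nrow(ad), ncol(ad)))
    minor <- t(matrix(field(as.vector(ad), 2L), nrow(ad), ncol(ad)))
    dimnames(major) <- dimnames(minor) <- dimnames(m)
    attr(m, "read_counts") <-
      structure(list(major = major, minor = minor), class = "read_counts")
  }
  m
}
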