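#' Depth thresholds for genotype calling
#'
#' Defaults follow the conservative GBS filtering scheme for
#' autotetraploids: heterozygous calls need a total depth of at least 4
#' reads, homozygous calls at least 11 reads (which caps the probability of
#' mistaking a simplex heterozygote for a homozygote at about 4.22%, see
#' [miscall_probability()]), and markers missing in more than 30% of
#' samples are dropped.
#'
#' @param het_min_depth Minimum total depth to call a heterozygote.
#' @param hom_min_depth Minimum total depth to call a homozygote.
#' @param max_missing_rate Maximum tolerated per-marker missing fraction.
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(het_min_depth = 4L, hom_min_depth = 11L,
                               max_missing_rate = 0.30) {
  het_min_depth <- as.integer(het_min_depth)
  hom_min_depth <- as.integer(hom_min_depth)
  if (het_min_depth < 1L || hom_min_depth < 1L) {
    stop("depth thresholds must be >= 1")
  }
  if (max_missing_rate < 0 || max_missing_rate > 1) {
    stop("max_missing_rate must be in [0, 1]")
  }
  structure(
    list(het_min_depth = het_min_depth, hom_min_depth = hom_min_depth,
         max_missing_rate = max_missing_rate),
    class = "calling_thresholds"
  )
}

#' Call a diploid-coded genotype from allele read counts
#'
#' Cell-local calling rule: if both alleles are observed the cell is a
#' heterozygote (code 1) provided total depth reaches `het_min_depth`;
#' if only one allele is observed the cell is a homozygote (2 for the
#' major allele, 0 for the minor) provided total depth reaches
#' `hom_min_depth`; anything below threshold, and zero-depth cells, are
#' missing (`NA`).
#'
#' @param major_reads,minor_reads Non-negative integer vectors of reads
#'   supporting the major and minor allele (recycled to common length).
#' @param thresholds A [calling_thresholds()].
#' @return Integer vector of codes in `{0, 1, 2, NA}`.
#' @export
#' @examples
#' call_genotype(c(6, 10, 11, 0), c(3, 0, 0, 0), calling_thresholds())
call_genotype <- function(major_reads, minor_reads,
                          thresholds = calling_thresholds()) {
  if (any(major_reads < 0, na.rm = TRUE) ||
      any(minor_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  depth <- major_reads + minor_reads
  both <- major_reads > 0 & minor_reads > 0
  code <- rep(NA_integer_, length(depth))
  code[both & depth >= thresholds$het_min_depth] <- 1L
  hom_ok <- !both & depth >= thresholds$hom_min_depth
  code[hom_ok & major_reads > 0] <- 2L
  code[hom_ok & minor_reads > 0] <- 0L
  code
}

#' Call a full genotype matrix from read counts
#'
#' Applies [call_genotype()] to every cell of a `read_counts` object.
#'
#' @param rc A `read_counts` object (matrices `major`, `minor`).
#' @param thresholds A [calling_thresholds()].
#' @return Integer matrix (samples x markers) of codes in `{0, 1, 2, NA}`.
#' @export
call_genotypes <- function(rc, thresholds = calling_thresholds()) {
  stopifnot(inherits(rc, "read_counts"))
  codes <- call_genotype(as.vector(rc$major), as.vector(rc$minor),
                         thresholds)
  matrix(codes, nrow = nrow(rc$major), dimnames = dimnames(rc$major))
}

#' Collapse a tetraploid allele dosage to a diploid code
#'
#' The two tetraploid homozygotes (dosage 0 = aaaa, 4 = AAAA) map to the
#' diploid homozygote codes 0 and 2; the three heterozygote classes
#' (Aaaa, AAaa, AAAa; dosage 1, 2, 3) all map to the diploid heterozygote
#' code 1.
#'
#' @param dosage Integer vector of major-allele dosages in `0..4`
#'   (`NA` passes through).
#' @return Integer vector of codes in `{0, 1, 2}`.
#' @export
#' @examples
#' collapse_tetraploid(0:4)
collapse_tetraploid <- function(dosage) {
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 4 & dosage == round(dosage))
  if (!all(ok)) stop("dosage must be in 0..4")
  code <- rep(NA_integer_, length(dosage))
  code[!is.na(dosage)] <- 1L
  code[!is.na(dosage) & dosage == 0] <- 0L
  code[!is.na(dosage) & dosage == 4] <- 2L
  if (is.matrix(dosage)) {
    code <- matrix(code, nrow = nrow(dosage), dimnames = dimnames(dosage))
  }
  code
}

#' Probability that a heterozygote yields reads of only one allele
#'
#' For a locus whose reads carry the majority allele with probability `p`
#' (e.g. 3/4 for a simplex tetraploid heterozygote AAAa), the probability
#' that all `depth` independent reads show a single allele — and the site
#' is therefore miscalled homozygous — is `p^depth + (1 - p)^depth`. At the
#' default homozygous-call threshold of 11 reads and `p = 0.75` this is
#' 0.0422 (4.22%), dominated by the majority term.
#'
#' @param majority_fraction Per-read probability of the majority allele,
#'   strictly between 0 and 1.
#' @param depth Read depth (>= 1).
#' @return Probability in `(0, 1]`; strictly decreasing in `depth`.
#' @export
#' @examples
#' miscall_probability(0.75, 11) # ~0.0422
miscall_probability <- function(majority_fraction, depth) {
  if (any(majority_fraction <= 0) || any(majority_fraction >= 1)) {
    stop("majority_fraction must be strictly between 0 and 1")
  }
  if (any(depth < 1) || any(depth != round(depth))) {
    stop("depth must be a positive integer")
  }
  majority_fraction^depth + (1 - majority_fraction)^depth
}

#' Filter markers by call rate
#'
#' Drops every marker whose missing fraction across samples exceeds
#' `max_missing_rate` (strictly greater; a marker missing exactly at the
#' threshold is kept, i.e. markers need a call rate of at least
#' `1 - max_missing_rate`). Retained genotype values are untouched.
#'
#' @param m Diploid-coded genotype matrix (samples x markers, `NA` missing).
#' @param max_missing_rate Maximum tolerated missing fraction.
#' @return The filtered matrix, with attributes `n_removed` and
#'   `missing_rate` (per retained marker).
#' @export
filter_markers_by_callrate <- function(m, max_missing_rate = 0.30) {
  stopifnot(is.matrix(m))
  if (ncol(m) == 0L || nrow(m) == 0L) {
    warning("empty genotype matrix; nothing to filter")
    attr(m, "n_removed") <- 0L
    return(m)
  }
  miss <- colMeans(is.na(m))
  keep <- miss <= max_missing_rate
  out <- m[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "missing_rate") <- miss[keep]
  message(sprintf("filter_markers_by_callrate: removed %d of %d markers ",
                  sum(!keep), ncol(m)),
          sprintf("(missing rate > %.2f)", max_missing_rate))
  out
}
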