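#' K-nearest-neighbour imputation of missing genotype codes
#'
#' Fills every missing cell of a diploid-coded genotype matrix from its
#' nearest samples. The distance between two samples is the mean mismatch
#' over their co-observed markers (pairs with no co-observed marker are
#' infinitely distant). For a missing cell, the `k` nearest samples with an
#' observed code at that marker vote; the imputed value is their modal
#' code, with mode ties resolved to the value of the single nearest
#' neighbour. Neighbour ties at equal distance are broken by ascending
#' sample index, making the procedure fully deterministic and
#' permutation-equivariant.
#'
#' @param m Genotype matrix (samples x markers), codes `{0, 1, 2}` with
#'   `NA` for missing.
#' @param k Number of neighbours (default 4).
#' @param min_shared_markers Minimum number of co-observed markers for a
#'   sample pair to count as comparable; every sample must be comparable
#'   with at least `k` others.
#' @return The matrix with all `NA` cells imputed; observed cells are
#'   returned unchanged.
#' @export
knn_impute <- function(m, k = 4L, min_shared_markers = 1L) {
  stopifnot(is.matrix(m))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(m)
  if (!anyNA(m)) return(m)
  if (n <= k) stop("need more than k samples to impute")

  obs <- !is.na(m)
  storage.mode(obs) <- "double"
  co_obs <- tcrossprod(obs) # co-observed marker counts
  equal <- matrix(0, n, n)
  for (g in c(0L, 1L, 2L)) {
    ind <- (!is.na(m)) & m == g
    storage.mode(ind) <- "double"
    equal <- equal + tcrossprod(ind)
  }
  dist <- (co_obs - equal) / co_obs # NaN where co_obs == 0
  dist[co_obs < min_shared_markers] <- Inf
  dist[!is.finite(dist)] <- Inf
  diag(dist) <- Inf

  comparable <- rowSums(is.finite(dist)) >= k
  if (!all(comparable)) {
    bad <- rownames(m)[!comparable]
    if (is.null(bad)) bad <- which(!comparable)
    stop("sample(s) share too few observed markers with ", k,
         " neighbours: ", paste(bad, collapse = ", "))
  }

  out <- m
  for (i in which(rowSums(!obs) > 0)) {
    # neighbour ranking for sample i: distance, then ascending index
    ord <- order(dist[i, ], seq_len(n))
    for (j in which(is.na(m[i, ]))) {
      cand <- ord[!is.na(m[ord, j]) & is.finite(dist[i, ord])]
      if (length(cand) == 0L) {
        stop("marker ", colnames(m)[j] %||% j,
             " has no observed neighbour for sample ", rownames(m)[i] %||% i)
      }
      nb <- cand[seq_len(min(k, length(cand)))]
      votes <- table(m[nb, j])
      top <- names(votes)[votes == max(votes)]
      out[i, j] <- if (length(top) == 1L) {
        as.integer(top)
      } else {
        m[nb[1L], j] # mode tie: value of the single nearest neighbour
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
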