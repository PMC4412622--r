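#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each sample's size factor
#' is the median, over genes, of the ratio between that sample's count and
#' the per-gene geometric mean across samples. Genes containing any zero
#' (whose geometric mean is zero) are excluded from the median. Dividing a
#' sample's counts by its factor gives normalized counts on a common scale.
#'
#' With `fallback = TRUE` the reference switches to the geometric mean of
#' the positive counts of each gene, which tolerates matrices where no
#' single gene is expressed in every sample (sparse data); ratios are then
#' taken only over positive cells.
#'
#' @param counts count matrix (genes x samples).
#' @param fallback use the positive-count pseudo-reference when no gene is
#'   expressed in all samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts, fallback = FALSE) {
  counts <- as_count_matrix(counts)
  loggeo <- rowMeans(log(counts))          # -Inf for genes with any zero
  use <- is.finite(loggeo)
  if (!any(use)) {
    if (!fallback) {
      stop("no gene has nonzero counts in every sample; ",
           "use fallback = TRUE for a positive-count pseudo-reference")
    }
    loggeo <- apply(counts, 1L, function(x) {
      if (any(x > 0)) mean(log(x[x > 0])) else -Inf
    })
    use <- is.finite(loggeo)
  }
  sf <- apply(counts, 2L, function(k) {
    r <- (log(k) - loggeo)[use & k > 0]
    if (!length(r)) return(NA_real_)
    exp(stats::median(r))
  })
  if (anyNA(sf) || any(sf <= 0) || any(!is.finite(sf))) {
    stop("could not estimate a positive size factor for sample: ",
         colnames(counts)[which(!is.finite(sf) | sf <= 0)][1L])
  }
  sf
}

#' Normalize counts by size factors
#'
#' @param counts count matrix (genes x samples).
#' @param sf size factors as returned by [estimate_size_factors()]; if
#'   named, names must match the sample ids.
#' @return matrix of normalized counts `counts[, j] / sf[j]`.
#' @export
normalize_counts <- function(counts, sf) {
  counts <- as_count_matrix(counts)
  if (length(sf) != ncol(counts)) {
    stop("length(sf) must equal the number of samples")
  }
  if (!is.null(names(sf)) && !identical(names(sf), colnames(counts))) {
    sf <- sf[colnames(counts)]
    if (anyNA(sf)) stop("size factor names do not match sample ids")
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, sf, "/")
}
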