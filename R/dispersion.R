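#' Estimate negative-binomial dispersions
#'
#' Per-gene overdispersion for the NB model `variance = mu + alpha * mu^2`,
#' estimated by the method of moments on normalized counts and shrunk
#' toward a mean-dispersion trend. The raw estimate for gene i is
#'
#'   `alpha_i = max(0, (v_i - mu_i * xi) / mu_i^2)`
#'
#' where `mu_i` and `v_i` are the mean and unbiased variance of the gene's
#' normalized counts over the replicate set and `xi = mean(1 / s_j)` is the
#' shot-noise correction that removes the Poisson sampling component.
#'
#' Two replicate sets are supported. `mode = "per_stage"` pools within-stage
#' residuals over all stages with at least two replicates (the variance is
#' the pooled within-stage unbiased variance), and requires at least one
#' such stage. `mode = "blind"` treats all samples as replicates of one
#' group regardless of stage; it is the strategy of record when a contrast
#' involves a condition with a single (possibly pooled) library, at the
#' price of absorbing real stage effects into the dispersion.
#'
#' The trend regresses `log(alpha_i + eps)` on `log(mu_i)` over genes with
#' positive raw dispersion (log-log linear, two coefficients). The working
#' dispersion combines gene and trend per `sharing`: `"max"` (default,
#' conservative for small replicate numbers) takes the elementwise maximum,
#' `"fit_only"` uses the trend alone, `"gene_only"` the raw estimates.
#'
#' @param counts count matrix.
#' @param design a [stage_design()]; required for `mode = "per_stage"`.
#' @param sf size factors; estimated from `counts` when omitted.
#' @param mode `"per_stage"` or `"blind"`.
#' @param sharing `"max"`, `"fit_only"` or `"gene_only"`.
#' @param trend_min_genes below this number of usable genes the trend fit
#'   is replaced by a pooled constant dispersion (with a warning).
#' @param eps offset inside the log of the trend regression.
#' @return an object of class `dispersion_model`: list with per-gene
#'   vectors `raw`, `fitted`, `working`, `base_mean`, the trend
#'   `coefficients` (or `NULL` if constant), and the call settings.
#' @export
estimate_dispersions <- function(counts, design = NULL, sf = NULL,
                                 mode = c("per_stage", "blind"),
                                 sharing = c("max", "fit_only", "gene_only"),
                                 trend_min_genes = 10L, eps = 1e-8) {
  counts <- as_count_matrix(counts)
  mode <- match.arg(mode)
  sharing <- match.arg(sharing)
  if (ncol(counts) < 2L) stop("dispersion estimation needs >= 2 samples")
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  q <- normalize_counts(counts, sf)

  if (mode == "per_stage") {
    if (is.null(design)) stop("mode = 'per_stage' needs a stage design")
    groups <- stage_samples(design)
    groups <- groups[vapply(groups, length, 1L) >= 2L]
    if (!length(groups)) {
      stop("mode = 'per_stage' needs at least one stage with >= 2 replicates")
    }
    sel <- unlist(groups, use.names = FALSE)
    qs <- q[, sel, drop = FALSE]
    mu <- rowMeans(qs)
    ss <- 0
    for (g in groups) {
      qg <- q[, g, drop = FALSE]
      ss <- ss + rowSums((qg - rowMeans(qg))^2)
    }
    v <- ss / (length(sel) - length(groups))
    xi <- mean(1 / sf[sel])
  } else {
    mu <- rowMeans(q)
    v <- apply(q, 1L, stats::var)
    xi <- mean(1 / sf)
  }

  raw <- ifelse(mu > 0, pmax(0, (v - mu * xi) / mu^2), 0)

  ok <- raw > 0 & mu > 0
  if (sum(ok) < trend_min_genes) {
    warning("fewer than ", trend_min_genes,
            " genes usable for the dispersion trend; ",
            "falling back to a pooled constant dispersion")
    const <- if (any(mu > 0)) mean(raw[mu > 0]) else 0
    fitted <- ifelse(mu > 0, const, 0)
    coefs <- NULL
  } else {
    fit <- stats::lm(log(raw[ok] + eps) ~ log(mu[ok]))
    # back-transforming a log-scale regression estimates the geometric
    # conditional mean; the smearing factor exp(s^2/2) retargets the
    # arithmetic mean, which is what the working dispersion should track
    smear <- exp(summary(fit)$sigma^2 / 2)
    coefs <- unname(stats::coef(fit))
    fitted <- ifelse(mu > 0,
                     pmax(0, smear *
                            exp(coefs[1L] + coefs[2L] * log(pmax(mu, 1e-300))) - eps),
                     0)
  }

  working <- switch(sharing,
                    max = pmax(raw, fitted),
                    fit_only = fitted,
                    gene_only = raw)
  structure(list(raw = stats::setNames(raw, rownames(counts)),
                 fitted = stats::setNames(fitted, rownames(counts)),
                 working = stats::setNames(working, rownames(counts)),
                 base_mean = stats::setNames(mu, rownames(counts)),
                 coefficients = coefs, mode = mode, sharing = sharing,
                 eps = eps),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf(
    "dispersion model (%s, sharing = %s): %d genes, median working alpha %.4g\n",
    x$mode, x$sharing, length(x$working), stats::median(x$working)))
  invisible(x)
}
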