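#' Settings for the pairwise testing stage
#'
#' @param sharing dispersion sharing mode passed to
#'   [estimate_dispersions()] (default `"max"`).
#' @param max_enum exact-enumeration cap of [nb_exact_test()].
#' @param sf_fallback passed to [estimate_size_factors()].
#' @return list of class `difftest_settings`.
#' @export
difftest_settings <- function(sharing = c("max", "fit_only", "gene_only"),
                              max_enum = 10000L, sf_fallback = FALSE) {
  structure(list(sharing = match.arg(sharing),
                 max_enum = as.integer(max_enum),
                 sf_fallback = isTRUE(sf_fallback)),
            class = "difftest_settings")
}

#' Run all pairwise stage contrasts
#'
#' Normalizes the matrix, estimates dispersions, and applies the
#' conditional NB exact test to every unordered pair of stages — C(S, 2)
#' contrasts per gene (6 for a four-stage design). For each contrast the
#' later stage (in design order) is `stage_b`, so
#' `log2fc = log2(mean_b / mean_a)` reads "later over earlier".
#'
#' Dispersion handling follows the small-replicate strategy of the NB
#' exact-test framework: contrasts where both stages have at least two
#' replicates use within-stage (`per_stage`) dispersions; contrasts that
#' involve a single-library stage — common when some stages are sequenced
#' as one pooled sample — use dispersions estimated `blind` across all
#' samples, which is deliberately conservative.
#'
#' When both stage means are zero `log2fc` is `NA`; when exactly one is
#' zero it is signed infinity. Downstream pattern calling compares raw
#' stage means and never consumes these sentinels.
#'
#' @param counts count matrix; must contain every sample of `design`.
#' @param design a [stage_design()].
#' @param settings a [difftest_settings()].
#' @return object of class `pairwise_results`: list with
#'   * `table`: data frame `gene, stage_a, stage_b, mean_a, mean_b,
#'     log2fc, pvalue` (one row per gene per contrast),
#'   * `stage_means`: genes x stages matrix of mean normalized counts,
#'   * `stages`, `size_factors`, `tissue`.
#' @export
run_pairwise <- function(counts, design, settings = difftest_settings()) {
  counts <- as_count_matrix(counts)
  if (!inherits(design, "stage_design")) stop("design must be a stage_design")
  missing_samples <- setdiff(names(design$sample_to_stage), colnames(counts))
  if (length(missing_samples)) {
    stop("design samples absent from count matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  counts <- counts[, names(design$sample_to_stage), drop = FALSE]

  sf <- estimate_size_factors(counts, fallback = settings$sf_fallback)
  q <- normalize_counts(counts, sf)
  groups <- stage_samples(design)
  nrep <- vapply(groups, length, 1L)

  stage_means <- vapply(groups, function(g) rowMeans(q[, g, drop = FALSE]),
                        numeric(nrow(q)))
  if (nrow(q) == 1L) stage_means <- matrix(stage_means, nrow = 1L,
                                           dimnames = list(rownames(q),
                                                           design$stages))

  disp_blind <- estimate_dispersions(counts, design, sf, mode = "blind",
                                     sharing = settings$sharing)
  disp_stage <- if (any(nrep >= 2L)) {
    estimate_dispersions(counts, design, sf, mode = "per_stage",
                         sharing = settings$sharing)
  } else NULL

  S <- length(design$stages)
  pairs <- utils::combn(S, 2L)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- design$stages[pairs[1L, p]]
    b <- design$stages[pairs[2L, p]]
    A <- groups[[a]]
    B <- groups[[b]]
    model <- if (min(nrep[[a]], nrep[[b]]) >= 2L && !is.null(disp_stage)) {
      disp_stage
    } else {
      disp_blind
    }
    kA <- rowSums(counts[, A, drop = FALSE])
    kB <- rowSums(counts[, B, drop = FALSE])
    sAv <- sum(sf[A]); sBv <- sum(sf[B])
    sA2 <- sum(sf[A]^2); sB2 <- sum(sf[B]^2)
    qhat <- rowMeans(q[, c(A, B), drop = FALSE])
    alpha <- model$working
    pv <- vapply(seq_len(nrow(counts)), function(i) {
      nb_exact_test(kA[i], kB[i], sAv, sBv, qhat[i], alpha[i],
                    sA2 = sA2, sB2 = sB2, max_enum = settings$max_enum)
    }, numeric(1L))
    mA <- stage_means[, a]; mB <- stage_means[, b]
    l2fc <- ifelse(mA == 0 & mB == 0, NA_real_, log2(mB / mA))
    rows[[p]] <- data.frame(gene = rownames(counts), stage_a = a, stage_b = b,
                            mean_a = mA, mean_b = mB, log2fc = l2fc,
                            pvalue = pv, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows),
                 stage_means = stage_means,
                 stages = design$stages,
                 size_factors = sf,
                 tissue = design$tissue),
            class = "pairwise_results")
}

#' @export
print.pairwise_results <- function(x, ...) {
  cat(sprintf("pairwise results: %d genes, %d stages (%s), %d contrasts\n",
              nrow(x$stage_means), length(x$stages),
              paste(x$stages, collapse = " < "),
              choose(length(x$stages), 2L)))
  invisible(x)
}

#' Write / read a pairwise-results table
#'
#' The TSV mirrors the columns of `pairwise_results$table`. The reader also
#' accepts externally produced tables with the same columns, so pattern
#' calling is agnostic to which differential-expression engine produced
#' them; stage order is taken from `stages` or, failing that, from first
#' appearance in the table.
#'
#' @param pr a `pairwise_results` object.
#' @param path TSV path.
#' @export
write_pairwise <- function(pr, path) {
  utils::write.table(pr$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param stages optional explicit stage order for [read_pairwise()].
#' @rdname write_pairwise
#' @export
read_pairwise <- function(path, stages = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_pairwise_results(tab, stages = stages)
}

#' Assemble pairwise results from a plain contrast table
#'
#' @param tab data frame with columns `gene, stage_a, stage_b, mean_a,
#'   mean_b, log2fc, pvalue`.
#' @param stages optional explicit stage order.
#' @return a `pairwise_results` object.
#' @export
as_pairwise_results <- function(tab, stages = NULL) {
  need <- c("gene", "stage_a", "stage_b", "mean_a", "mean_b", "pvalue")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("contrast table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(stages)) {
    stages <- unique(as.vector(t(cbind(tab$stage_a, tab$stage_b))))
  }
  S <- length(stages)
  genes <- unique(tab$gene)
  sm <- matrix(NA_real_, length(genes), S, dimnames = list(genes, stages))
  ia <- cbind(match(tab$gene, genes), match(tab$stage_a, stages))
  ib <- cbind(match(tab$gene, genes), match(tab$stage_b, stages))
  sm[ia] <- tab$mean_a
  sm[ib] <- tab$mean_b
  if (anyNA(sm)) stop("contrast table does not cover every stage per gene")
  structure(list(table = as.data.frame(tab), stage_means = sm,
                 stages = stages, size_factors = NULL, tissue = ""),
            class = "pairwise_results")
}
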