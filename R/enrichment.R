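#' One-tailed term over-representation for one gene list
#'
#' For every term with at least one hit in the list, computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of annotated genes when `list_size` genes are sampled from a
#' background of `background_size` genes of which `background_hits` carry
#' the term (the one-tailed Fisher exact test for over-representation).
#' Gene-term pairs are deduplicated upstream, so a gene counts once per
#' term. The expected hit count under random sampling,
#' `list_size * background_hits / background_size`, is reported alongside
#' the observed count for observed-versus-expected displays.
#'
#' @param genes character vector: the gene list (e.g. one binary pattern's
#'   genes). Must be a subset of `universe`.
#' @param universe character vector: the background gene set.
#' @param ann an [annotation_set()].
#' @return data frame `term, list_hits, list_size, background_hits,
#'   background_size, expected_hits, pvalue`, one row per term hit in the
#'   list, ordered by increasing p-value.
#' @export
fisher_enrich <- function(genes, universe, ann) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!length(genes)) stop("empty gene list")
  if (!length(universe)) stop("empty universe")
  out <- setdiff(genes, universe)
  if (length(out)) stop("gene list not contained in universe: ", out[1L])
  a <- ann[ann$gene %in% universe, , drop = FALSE]
  if (!nrow(a)) stop("no annotations overlap the universe")
  bg_hits <- table(a$term)
  in_list <- a[a$gene %in% genes, , drop = FALSE]
  list_hits <- table(in_list$term)
  if (!length(list_hits)) {
    return(data.frame(term = character(), list_hits = integer(),
                      list_size = integer(), background_hits = integer(),
                      background_size = integer(), expected_hits = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  terms <- names(list_hits)
  k <- as.integer(list_hits)
  m <- as.integer(bg_hits[terms])
  N <- length(universe)
  n <- length(genes)
  p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
  out <- data.frame(term = terms, list_hits = k, list_size = n,
                    background_hits = m, background_size = N,
                    expected_hits = n * m / N, pvalue = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone in p-rank, capped at
#' 1, invariant to input order. The family is whichever vector is passed —
#' in this pipeline, the terms tested within one pattern list.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Assign significance tiers with the nominal fallback
#'
#' Primary cutoff: FDR < `fdr_cut` (tier `"fdr"`). When a pattern's term
#' family yields no FDR-significant row at all, the test falls back to the
#' nominal p-value with no FDR cutoff: rows with `p < p_cut` get tier
#' `"nominal"`. Everything else is `"ns"`. The fallback is applied per
#' pattern when a `pattern` column is present, otherwise to the whole
#' table.
#'
#' @param tab data frame with columns `pvalue`, `fdr` (and optionally
#'   `pattern`).
#' @param fdr_cut,p_cut the two cutoffs (defaults 0.05).
#' @return `tab` with a `tier` column.
#' @export
apply_tiers <- function(tab, fdr_cut = 0.05, p_cut = 0.05) {
  if (!nrow(tab)) {
    tab$tier <- character(0L)
    return(tab)
  }
  tier_one <- function(d) {
    if (any(d$fdr < fdr_cut)) {
      ifelse(d$fdr < fdr_cut, "fdr", "ns")
    } else {
      ifelse(d$pvalue < p_cut, "nominal", "ns")
    }
  }
  if ("pattern" %in% colnames(tab)) {
    tab$tier <- NA_character_
    for (p in unique(tab$pattern)) {
      i <- tab$pattern == p
      tab$tier[i] <- tier_one(tab[i, , drop = FALSE])
    }
  } else {
    tab$tier <- tier_one(tab)
  }
  tab
}

#' Reduce significant terms to the most specific ones
#'
#' Among the significant rows (tier other than `"ns"`) of each pattern,
#' drops any term that is a transitive ancestor of another significant
#' term, keeping only leaf-most results. Non-significant rows are left
#' untouched, and a term never disappears unless one of its descendants
#' survives. Terms absent from the hierarchy are treated as leaves.
#'
#' @param tab data frame with columns `term`, `tier` (and optionally
#'   `pattern`).
#' @param hierarchy a [term_hierarchy()], or `NULL` for no reduction.
#' @return the reduced table.
#' @export
reduce_to_most_specific <- function(tab, hierarchy = NULL) {
  if (is.null(hierarchy) || !nrow(tab)) return(tab)
  known <- unique(c(hierarchy$child, hierarchy$parent))
  missing_terms <- setdiff(unique(tab$term[tab$tier != "ns"]), known)
  if (length(missing_terms)) {
    warning(length(missing_terms),
            " significant term(s) absent from the hierarchy; kept as leaves")
  }
  anc <- hierarchy_ancestors(hierarchy, unique(tab$term))
  grp <- if ("pattern" %in% colnames(tab)) tab$pattern else rep("", nrow(tab))
  drop <- rep(FALSE, nrow(tab))
  for (p in unique(grp)) {
    i <- which(grp == p & tab$tier != "ns")
    sig_terms <- tab$term[i]
    ancestors_of_sig <- unique(unlist(anc[sig_terms], use.names = FALSE))
    drop[i] <- sig_terms %in% ancestors_of_sig
  }
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment settings
#' @param fdr_cut,p_cut significance cutoffs for [apply_tiers()].
#' @param universe `"annotated"` (default: all annotated genes of the
#'   assignment table) or `"all"` (every gene of the assignment table).
#' @return list of class `enrich_settings`.
#' @export
enrich_settings <- function(fdr_cut = 0.05, p_cut = 0.05,
                            universe = c("annotated", "all")) {
  structure(list(fdr_cut = fdr_cut, p_cut = p_cut,
                 universe = match.arg(universe)),
            class = "enrich_settings")
}

#' Per-pattern term over-representation
#'
#' Runs, for each binary pattern's gene list, the one-tailed Fisher test
#' over all terms hit in the list, Benjamini-Hochberg adjustment within
#' the pattern's term family, tier assignment with the nominal fallback,
#' and reduction to most-specific terms. Grey genes are excluded from
#' pattern lists; pattern lists with no annotated gene are skipped with a
#' warning.
#'
#' @param assignments output of [call_patterns()].
#' @param ann an [annotation_set()]; must not be empty.
#' @param hierarchy optional [term_hierarchy()] for the reduction step.
#' @param settings an [enrich_settings()].
#' @return data frame of class `enrichment_table`: columns `pattern`,
#'   `term`, `list_hits`, `list_size`, `background_hits`,
#'   `background_size`, `expected_hits`, `pvalue`, `fdr`, `tier`.
#' @export
enrich_pattern_lists <- function(assignments, ann, hierarchy = NULL,
                                 settings = enrich_settings()) {
  if (!nrow(ann)) stop("annotation set is empty")
  genes_all <- assignments$gene
  universe <- if (settings$universe == "annotated") {
    intersect(genes_all, unique(ann$gene))
  } else {
    genes_all
  }
  if (!length(universe)) stop("no assigned gene carries an annotation")
  codes <- sort(unique(assignments$code[!is.na(assignments$code)]))
  out <- list()
  for (cd in codes) {
    lst <- intersect(assignments$gene[!is.na(assignments$code) &
                                        assignments$code == cd], universe)
    if (!length(lst)) {
      warning("pattern ", cd, " has no annotated genes; skipped")
      next
    }
    e <- fisher_enrich(lst, universe, ann)
    if (!nrow(e)) next
    e$fdr <- bh_fdr(e$pvalue)
    e <- cbind(pattern = cd, e, stringsAsFactors = FALSE)
    out[[cd]] <- e
  }
  if (!length(out)) {
    stop("no pattern list produced any enrichment row")
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab <- apply_tiers(tab, settings$fdr_cut, settings$p_cut)
  tab <- reduce_to_most_specific(tab, hierarchy)
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Write an enrichment table
#' @param tab output of [enrich_pattern_lists()].
#' @param path TSV path.
#' @export
write_enrichment <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
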