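#' Enumerate all binary codes over S stages
#'
#' A binary code is a length-S string over {0,1}; position k refers to
#' stage k of the design, 1 marking a high-read stage and 0 a low-read
#' stage. A four-stage design yields the sixteen codes 0000 ... 1111.
#'
#' @param S number of stages (>= 1).
#' @return character vector of all `2^S` codes in lexicographic order.
#' @export
enumerate_codes <- function(S) {
  if (length(S) != 1L || is.na(S) || S < 1L || S != round(S)) {
    stop("S must be a positive integer")
  }
  S <- as.integer(S)
  if (S > 20L) stop("S too large to enumerate")
  vapply(0:(2^S - 1L), function(x) {
    paste(rev((x %/% 2^(0:(S - 1L))) %% 2L), collapse = "")
  }, character(1L))
}

code_bits <- function(code) as.integer(strsplit(code, "")[[1L]])

#' Pattern-caller settings
#'
#' The two cutoffs of the binary-patterning rule: a contrast counts as
#' significant when its pairwise p-value is below `alpha`, and a stage may
#' be called high only when its mean normalized read count reaches
#' `min_reads` (default 1000 reads, retaining results likely to carry
#' biological meaning rather than noise around zero).
#'
#' `consistency = "strict"` (default) additionally requires that stages
#' sharing a bit are *not* significantly different from each other; this
#' makes the assigned code provably unique. `"lenient"` drops that
#' requirement and reproduces the literal high-versus-low reading, at the
#' price that several codes can fit one gene (such genes become grey with
#' `n_consistent_codes` recorded).
#'
#' `high_stage_rule` controls how `min_reads` is applied:
#' `"every_high_stage"` (default) requires every high stage's mean to reach
#' the cutoff, `"any_high_stage"` only the best one.
#'
#' @param alpha pairwise significance cutoff in (0, 1).
#' @param min_reads minimum mean normalized read count for a high stage.
#' @param consistency `"strict"` or `"lenient"`.
#' @param high_stage_rule `"every_high_stage"` or `"any_high_stage"`.
#' @return list of class `caller_settings`.
#' @export
caller_settings <- function(alpha = 0.05, min_reads = 1000,
                            consistency = c("strict", "lenient"),
                            high_stage_rule = c("every_high_stage",
                                                "any_high_stage")) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (min_reads < 0) stop("min_reads must be >= 0")
  structure(list(alpha = alpha, min_reads = min_reads,
                 consistency = match.arg(consistency),
                 high_stage_rule = match.arg(high_stage_rule)),
            class = "caller_settings")
}

# Symmetric S x S p-value matrix for one gene from its contrast rows.
gene_pmatrix <- function(tab_gene, stages) {
  S <- length(stages)
  P <- matrix(NA_real_, S, S, dimnames = list(stages, stages))
  ia <- match(tab_gene$stage_a, stages)
  ib <- match(tab_gene$stage_b, stages)
  P[cbind(ia, ib)] <- tab_gene$pvalue
  P[cbind(ib, ia)] <- tab_gene$pvalue
  if (anyNA(P[upper.tri(P)])) {
    miss <- which(is.na(P) & upper.tri(P), arr.ind = TRUE)[1L, ]
    stop("missing contrast: ", stages[miss[1L]], " vs ", stages[miss[2L]])
  }
  P
}

# threshold rule on the high stages of a code
threshold_ok <- function(bits, stage_means, settings) {
  hi <- stage_means[bits == 1L]
  if (!length(hi)) return(TRUE)
  if (settings$high_stage_rule == "every_high_stage") {
    all(hi >= settings$min_reads)
  } else {
    any(hi >= settings$min_reads)
  }
}

#' Check one binary code against a gene's pairwise evidence
#'
#' A mixed code (containing both 0 and 1) is consistent when
#' (i) every (high, low) stage pair is significantly different
#' (`p < alpha`) with the high stage's mean strictly above the low
#' stage's — ties fail, since a high call demands a positive fold
#' change; (ii) in strict mode, every same-bit pair is *not* significant
#' (`p >= alpha`); and (iii) the high stages satisfy the minimum-read
#' rule. For the all-ones (all-zeros) code, (i) is vacuous and consistency
#' reduces to (ii) plus every (no) stage passing the read threshold.
#'
#' @param pmat symmetric S x S matrix of pairwise p-values (dimnames =
#'   stages), or a gene's subset of a `pairwise_results$table`.
#' @param stage_means named length-S vector of mean normalized counts.
#' @param code a binary code string of length S.
#' @param settings a [caller_settings()].
#' @return list with `consistent` (logical) and `violations` (data frame
#'   `stage_a, stage_b, reason`, empty when consistent).
#' @export
code_consistent <- function(pmat, stage_means, code,
                            settings = caller_settings()) {
  stages <- names(stage_means)
  if (is.data.frame(pmat)) pmat <- gene_pmatrix(pmat, stages)
  bits <- code_bits(code)
  if (length(bits) != length(stages)) stop("code length != number of stages")
  viol <- list()
  for (i in seq_along(stages)[-length(stages)]) {
    for (j in (i + 1L):length(stages)) {
      p <- pmat[i, j]
      if (bits[i] != bits[j]) {
        h <- if (bits[i] == 1L) i else j
        l <- if (bits[i] == 1L) j else i
        if (!(p < settings$alpha)) {
          viol[[length(viol) + 1L]] <- c(stages[i], stages[j],
                                         "high/low pair not significant")
        } else if (!(stage_means[h] > stage_means[l])) {
          viol[[length(viol) + 1L]] <- c(stages[i], stages[j],
                                         "high stage mean not above low stage mean")
        }
      } else if (settings$consistency == "strict" && p < settings$alpha) {
        viol[[length(viol) + 1L]] <- c(stages[i], stages[j],
                                       "same-bit pair significantly different")
      }
    }
  }
  if (!threshold_ok(bits, stage_means, settings)) {
    viol[[length(viol) + 1L]] <- c(NA_character_, NA_character_,
                                   "high stage below minimum-read cutoff")
  }
  violations <- if (length(viol)) {
    as.data.frame(do.call(rbind, viol), stringsAsFactors = FALSE) |>
      stats::setNames(c("stage_a", "stage_b", "reason"))
  } else {
    data.frame(stage_a = character(), stage_b = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  list(consistent = nrow(violations) == 0L, violations = violations)
}

# Fast consistency over all mixed codes for one gene. pv/i/j index the
# C(S,2) pairs; returns logical vector over `codes` rows (bit matrix).
consistent_mixed <- function(codes_bits, pair_i, pair_j, pv, means,
                             settings) {
  sig <- pv < settings$alpha
  gt_i <- means[pair_i] > means[pair_j]
  gt_j <- means[pair_j] > means[pair_i]
  ok_hi_i <- sig & gt_i   # valid when bit_i = 1, bit_j = 0
  ok_hi_j <- sig & gt_j   # valid when bit_i = 0, bit_j = 1
  ok_same <- if (settings$consistency == "strict") !sig else rep(TRUE, length(pv))
  vapply(seq_len(nrow(codes_bits)), function(c) {
    bi <- codes_bits[c, pair_i]
    bj <- codes_bits[c, pair_j]
    ok <- ifelse(bi == bj, ok_same, ifelse(bi == 1L, ok_hi_i, ok_hi_j))
    all(ok) && threshold_ok(codes_bits[c, ], means, settings)
  }, logical(1L))
}

#' Assign a binary code to one gene
#'
#' Decision rule over the `2^S - 2` mixed codes:
#' * exactly one consistent mixed code: the gene is `assigned` that code;
#' * no consistent mixed code and no significant pair at all: the gene is
#'   flat — `assigned` all-ones if every stage passes the minimum-read
#'   cutoff, otherwise `low` with the all-zeros code (few reads
#'   everywhere);
#' * no consistent mixed code but at least one significant pair: `grey` —
#'   the expression profile is real but fits no binary pattern;
#' * two or more consistent mixed codes (possible only in lenient mode):
#'   `grey`, with the number of candidates recorded.
#'
#' @param pmat symmetric p-value matrix or gene contrast rows (as in
#'   [code_consistent()]).
#' @param stage_means named length-S vector of mean normalized counts.
#' @param settings a [caller_settings()].
#' @return list with `code` (string or `NA`), `status` (`"assigned"`,
#'   `"grey"`, `"low"`), `n_consistent_codes`, `n_significant_pairs`.
#' @export
assign_code <- function(pmat, stage_means, settings = caller_settings()) {
  stages <- names(stage_means)
  if (is.data.frame(pmat)) pmat <- gene_pmatrix(pmat, stages)
  S <- length(stages)
  codes <- enumerate_codes(S)
  mixed <- codes[-c(1L, length(codes))]
  cb <- do.call(rbind, lapply(mixed, code_bits))
  pr <- utils::combn(S, 2L)
  pv <- pmat[t(pr)]
  cons <- consistent_mixed(cb, pr[1L, ], pr[2L, ], pv, stage_means, settings)
  nsig <- sum(pv < settings$alpha)
  ncons <- sum(cons)
  if (ncons == 1L) {
    list(code = mixed[cons], status = "assigned",
         n_consistent_codes = 1L, n_significant_pairs = nsig)
  } else if (ncons == 0L && nsig == 0L) {
    if (all(stage_means >= settings$min_reads)) {
      list(code = paste(rep("1", S), collapse = ""), status = "assigned",
           n_consistent_codes = 0L, n_significant_pairs = nsig)
    } else {
      list(code = paste(rep("0", S), collapse = ""), status = "low",
           n_consistent_codes = 0L, n_significant_pairs = nsig)
    }
  } else {
    list(code = NA_character_, status = "grey",
         n_consistent_codes = ncons, n_significant_pairs = nsig)
  }
}

#' Call binary patterns for all genes
#'
#' Applies [assign_code()] to every gene of a pairwise-results object (or
#' an external contrast table accepted by [as_pairwise_results()]).
#' Deterministic given its inputs; each gene receives exactly one status,
#' so assigned + grey + low partition the gene set.
#'
#' @param pr a `pairwise_results` object or a contrast data frame.
#' @param settings a [caller_settings()].
#' @return data frame of class `pattern_assignments`: `gene`, `code`
#'   (`NA` for grey), `status`, one `stage_mean_<stage>` column per stage,
#'   `n_consistent_codes`, `n_significant_pairs`. The stage order is kept
#'   in attribute `stages`, the settings in attribute `settings`.
#' @export
call_patterns <- function(pr, settings = caller_settings()) {
  if (is.data.frame(pr)) pr <- as_pairwise_results(pr)
  if (!inherits(pr, "pairwise_results")) {
    stop("pr must be pairwise_results or a contrast data frame")
  }
  stages <- pr$stages
  S <- length(stages)
  genes <- rownames(pr$stage_means)
  tab <- pr$table
  pvm <- matrix(NA_real_, length(genes), choose(S, 2L))
  pairs <- utils::combn(S, 2L)
  key <- paste(stages[pairs[1L, ]], stages[pairs[2L, ]])
  k1 <- paste(tab$stage_a, tab$stage_b)
  k2 <- paste(tab$stage_b, tab$stage_a)
  col <- match(k1, key)
  col[is.na(col)] <- match(k2, key)[is.na(col)]
  if (anyNA(col)) stop("contrast table has a stage pair outside the design")
  pvm[cbind(match(tab$gene, genes), col)] <- tab$pvalue
  if (anyNA(pvm)) stop("contrast table does not cover all C(S,2) pairs")

  codes <- enumerate_codes(S)
  mixed <- codes[-c(1L, length(codes))]
  cb <- do.call(rbind, lapply(mixed, code_bits))
  all1 <- codes[length(codes)]
  all0 <- codes[1L]

  res <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    means <- pr$stage_means[g, ]
    pv <- pvm[g, ]
    cons <- consistent_mixed(cb, pairs[1L, ], pairs[2L, ], pv, means, settings)
    nsig <- sum(pv < settings$alpha)
    ncons <- sum(cons)
    if (ncons == 1L) {
      res[[g]] <- list(mixed[cons], "assigned", 1L, nsig)
    } else if (ncons == 0L && nsig == 0L) {
      if (all(means >= settings$min_reads)) {
        res[[g]] <- list(all1, "assigned", 0L, nsig)
      } else {
        res[[g]] <- list(all0, "low", 0L, nsig)
      }
    } else {
      res[[g]] <- list(NA_character_, "grey", ncons, nsig)
    }
  }
  out <- data.frame(
    gene = genes,
    code = vapply(res, `[[`, character(1L), 1L),
    status = vapply(res, `[[`, character(1L), 2L),
    stringsAsFactors = FALSE)
  sm <- pr$stage_means
  colnames(sm) <- paste0("stage_mean_", stages)
  out <- cbind(out, as.data.frame(sm, row.names = NULL))
  out$n_consistent_codes <- vapply(res, `[[`, integer(1L), 3L)
  out$n_significant_pairs <- vapply(res, `[[`, integer(1L), 4L)
  rownames(out) <- NULL
  attr(out, "stages") <- stages
  attr(out, "settings") <- settings
  class(out) <- c("pattern_assignments", "data.frame")
  out
}

#' Pattern abundance table
#'
#' Counts genes per binary code (grey genes form their own bucket) and
#' ranks patterns from most to least abundant. Counts always sum to the
#' number of genes.
#'
#' @param assignments output of [call_patterns()].
#' @return data frame `code, count, fraction, rank`, sorted by descending
#'   count; grey genes appear under code `"grey"`.
#' @export
pattern_abundance <- function(assignments) {
  code <- ifelse(is.na(assignments$code), "grey", assignments$code)
  tab <- table(code)
  out <- data.frame(code = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$code), , drop = FALSE]
  out$fraction <- out$count / sum(out$count)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write / read a pattern-assignment table
#' @param assignments output of [call_patterns()].
#' @param path TSV path.
#' @export
write_assignments <- function(assignments, path) {
  df <- as.data.frame(assignments)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(code = "character"), na.strings = "")
  sm_cols <- grep("^stage_mean_", colnames(df), value = TRUE)
  attr(df, "stages") <- sub("^stage_mean_", "", sm_cols)
  class(df) <- c("pattern_assignments", "data.frame")
  df
}

#' Write one gene-list file per pattern
#'
#' Mirrors the per-pattern contig lists of the binary-patterning workflow:
#' one single-column TSV per code under `dir`, named `pattern_<code>.tsv`.
#'
#' @param assignments output of [call_patterns()].
#' @param dir output directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
write_pattern_lists <- function(assignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  codes <- sort(unique(assignments$code[!is.na(assignments$code)]))
  paths <- character(0L)
  for (cd in codes) {
    p <- file.path(dir, paste0("pattern_", cd, ".tsv"))
    utils::write.table(
      data.frame(gene = assignments$gene[!is.na(assignments$code) &
                                           assignments$code == cd]),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
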