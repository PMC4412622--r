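#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants every downstream step relies on: a numeric matrix
#' of nonnegative integral read counts with unique, non-empty gene and
#' sample identifiers, at least one gene and at least two samples.
#' Fractional values are rejected rather than rounded, so pre-normalized
#' matrices cannot slip in silently.
#'
#' @param counts matrix of read counts, genes in rows, samples in columns;
#'   `rownames` are gene ids, `colnames` are sample ids.
#' @return the validated matrix (numeric storage, integral values).
#' @export
as_count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (nrow(counts) < 1L) stop("count matrix needs at least 1 gene")
  if (ncol(counts) < 2L) stop("count matrix needs at least 2 samples")
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    stop("count matrix must have non-empty gene ids as rownames")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("count matrix must have non-empty sample ids as colnames")
  }
  if (anyDuplicated(gid)) {
    stop("duplicated gene id: ", gid[duplicated(gid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample id: ", sid[duplicated(sid)][1L])
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(counts)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(counts)) + 1L
    stop(sprintf(
      "count matrix cell [%s, %s] = %s is not a nonnegative integer",
      gid[i], sid[j], format(counts[i, j])))
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a count table
#'
#' The first column holds gene ids, the header row sample ids, the body
#' nonnegative integer read counts. Row and column order are preserved
#' exactly as in the file.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a validated count matrix (see [as_count_matrix()]).
#' @export
read_counts <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count table needs a gene column and >= 2 samples")
  gid <- df[[1L]]
  sid <- colnames(df)[-1L]
  if (anyDuplicated(sid)) {
    stop("duplicated sample id in header: ", sid[duplicated(sid)][1L])
  }
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(num)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(num)) + 1L
    stop(sprintf("non-numeric count at gene %s, sample %s: '%s'",
                 gid[i], sid[j], body[i, j]))
  }
  dimnames(num) <- list(gid, sid)
  as_count_matrix(num)
}

#' Write a count table
#'
#' Inverse of [read_counts()]; the round trip is lossless.
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "csv")) {
  counts <- as_count_matrix(counts)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(counts),
                   format(counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a stage design
#'
#' An ordered set of S >= 2 stage labels plus a total map from samples to
#' stages. The order of `stages` is semantic: position k of every binary
#' code refers to stage k. Order is always explicit, never alphabetical.
#'
#' @param stages character vector of unique stage labels in biological
#'   order (e.g. inter-molt, early pre-molt, late pre-molt, post-molt).
#' @param sample_to_stage named character vector: names are sample ids,
#'   values are stage labels.
#' @param tissue free-text label carried through outputs.
#' @return an object of class `stage_design` with elements `stages`,
#'   `sample_to_stage`, `tissue`.
#' @export
stage_design <- function(stages, sample_to_stage, tissue = "") {
  stages <- as.character(stages)
  if (length(stages) < 2L) stop("a stage design needs >= 2 stages")
  if (anyDuplicated(stages)) stop("duplicated stage label")
  s2s <- as.character(sample_to_stage)
  names(s2s) <- names(sample_to_stage)
  if (is.null(names(s2s)) || any(names(s2s) == "") || anyNA(names(s2s))) {
    stop("sample_to_stage must be a named vector (names = sample ids)")
  }
  if (anyDuplicated(names(s2s))) {
    stop("sample mapped twice: ", names(s2s)[duplicated(names(s2s))][1L])
  }
  unknown <- setdiff(unique(s2s), stages)
  if (length(unknown)) stop("stage not in stage list: ", unknown[1L])
  empty <- setdiff(stages, s2s)
  if (length(empty)) stop("stage with zero samples: ", empty[1L])
  structure(list(stages = stages, sample_to_stage = s2s,
                 tissue = as.character(tissue)[1L]),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("stage design: %d stages (%s), %d samples%s\n",
              length(x$stages), paste(x$stages, collapse = " < "),
              length(x$sample_to_stage),
              if (nzchar(x$tissue)) paste0(", tissue ", x$tissue) else ""))
  invisible(x)
}

# samples belonging to each stage, in design order
stage_samples <- function(design) {
  lapply(stats::setNames(design$stages, design$stages),
         function(st) names(design$sample_to_stage)[design$sample_to_stage == st])
}

#' Read a stage design table
#'
#' Two-column TSV (`sample`, `stage`). Stage order comes from an optional
#' leading comment line `# stages: A,B,C,...`; without it, first-appearance
#' order of the stage column is used.
#'
#' @param path path to the TSV.
#' @param tissue optional tissue label.
#' @return a [stage_design()] object.
#' @export
read_design <- function(path, tissue = "") {
  lines <- readLines(path)
  order_line <- grep("^#\\s*stages\\s*:", lines, value = TRUE)
  body <- lines[!startsWith(trimws(lines), "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "stage") %in% colnames(df))) {
    stop("design table needs columns 'sample' and 'stage'")
  }
  if (length(order_line)) {
    ord <- sub("^#\\s*stages\\s*:\\s*", "", order_line[1L])
    stages <- trimws(strsplit(ord, ",")[[1L]])
  } else {
    stages <- unique(df$stage)
  }
  stage_design(stages, stats::setNames(df$stage, df$sample), tissue = tissue)
}

#' Write a stage design table
#' @param design a [stage_design()] object.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stages: ", paste(design$stages, collapse = ",")), con)
  utils::write.table(
    data.frame(sample = names(design$sample_to_stage),
               stage = unname(design$sample_to_stage)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' Deduplicated (gene, term) pairs, e.g. a two-column export of a
#' Blast2GO-style annotation table. A gene counts at most once per term.
#'
#' @param gene,term character vectors of equal length.
#' @param term_names optional named character vector mapping term ids to
#'   human-readable labels.
#' @return an object of class `annotation_set`: a data frame with columns
#'   `gene`, `term` and attribute `term_names`.
#' @export
annotation_set <- function(gene, term, term_names = NULL) {
  stopifnot(length(gene) == length(term))
  df <- unique(data.frame(gene = as.character(gene),
                          term = as.character(term),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "term_names") <- term_names
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (gene, term); an optional third column gives term labels.
#' Duplicate rows are collapsed.
#'
#' @param path path to the TSV.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) {
    if (nrow(df) == 0L && ncol(df) < 2L) {
      return(annotation_set(character(), character()))
    }
    stop("annotation table needs two columns (gene, term)")
  }
  tn <- NULL
  if (ncol(df) >= 3L) {
    tn <- df[[3L]]
    names(tn) <- df[[2L]]
    tn <- tn[!duplicated(names(tn))]
  }
  annotation_set(df[[1L]], df[[2L]], term_names = tn)
}

#' Construct a term hierarchy
#'
#' Directed (child, parent) edges over term ids; checked to be acyclic.
#' On a cycle the error message prints one offending cycle.
#'
#' @param child,parent character vectors of equal length.
#' @return an object of class `term_hierarchy`: a data frame with columns
#'   `child`, `parent`.
#' @export
term_hierarchy <- function(child, parent) {
  stopifnot(length(child) == length(parent))
  df <- unique(data.frame(child = as.character(child),
                          parent = as.character(parent),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  cyc <- find_cycle(df$child, df$parent)
  if (!is.null(cyc)) {
    stop("term hierarchy contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  class(df) <- c("term_hierarchy", "data.frame")
  df
}

#' Read a term hierarchy table
#' @param path path to a two-column TSV (child, parent).
#' @return a [term_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(term_hierarchy(character(), character()))
  if (ncol(df) < 2L) stop("hierarchy table needs two columns (child, parent)")
  term_hierarchy(df[[1L]], df[[2L]])
}

# Depth-first search for a directed cycle; returns the node sequence of one
# cycle (closed: first == last) or NULL if the edge set is acyclic.
find_cycle <- function(from, to) {
  adj <- split(to, factor(from, levels = unique(from)))
  color <- new.env(parent = emptyenv())  # 1 = on stack, 2 = done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = color, ifnotfound = 0L)[[1L]]
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    assign(v, 1L, envir = color)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = color)
  }
  for (v in unique(from)) visit(v)
  found
}

# All ancestors of each term under the (child, parent) edge relation,
# as a named list of character vectors. Terms absent from the hierarchy
# are treated as leaves with no ancestors.
hierarchy_ancestors <- function(h, terms) {
  parents <- split(h$parent, factor(h$child, levels = unique(h$child)))
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    hit <- mget(t, envir = memo, ifnotfound = list(NULL))[[1L]]
    if (!is.null(hit)) return(hit)
    ps <- parents[[t]]
    out <- if (is.null(ps)) character() else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    assign(t, out, envir = memo)
    out
  }
  stats::setNames(lapply(terms, anc), terms)
}
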