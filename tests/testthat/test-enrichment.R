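test_that("one-tailed over-representation matches direct enumeration", {
  # 10 genes drawn from 100, a term annotating 50 of the universe and all
  # 10 of the list: p = C(50,10)/C(100,10), frozen from the lchoose oracle
  universe <- sprintf("u%03d", 1:100)
  lst <- universe[1:10]
  ann <- annotation_set(universe[1:50], rep("tX", 50))
  e <- fisher_enrich(lst, universe, ann)
  expect_equal(e$pvalue, 5.934197e-04, tolerance = 1e-6)
  expect_equal(e$pvalue, hyper_tail_oracle(10, 50, 100, 10),
               tolerance = 1e-12)
  expect_equal(e$expected_hits, 5)  # 10 * 50 / 100
  expect_equal(e$list_hits, 10L)
  expect_equal(e$background_hits, 50L)

  # a term annotating the entire universe is never enriched
  ann2 <- annotation_set(universe, rep("tAll", 100))
  expect_equal(fisher_enrich(lst, universe, ann2)$pvalue, 1)

  expect_error(fisher_enrich(character(), universe, ann), "empty")
  expect_error(fisher_enrich("zz", universe, ann), "not contained")
})

test_that("hypergeometric p-values match brute force over a dense grid", {
  worst <- 0
  for (N in c(10, 25, 40, 60)) {
    for (m in unique(round(c(N / 5, N / 2, N - 2)))) {
      for (n in unique(round(c(3, N / 3, N / 2)))) {
        universe <- sprintf("g%03d", 1:N)
        ann <- annotation_set(universe[1:m], rep("t", m))
        for (k in 1:min(m, n)) {
          lst <- c(universe[1:k], universe[(m + 1):(m + n - k)])
          if (length(lst) != n || n - k > N - m) next
          e <- fisher_enrich(lst, universe, ann)
          worst <- max(worst, abs(e$pvalue - hyper_tail_oracle(k, m, N, n)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("BH adjustment reproduces the step-up formula and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.004, 0.9, 0.03, 0.2, 0.65)
  f <- bh_fdr(p)
  expect_true(all(f >= p))
  expect_true(all(f <= 1))
  # order invariance and idempotence under re-sorting
  o <- sample(length(p))
  expect_equal(bh_fdr(p[o]), f[o])
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("tier assignment applies the nominal fallback per pattern", {
  t1 <- data.frame(pvalue = c(0.001, 0.15), fdr = c(0.01, 0.2))
  expect_equal(apply_tiers(t1)$tier, c("fdr", "ns"))

  t2 <- data.frame(pvalue = c(0.01, 0.2), fdr = c(0.2, 0.3))
  expect_equal(apply_tiers(t2)$tier, c("nominal", "ns"))

  t3 <- data.frame(pattern = c("0110", "0110", "1001", "1001"),
                   pvalue = c(0.001, 0.03, 0.02, 0.5),
                   fdr = c(0.01, 0.3, 0.12, 0.8))
  tiers <- apply_tiers(t3)$tier
  expect_equal(tiers, c("fdr", "ns", "nominal", "ns"))

  t0 <- data.frame(pvalue = numeric(), fdr = numeric())
  expect_equal(nrow(apply_tiers(t0)), 0L)
})

test_that("reduction keeps leaf-most significant terms only", {
  h <- term_hierarchy(c("child", "mid"), c("mid", "root"))
  tab <- data.frame(term = c("child", "mid", "root", "other"),
                    tier = c("fdr", "fdr", "fdr", "ns"),
                    stringsAsFactors = FALSE)
  red <- reduce_to_most_specific(tab, h)
  expect_identical(red$term, c("child", "other"))  # ns rows untouched

  sib <- data.frame(term = c("child", "sibling"), tier = c("fdr", "fdr"),
                    stringsAsFactors = FALSE)
  expect_warning(red2 <- reduce_to_most_specific(sib, h), "absent")
  expect_equal(nrow(red2), 2L)  # siblings both kept, unknown term = leaf

  expect_identical(reduce_to_most_specific(tab, NULL), tab)
})

test_that("reduction never removes a term without a surviving descendant", {
  set.seed(40)
  terms <- sprintf("t%02d", 1:12)
  for (i in 1:20) {
    # random forest: each term may point to a lower-indexed parent
    child <- parent <- character()
    for (j in 2:12) {
      if (runif(1) < 0.7) {
        child <- c(child, terms[j])
        parent <- c(parent, terms[sample(j - 1, 1)])
      }
    }
    h <- term_hierarchy(child, parent)
    tab <- data.frame(term = terms,
                      tier = sample(c("fdr", "nominal", "ns"), 12,
                                    replace = TRUE),
                      stringsAsFactors = FALSE)
    red <- suppressWarnings(reduce_to_most_specific(tab, h))
    dropped <- setdiff(tab$term[tab$tier != "ns"],
                       red$term[red$tier != "ns"])
    anc <- binpat:::hierarchy_ancestors(h, terms)
    surviving <- red$term[red$tier != "ns"]
    for (d in dropped) {
      has_desc <- any(vapply(surviving, function(s) d %in% anc[[s]],
                             logical(1)))
      expect_true(has_desc)
    }
  }
})

test_that("a planted enrichment is detected and survives reduction", {
  cfg <- sim_config(n_genes = 800L, stages = molt_stages,
                    replicates = c(3L, 3L, 3L, 3L),
                    code_proportions = c("0110" = 0.25),
                    fold_change = 8, dispersion = 0.05,
                    baseline_meanlog = log(3000), baseline_sdlog = 0.3,
                    planted_terms = data.frame(term = "chitin_catabolic",
                                               code = "0110", factor = 5),
                    n_noise_terms = 10L, annotation_rate = 0.05,
                    seed = 13L)
  sim <- simulate_counts(cfg)
  asg <- call_patterns(run_pairwise(sim$counts, sim$design))

  # parent term annotates every child-term gene plus a few more
  child_genes <- sim$annotations$gene[sim$annotations$term ==
                                        "chitin_catabolic"]
  extra <- setdiff(sim$truth$gene, child_genes)[1:20]
  ann <- annotation_set(c(sim$annotations$gene, child_genes, extra),
                        c(sim$annotations$term,
                          rep("catabolic_process",
                              length(child_genes) + length(extra))))
  h <- term_hierarchy("chitin_catabolic", "catabolic_process")
  tab <- suppressWarnings(enrich_pattern_lists(asg, ann, h))
  row <- tab[tab$pattern == "0110" & tab$term == "chitin_catabolic", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$tier, "fdr")
  expect_false("catabolic_process" %in%
                 tab$term[tab$pattern == "0110" & tab$tier != "ns"])
  expect_true(all(tab$fdr >= tab$pvalue))
  expect_equal(tab$expected_hits,
               tab$list_size * tab$background_hits / tab$background_size)
})

test_that("uniform annotations rarely reach the FDR tier", {
  set.seed(50)
  genes <- sprintf("g%03d", 1:500)
  asg <- data.frame(gene = genes,
                    code = sample(c("0110", "1001", "1111", "0000"), 500,
                                  replace = TRUE),
                    status = "assigned", stringsAsFactors = FALSE)
  gene_v <- character(); term_v <- character()
  for (t in sprintf("t%02d", 1:20)) {
    hit <- runif(500) < 0.1
    gene_v <- c(gene_v, genes[hit])
    term_v <- c(term_v, rep(t, sum(hit)))
  }
  ann <- annotation_set(gene_v, term_v)
  tab <- enrich_pattern_lists(asg, ann)
  expect_lt(mean(tab$tier == "fdr"), 0.10)
})
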