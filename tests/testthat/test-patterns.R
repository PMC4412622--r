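test_that("code enumeration is complete and lexicographic", {
  expect_identical(enumerate_codes(1), c("0", "1"))
  expect_identical(enumerate_codes(2), c("00", "01", "10", "11"))
  c4 <- enumerate_codes(4)
  expect_length(c4, 16L)
  expect_identical(c4, sort(c4))
  expect_error(enumerate_codes(0), "positive")
})

test_that("pre-molt-high genes are consistent with 0110 and fail below the read cutoff", {
  means <- c(IM = 200, EPM = 4000, LPM = 4500, PM = 150)
  P <- make_pmat(molt_stages,
                 sig = cbind(c("IM", "IM", "EPM", "LPM"),
                             c("EPM", "LPM", "PM", "PM")))
  chk <- code_consistent(P, means, "0110")
  expect_true(chk$consistent)
  expect_equal(nrow(chk$violations), 0L)

  means_lo <- c(IM = 200, EPM = 500, LPM = 4500, PM = 150)
  chk2 <- code_consistent(P, means_lo, "0110")
  expect_false(chk2$consistent)
  expect_match(chk2$violations$reason, "minimum-read", all = FALSE)

  # any_high_stage only needs the best high stage over the cutoff
  lenient_thr <- caller_settings(high_stage_rule = "any_high_stage")
  expect_true(code_consistent(P, means_lo, "0110", lenient_thr)$consistent)
})

test_that("inter-molt/post-molt-high evidence assigns 1001", {
  means <- c(IM = 5000, EPM = 300, LPM = 250, PM = 6000)
  P <- make_pmat(molt_stages,
                 sig = cbind(c("IM", "IM", "EPM", "LPM"),
                             c("EPM", "LPM", "PM", "PM")))
  res <- assign_code(P, means)
  expect_equal(res$code, "1001")
  expect_equal(res$status, "assigned")
})

test_that("flat genes split into all-ones and all-zeros by the read cutoff", {
  P <- make_pmat(molt_stages)  # nothing significant
  hi <- assign_code(P, c(IM = 2000, EPM = 1500, LPM = 3000, PM = 1200))
  expect_equal(hi$code, "1111")
  expect_equal(hi$status, "assigned")
  lo <- assign_code(P, c(IM = 5, EPM = 5, LPM = 5, PM = 5))
  expect_equal(lo$code, "0000")
  expect_equal(lo$status, "low")
  # mixed threshold status with no significance still falls to all-zeros
  mid <- assign_code(P, c(IM = 2000, EPM = 5, LPM = 5, PM = 5))
  expect_equal(mid$code, "0000")
  expect_equal(mid$status, "low")
})

test_that("a fully graded profile fits no binary code and goes grey", {
  means <- c(IM = 1000, EPM = 2000, LPM = 4000, PM = 8000)
  P <- make_pmat(molt_stages, sig = t(combn(molt_stages, 2)))
  for (code in setdiff(enumerate_codes(4), c("0000", "1111"))) {
    expect_false(code_consistent(P, means, code)$consistent)
  }
  res <- assign_code(P, means)
  expect_equal(res$status, "grey")
  expect_true(is.na(res$code))
  expect_equal(res$n_significant_pairs, 6L)
})

test_that("lenient mode can match several codes and reports the multiplicity", {
  means <- c(IM = 9000, EPM = 6000, LPM = 3000, PM = 1500)
  P <- make_pmat(molt_stages, sig = t(combn(molt_stages, 2)))
  len <- caller_settings(consistency = "lenient")
  expect_true(code_consistent(P, means, "1000", len)$consistent)
  expect_true(code_consistent(P, means, "1100", len)$consistent)
  res <- assign_code(P, means, len)
  expect_equal(res$status, "grey")
  expect_gte(res$n_consistent_codes, 2L)
})

test_that("strict mode admits at most one mixed code on every topology", {
  inst <- uniqueness_instances()
  st <- caller_settings()
  base_means <- c(1000, 2000, 4000, 8000)
  mixed <- setdiff(enumerate_codes(4), c("0000", "1111"))
  for (g in 0:63) {
    sig_pairs <- inst$pairs[bitwAnd(g, 2^(0:5)) > 0, , drop = FALSE]
    for (r in seq_len(nrow(inst$perms))) {
      means <- setNames(base_means[inst$perms[r, ]], molt_stages)
      P <- make_pmat(molt_stages,
                     sig = cbind(molt_stages[sig_pairs[, 1]],
                                 molt_stages[sig_pairs[, 2]]))
      n_ok <- sum(vapply(mixed, function(cd) {
        code_consistent(P, means, cd, st)$consistent
      }, logical(1)))
      expect_lte(n_ok, 1L)
    }
  }
})

test_that("shrinking alpha never creates new codes under the high-low rule", {
  # the high-versus-low condition alone (lenient mode) is monotone in alpha
  set.seed(23)
  for (i in 1:40) {
    means <- setNames(exp(runif(4, log(100), log(10000))), molt_stages)
    P <- make_pmat(molt_stages)
    pv <- runif(6)
    P[lower.tri(P)] <- 0
    pairs <- t(combn(4, 2))
    for (r in 1:6) {
      P[pairs[r, 1], pairs[r, 2]] <- pv[r]
      P[pairs[r, 2], pairs[r, 1]] <- pv[r]
    }
    small <- caller_settings(alpha = 0.01, consistency = "lenient")
    large <- caller_settings(alpha = 0.10, consistency = "lenient")
    for (cd in setdiff(enumerate_codes(4), c("0000", "1111"))) {
      ok_small <- code_consistent(P, means, cd, small)$consistent
      ok_large <- code_consistent(P, means, cd, large)$consistent
      expect_true(!ok_small || ok_large)
    }
  }
})

test_that("raising the read cutoff only demotes, never promotes", {
  set.seed(24)
  for (i in 1:40) {
    means <- setNames(exp(runif(4, log(100), log(10000))), molt_stages)
    k <- sample(0:6, 1)
    pairs <- t(combn(4, 2))
    sig <- pairs[sample(6, k), , drop = FALSE]
    P <- make_pmat(molt_stages,
                   sig = cbind(molt_stages[sig[, 1]], molt_stages[sig[, 2]]))
    lo <- assign_code(P, means, caller_settings(min_reads = 500))
    hi <- assign_code(P, means, caller_settings(min_reads = 3000))
    hi_mixed <- hi$status == "assigned" && grepl("0", hi$code) &&
      grepl("1", hi$code)
    lo_mixed <- lo$status == "assigned" && grepl("0", lo$code) &&
      grepl("1", lo$code)
    expect_true(!hi_mixed || (lo_mixed && lo$code == hi$code))
  }
})

test_that("assignments partition the gene set and abundance conserves it", {
  cfg <- planted_recovery_cfg(400L)
  sim <- simulate_counts(cfg)
  pr <- run_pairwise(sim$counts, sim$design)
  asg <- call_patterns(pr)
  expect_equal(nrow(asg), 400L)
  expect_true(all(asg$status %in% c("assigned", "grey", "low")))
  expect_true(all(is.na(asg$code) == (asg$status == "grey")))
  expect_true(all(asg$code[asg$status == "low"] == "0000"))
  ab <- pattern_abundance(asg)
  expect_equal(sum(ab$count), 400L)
  expect_true(all(diff(ab$count) <= 0))  # most to least abundant
  expect_identical(ab$rank, seq_len(nrow(ab)))
})

test_that("planted proportions are recovered among non-grey genes", {
  cfg <- sim_config(n_genes = 1000L, stages = molt_stages,
                    replicates = c(3L, 3L, 3L, 3L),
                    code_proportions = c("0110" = 0.3, "1001" = 0.2,
                                         "1111" = 0.5),
                    fold_change = 8, dispersion = 0.05,
                    baseline_meanlog = log(3000), baseline_sdlog = 0.3,
                    seed = 101L)
  sim <- simulate_counts(cfg)
  asg <- call_patterns(run_pairwise(sim$counts, sim$design))
  ab <- pattern_abundance(asg)
  keep <- ab$code != "grey"
  frac <- setNames(ab$count[keep] / sum(ab$count[keep]), ab$code[keep])
  for (cd in c("0110", "1001", "1111")) {
    expect_lt(abs(frac[[cd]] - cfg$code_proportions[[cd]]), 0.1)
  }
})

test_that("relabelling stages permutes the assigned codes identically", {
  cfg <- sim_config(n_genes = 200L, stages = molt_stages,
                    replicates = c(2L, 2L, 2L, 2L),
                    code_proportions = c("0110" = 0.3), fold_change = 8,
                    dispersion = 0.05, seed = 31L)
  sim <- simulate_counts(cfg)
  pr <- run_pairwise(sim$counts, sim$design)
  asg <- call_patterns(pr)

  perm <- c(3L, 1L, 4L, 2L)
  d2 <- stage_design(sim$design$stages[perm], sim$design$sample_to_stage)
  pr2 <- run_pairwise(sim$counts, d2)
  asg2 <- call_patterns(pr2)

  permute_code <- function(code) {
    ifelse(is.na(code), NA_character_,
           vapply(strsplit(code, ""), function(b) {
             paste(b[perm], collapse = "")
           }, character(1)))
  }
  expect_identical(asg2$code, permute_code(asg$code))
  expect_identical(asg2$status, asg$status)
})

test_that("assignment tables round-trip with codes kept as strings", {
  asg <- data.frame(gene = c("g1", "g2", "g3"),
                    code = c("0110", NA, "0000"),
                    status = c("assigned", "grey", "low"),
                    stage_mean_IM = c(10, 20, 1),
                    stage_mean_PM = c(5000, 30, 2),
                    n_consistent_codes = c(1L, 0L, 0L),
                    n_significant_pairs = c(4L, 2L, 0L),
                    stringsAsFactors = FALSE)
  class(asg) <- c("pattern_assignments", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(asg, f)
  back <- read_assignments(f)
  expect_identical(back$code, c("0110", NA, "0000"))
  expect_identical(attr(back, "stages"), c("IM", "PM"))

  d <- withr::local_tempdir()
  files <- write_pattern_lists(asg, d)
  expect_true(file.exists(file.path(d, "pattern_0110.tsv")))
  lst <- read.table(file.path(d, "pattern_0110.tsv"), header = TRUE)
  expect_equal(lst$gene, "g1")
})
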