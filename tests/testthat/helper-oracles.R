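# Independent oracles and small fixture builders shared across test files.
# The oracles deliberately avoid the code paths (and, where possible, the
# library calls) of the implementation they check.

# Conditional binomial oracle for the Poisson limit of the NB exact test:
# given total K and condition weights sA, sB, the split kA | K is
# Binomial(K, sA / (sA + sB)); the two-sided p sums binomial probabilities
# no larger than the observed one.
binom_cond_oracle <- function(kA, K, sA, sB) {
  d <- dbinom(0:K, K, sA / (sA + sB))
  min(1, sum(d[d <= d[kA + 1L] * (1 + 1e-7)]))
}

# Upper-tail hypergeometric by direct enumeration of binomial coefficients
# (no phyper): P(X >= k) drawing n from N with m successes.
hyper_tail_oracle <- function(k, m, N, n) {
  js <- k:min(m, n)
  sum(exp(lchoose(m, js) + lchoose(N - m, n - js) - lchoose(N, n)))
}

# Symmetric p-value matrix over stages: `sig` is a two-column matrix of
# stage-index pairs that are significant (p = p_sig), all others p_ns.
make_pmat <- function(stages, sig = NULL, p_sig = 0.001, p_ns = 0.8) {
  S <- length(stages)
  P <- matrix(p_ns, S, S, dimnames = list(stages, stages))
  if (!is.null(sig)) {
    for (r in seq_len(nrow(sig))) {
      P[sig[r, 1L], sig[r, 2L]] <- p_sig
      P[sig[r, 2L], sig[r, 1L]] <- p_sig
    }
  }
  diag(P) <- NA_real_
  P
}

# A tiny deterministic count matrix with named dims.
toy_counts <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

molt_stages <- c("IM", "EPM", "LPM", "PM")

# Frozen study-condition scenarios used by property and acceptance tests.
null_calibration_cfg <- function(n_genes = 2000L) {
  sim_config(n_genes = n_genes, stages = molt_stages,
             replicates = c(3L, 3L, 3L, 3L),
             code_proportions = c("0000" = 0),
             dispersion = 0.1, baseline_meanlog = log(2500),
             baseline_sdlog = 0.6, seed = 42L)
}

planted_recovery_cfg <- function(n_genes = 1000L) {
  sim_config(n_genes = n_genes, stages = molt_stages,
             replicates = c(3L, 3L, 3L, 3L),
             code_proportions = c("0110" = 0.3, "1001" = 0.2),
             fold_change = 4, dispersion = 0.05,
             baseline_meanlog = log(1500), baseline_sdlog = 0.3,
             seed = 11L)
}

# Enumerate every significance-graph topology over the C(4,2) = 6 stage
# pairs (64 graphs) crossed with every strict ordering of the four stage
# means (24 permutations); used by the uniqueness checks.
uniqueness_instances <- function() {
  pairs <- t(combn(4L, 2L))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1L, function(x) length(unique(x)) == 4L), ,
                 drop = FALSE]
  list(pairs = pairs, perms = perms)
}
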