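# Independent oracles used to cross-check the implementation. These never
# call the code paths they verify.

# Gaussian quadratic discriminant fitted and resubstituted by hand:
# per-class means/covariances, empirical log-priors, explicit log-densities.
oracle_qda_accuracy <- function(x, g) {
  g <- factor(g)
  cls <- levels(g)
  n <- nrow(x)
  stats <- lapply(cls, function(k) {
    xi <- x[g == k, , drop = FALSE]
    list(mu = colMeans(xi), S = stats::cov(xi), lp = log(nrow(xi) / n))
  })
  ld <- sapply(stats, function(s) {
    d <- sweep(x, 2, s$mu)
    Si <- solve(s$S)
    -0.5 * log(det(s$S)) - 0.5 * rowSums((d %*% Si) * d) + s$lp
  })
  mean(cls[max.col(ld)] == as.character(g))
}

# Tanimoto via dense logical vectors (the implementation works on index sets)
oracle_tanimoto <- function(bits_a, bits_b, universe) {
  va <- logical(universe); va[bits_a] <- TRUE
  vb <- logical(universe); vb[bits_b] <- TRUE
  sum(va & vb) / sum(va | vb)
}

# exact one-decimal half-up percentage via integer arithmetic
oracle_hit_rate <- function(n, N) floor((2000 * n + N) / (2 * N)) / 10

# a melt curve guaranteed to earn a given score against a flat-zero control:
# logistic decay from (baseline + amplitude) through the stated midpoint
rule_curve <- function(amplitude, midpoint = 45, baseline = 0,
                       channel = "FAM", ramp = fluoroscreen::default_ramp()) {
  fluoroscreen::melt_curve(
    ramp, baseline + amplitude / (1 + exp((ramp - midpoint) / 3)), channel)
}

flat_curve <- function(level = 0, channel = "FAM",
                       ramp = fluoroscreen::default_ramp()) {
  fluoroscreen::melt_curve(ramp, rep(level, length(ramp)), channel)
}

# small fixed screen design reused by end-to-end tests
small_conditions <- function() {
  data.frame(protein_variant = rep(c("WT", "P301S"), each = 2),
             inducer_id = rep(1:2, 2), stringsAsFactors = FALSE)
}

small_mix <- function() {
  c(pan_binder = 0.1, wt_selective = 0.1, p301s_selective = 0.1,
    monomer_binder = 0.1, bright_artifact = 0.1, inert = 0.5)
}
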