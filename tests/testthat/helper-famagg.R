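# Shared fixtures and small independent oracles, built in code.

# A compact, well-separated cohort configuration for recovery checks.
tiny_config <- function(...) {
  args <- list(n_genes = 60, n_markers_per_subtype = 10,
               sigma = 0.5, family_sizes = rep(1L, 20))
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# All permutations of a vector, one per column (for complete-enumeration
# oracles on tiny label multisets).
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, nrow = 1L))
  out <- lapply(seq_len(n), function(i) {
    rbind(x[i], all_permutations(x[-i]))
  })
  do.call(cbind, out)
}

# Direct (slow) concordance statistic over an ordered label vector split
# into consecutive family blocks of the given sizes.
stat_by_blocks <- function(labels, sizes) {
  idx <- rep.int(seq_along(sizes), sizes)
  sum(vapply(split(labels, idx), function(l) any(duplicated(l)), logical(1)))
}

# Two-sided Fisher p-value by direct enumeration of all 2x2 tables with the
# observed margins: sum of hypergeometric probabilities of tables as or
# less probable than the observed one.
fisher_enum_oracle <- function(a, na, b, nb) {
  k <- a + b                      # first-row margin (subtype count)
  xs <- max(0, k - nb):min(k, na) # feasible counts in group A
  probs <- choose(na, xs) * choose(nb, k - xs) / choose(na + nb, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
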