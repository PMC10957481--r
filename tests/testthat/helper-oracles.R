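# Independent oracles and fixture builders used across the test files.

# Exhaustive two-sided Fisher p via direct binomial-coefficient enumeration
# of every table with the observed margins (independent of dhyper).
fisher_oracle <- function(a, ta, b, tb) {
  k <- a + b
  if (k == 0) return(1)
  x <- max(0, k - tb):min(k, ta)
  logp <- lchoose(ta, x) + lchoose(tb, k - x) - lchoose(ta + tb, k)
  p <- exp(logp)
  p_obs <- p[x == a]
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# Naive reference ssGSEA: explicit per-position running sums, written
# independently of the package implementation but under the same stated
# conventions (average ranks, ties in the ordering broken by gene id).
ssgsea_reference <- function(mat, sig_genes, alpha = 0.25,
                             normalize = TRUE) {
  es <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-r, rownames(mat))
    genes <- rownames(mat)[ord]
    rk <- r[ord]
    in_set <- genes %in% sig_genes
    n_in <- sum(in_set)
    n_out <- length(genes) - n_in
    denom_in <- sum(rk[in_set]^alpha)
    run_in <- 0
    run_out <- 0
    total <- 0
    for (i in seq_along(genes)) {
      if (in_set[i]) run_in <- run_in + rk[i]^alpha / denom_in
      else run_out <- run_out + 1 / n_out
      total <- total + (run_in - run_out)
    }
    es[j] <- total
  }
  if (normalize && ncol(mat) > 1) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

# Sample builder with explicit ids (productive by construction).
make_sample <- function(counts, patient = "P1", visit = "C0D1",
                        ids = NULL) {
  repertoire_sample(patient, visit, counts, rearrangement_id = ids)
}

# Write a small AIRR TSV fixture from vectors.
write_airr_fixture <- function(path, nt, aa, v, j, count,
                               productive = NULL) {
  tab <- data.frame(
    sequence_id = seq_along(nt), junction = nt, junction_aa = aa,
    v_call = v, j_call = j, duplicate_count = count
  )
  if (!is.null(productive)) tab$productive <- productive
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
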