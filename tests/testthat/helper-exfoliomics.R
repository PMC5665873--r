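# shared fixtures, all built in code

# small default-structured simulation (cheap enough for unit tests)
small_sim <- function(seed = 11, n_genes = 600, hk = 100) {
  simulate_counts(simulation_params(n_genes = n_genes, hk_gene_count = hk,
                                    seed = seed))
}

# counts with equal column sums so library equalization is the identity
balanced_counts <- function(gene1, filler_total = 1000) {
  stopifnot(all(gene1 <= filler_total))
  m <- rbind(gene1, filler_total - gene1)
  rownames(m) <- c("gA", "gB")
  colnames(m) <- paste0("s", seq_along(gene1))
  storage.mode(m) <- "integer"
  m
}

# independent enumeration oracle for the conditional NB two-sided p-value
oracle_exact_p <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  k <- 0:t
  mu <- t / (n1 + n2)
  lp <- dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
    dnbinom(t - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[k <= s1]), sum(pr[k >= s1])))
}

# independent ANOSIM R for a lower-triangle-ranked distance matrix
oracle_anosim_r <- function(d, g) {
  n <- nrow(d)
  lt <- lower.tri(d)
  rk <- rank(d[lt])
  w <- (g[row(d)[lt]] == g[col(d)[lt]])
  (mean(rk[!w]) - mean(rk[w])) / (n * (n - 1) / 4)
}
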