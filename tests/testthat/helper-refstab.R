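# Shared fixtures and independent brute-force oracles. The oracles implement
# each statistic straight from its definition with explicit loops; they never
# call the package's own vectorized code paths.

fpkm_fixture <- function() {
  read_expression_matrix(refstab_example("candidate_fpkm.tsv"))
}

published_cv_fixture <- function() {
  df <- utils::read.table(refstab_example("candidate_cv_published.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$cv, df$gene)
}

# a ct_matrix straight from a mean-Ct matrix with one group per sample list
make_ct <- function(m, groups = NULL) ct_matrix(m, groups = groups)

# random relative-quantity matrix via random Ct values
random_q <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, 18, 30), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  relative_quantities(make_ct(m))
}

# --- geNorm oracles -------------------------------------------------------

oracle_m_values <- function(q, genes = rownames(q)) {
  out <- numeric(length(genes))
  names(out) <- genes
  for (j in genes) {
    acc <- c()
    for (k in genes) {
      if (j == k) next
      ratios <- numeric(ncol(q))
      for (s in seq_len(ncol(q))) ratios[s] <- log2(q[j, s] / q[k, s])
      acc <- c(acc, stats::sd(ratios))
    }
    out[j] <- mean(acc)
  }
  out
}

oracle_v_series <- function(q, order, threshold = 0.15) {
  k <- length(order)
  v <- numeric(k - 2)
  for (n in 2:(k - 1)) {
    nf_n <- nf_n1 <- numeric(ncol(q))
    for (s in seq_len(ncol(q))) {
      nf_n[s] <- prod(q[order[1:n], s]) ^ (1 / n)
      nf_n1[s] <- prod(q[order[1:(n + 1)], s]) ^ (1 / (n + 1))
    }
    v[n - 1] <- stats::sd(log2(nf_n / nf_n1))
  }
  v
}

# --- NormFinder oracle ----------------------------------------------------
# explicit loops over the variance-decomposition equations

oracle_normfinder <- function(logq, groups) {
  I <- nrow(logq); genes <- rownames(logq)
  glev <- unique(groups); G <- length(glev)
  z <- logq
  for (s in seq_len(ncol(logq))) z[, s] <- logq[, s] - mean(logq[, s])
  s2 <- zbar <- matrix(0, I, G, dimnames = list(genes, glev))
  ng <- integer(G)
  for (g in seq_len(G)) {
    cols <- which(groups == glev[g])
    ng[g] <- length(cols)
    for (i in seq_len(I)) {
      zi <- z[i, cols]
      zbar[i, g] <- mean(zi)
      s2[i, g] <- sum((zi - mean(zi)) ^ 2) / (length(zi) - 1)
    }
  }
  sigma2 <- matrix(0, I, G, dimnames = list(genes, glev))
  for (g in seq_len(G)) {
    for (i in seq_len(I)) {
      sigma2[i, g] <- max(0, (s2[i, g] - sum(s2[, g]) / (I * (I - 1))) * I / (I - 2))
    }
  }
  if (G == 1) return(list(stability = sqrt(sigma2[, 1]), sigma2 = sigma2))
  d <- zbar
  for (i in seq_len(I)) d[i, ] <- zbar[i, ] - mean(zbar[i, ])
  vard <- sigma2
  for (g in seq_len(G)) vard[, g] <- sigma2[, g] / ng[g]
  gamma2 <- max(0, sum(d ^ 2) / ((I - 1) * (G - 1)) - mean(vard))
  stab <- numeric(I)
  for (i in seq_len(I)) {
    terms <- numeric(G)
    for (g in seq_len(G)) {
      w <- if (gamma2 > 0) gamma2 / (gamma2 + vard[i, g]) else 0
      terms[g] <- abs(d[i, g] * w) + sqrt(vard[i, g] * w)
    }
    stab[i] <- mean(terms)
  }
  names(stab) <- genes
  list(stability = stab, sigma2 = sigma2, d = d, gamma2 = gamma2)
}

# --- BestKeeper oracles ---------------------------------------------------

oracle_mad <- function(x) {
  mu <- sum(x) / length(x)
  dev <- 0
  for (xi in x) dev <- dev + abs(xi - mu)
  dev / length(x)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx) ^ 2
    syy <- syy + (y[i] - my) ^ 2
  }
  num / sqrt(sxx * syy)
}

# rank positions of a set of genes in a method's ranking (1 = most stable)
rank_of <- function(ranks, genes) unname(ranks[genes])
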