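# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# all permutations of 1..n as rows
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# two-sided signed-rank p by enumeration of all 2^n sign assignments of
# the observed |differences| (tie-free data assumed)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# two-sided exact Spearman p by enumeration over all n! rank permutations
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  pm <- all_perms(length(x))
  rhos <- apply(pm, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# two-sided Fisher exact p by hypergeometric enumeration with fixed
# margins, minimum-likelihood convention
oracle_fisher_p <- function(tp, fp, tn, fn) {
  r1 <- tp + fn; r2 <- fp + tn; c1 <- tp + fp
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tp, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by brute-force pairwise comparison (U statistic)
oracle_auc <- function(scores, labels, positive = "HG") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
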