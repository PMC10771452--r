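# Independent oracles: straight transcriptions of textbook formulas and
# brute-force enumeration, deliberately sharing no code with the package.

# Chao & Lee ACE, transcribed directly from the estimator definition.
ace_oracle <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  s_ab <- sum(x > cutoff); s_r <- length(rare)
  if (s_r == 0) return(length(x))
  n_r <- sum(rare); f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_r
  g2 <- max(s_r / c_ace *
              sum(sapply(1:cutoff, function(i) i * (i - 1) * sum(rare == i))) /
              (n_r * (n_r - 1)) - 1, 0)
  s_ab + s_r / c_ace + f1 / c_ace * g2
}

# Kruskal-Wallis H with tie correction from first principles.
kw_oracle <- function(v, g) {
  r <- rank(v); N <- length(v)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# All n! permutations of 1..n (row per permutation).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# One-factor PERMANOVA from the distance formulation, with the p value by
# exhaustive enumeration of label permutations.
permanova_oracle <- function(d, groups) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2); k <- length(unique(groups))
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw_of <- function(g) {
    sum(vapply(unique(g), function(u) {
      idx <- which(g == u)
      sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }, 0))
  }
  f_of <- function(g) {
    ssw <- ssw_of(g)
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_of(groups)
  perms <- combinat_perms(n)
  f_perm <- apply(perms, 1, function(ix) f_of(groups[ix]))
  list(f = f_obs, ss = sst - ssw_of(groups),
       p_exact = mean(f_perm >= f_obs - 1e-12))
}

# Welch's t from the definition.
welch_oracle <- function(x, y) {
  se2 <- var(x) / length(x) + var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                   (var(y) / length(y))^2 / (length(y) - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}
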