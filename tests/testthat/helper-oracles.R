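# Independent oracles used to validate the implementation. Each one solves
# the same problem by a different route (proximal gradient, brute-force
# enumeration, direct linear algebra) and is deliberately slow and simple.

# Proximal-gradient (ISTA) solver for
#   (1/2n) ||y - X b||^2 + lambda ||b||_1
# run to a tight fixed point; independent of the coordinate-descent path.
lasso_prox_oracle <- function(X, y, lambda, tol = 1e-12, max_iter = 5e5) {
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) L <- 1
  step <- 1 / L
  b <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    g <- as.numeric(crossprod(X, X %*% b - y)) / n
    bn <- b - step * g
    bn <- sign(bn) * pmax(abs(bn) - lambda * step, 0)
    if (max(abs(bn - b)) < tol) {
      b <- bn
      break
    }
    b <- bn
  }
  b
}

# Expected dosage at a position between two homozygous flanks, by
# enumerating the two Bernoulli recombination events of the two-state
# chain (left flank state sl at distance d1 cM, right flank sr at d2 cM).
dosage_enum_oracle <- function(sl, sr, d1_cm, d2_cm) {
  r1 <- 0.5 * tanh(d1_cm / 50)
  r2 <- 0.5 * tanh(d2_cm / 50)
  num <- den <- 0
  for (x1 in 0:1) {
    for (x2 in 0:1) {
      q <- sl * (1 - 2 * x1)
      if (sr != q * (1 - 2 * x2)) next
      pr <- (if (x1) r1 else 1 - r1) * (if (x2) r2 else 1 - r2)
      num <- num + q * pr
      den <- den + pr
    }
  }
  num / den
}

# Type-7 empirical quantile computed from first principles on a sorted copy.
quantile_sort_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small log-expression matrix with a given number of planted genes whose
# expression is linearly coupled to the trait (plus independent null genes).
make_planted_expr <- function(n_genes, n_samples, n_planted, coupling = 1.2,
                              noise_sd = 0.5) {
  y <- rnorm(n_samples)
  z <- (y - mean(y)) / sd(y)
  expr <- matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
  if (n_planted > 0) {
    expr[seq_len(n_planted), ] <- expr[seq_len(n_planted), , drop = FALSE] +
      outer(coupling * rep_len(c(1, -1), n_planted), z)
  }
  rownames(expr) <- sprintf("g%05d", seq_len(n_genes))
  colnames(expr) <- sprintf("S%02d", seq_len(n_samples))
  list(expr = expr, trait = setNames(y, colnames(expr)))
}
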