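# Independent brute-force oracles, deliberately coded as plain loops over
# the definitions so they share no code path with the package internals.

# Mean, over all other genes, of sd(log2 ratio) -- direct double loop.
oracleGeNormM <- function(q) {
  n <- nrow(q)
  M <- numeric(n)
  for (j in seq_len(n)) {
    vs <- numeric(0)
    for (k in seq_len(n)) {
      if (k == j) next
      vs <- c(vs, sd(log2(q[j, ] / q[k, ])))
    }
    M[j] <- mean(vs)
  }
  names(M) <- rownames(q)
  M
}

# V(n, n+1) from first principles: per-sample geometric-mean normalization
# factors of the top-n and top-(n+1) genes, then sd of the log2 ratio.
oracleVCurve <- function(q, ranking) {
  N <- nrow(q)
  out <- numeric(0)
  for (n in 2:(N - 1)) {
    nf_n <- apply(q[ranking[1:n], , drop = FALSE], 2,
                  function(col) prod(col)^(1 / length(col)))
    nf_n1 <- apply(q[ranking[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / length(col)))
    out <- c(out, sd(log2(nf_n / nf_n1)))
  }
  names(out) <- paste0("V", 2:(N - 1), "/", 3:N)
  out
}

# Method-of-moments NormFinder oracle, scalar loops throughout.
oracleNormFinder <- function(ct, groups, ampFactor = 2) {
  k <- nrow(ct)
  y <- -ct * log2(ampFactor)
  # sample centering
  z <- y
  for (j in seq_len(ncol(y))) z[, j] <- y[, j] - mean(y[, j])
  gl <- sort(unique(groups))
  G <- length(gl)
  zbar <- v <- sigma2 <- matrix(0, k, G)
  ng <- numeric(G)
  for (gi in seq_len(G)) {
    cols <- which(groups == gl[gi])
    ng[gi] <- length(cols)
    for (i in seq_len(k)) {
      zbar[i, gi] <- mean(z[i, cols])
      v[i, gi] <- var(z[i, cols])
    }
  }
  for (gi in seq_len(G)) {
    vbar <- mean(v[, gi])
    for (i in seq_len(k)) {
      sigma2[i, gi] <- max(k / (k - 2) * (v[i, gi] - vbar / (k - 1)), 0)
    }
  }
  if (G == 1) {
    stab <- sqrt(sigma2[, 1])
    names(stab) <- rownames(ct)
    return(stab)
  }
  stab <- numeric(k)
  for (i in seq_len(k)) {
    overall <- sum(zbar[i, ] * ng) / sum(ng)
    d <- zbar[i, ] - overall
    sv <- sigma2[i, ] / ng
    gamma2 <- max(sum(d^2) / (G - 1) - mean(sv), 0)
    acc <- 0
    for (gi in seq_len(G)) {
      shrink <- if (gamma2 + sv[gi] > 0) gamma2 / (gamma2 + sv[gi]) else 0
      acc <- acc + abs(d[gi] * shrink) + sqrt(sv[gi])
    }
    stab[i] <- acc / G
  }
  names(stab) <- rownames(ct)
  stab
}

# Two-pass brute-force candidate screen: per-gene loop with explicit window
# and CV checks.
oracleScreen <- function(m, lo, hi, cvMax) {
  keep <- character(0)
  for (i in seq_len(nrow(m))) {
    vals <- m[i, ]
    inside <- TRUE
    for (v in vals) if (v < lo || v > hi) inside <- FALSE
    if (!inside) next
    cv <- sd(vals) / mean(vals)
    if (cv <= cvMax) keep <- c(keep, rownames(m)[i])
  }
  keep
}

randomCtMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  matrix(runif(nGenes * nSamples, 20, 30), nGenes, nSamples,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)), NULL))
}
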