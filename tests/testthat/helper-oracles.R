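# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# direct numerical minimization of the square-loss margin objective over
# (w, b) in input space (linear kernel)
bruteForceSquareLossJ <- function(X, y, C) {
  d <- ncol(X)
  obj <- function(p) {
    w <- p[seq_len(d)]; b <- p[d + 1]
    f <- as.numeric(X %*% w) + b
    0.5 * sum(w^2) + C / 2 * sum((1 - y * f)^2)
  }
  o <- stats::optim(rep(0, d + 1), obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  o$value
}

# exhaustive minimum of sum((s + b - y)^2) over all sign vectors with
# |sum(y)| <= l (parity rounded outward) and the continuously optimal b
bruteForceRefineObjective <- function(s, l) {
  n <- length(s)
  leff <- max(l, (n + l) %% 2)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    y <- 2 * ((m %/% 2^(0:(n - 1))) %% 2) - 1
    if (abs(sum(y)) > leff) next
    b <- mean(y - s)
    best <- min(best, sum((s + b - y)^2))
  }
  best
}

# all permutations of 1..k via Heap's algorithm (iterative flavour,
# independent of the recursive enumeration inside the package)
heapPermutations <- function(k) {
  a <- seq_len(k)
  out <- list(a)
  c_ <- rep(1L, k)
  i <- 1L
  while (i <= k) {
    if (c_[i] < i) {
      if (i %% 2L == 1L) a[c(1L, i)] <- a[c(i, 1L)]
      else a[c(c_[i], i)] <- a[c(i, c_[i])]
      out[[length(out) + 1L]] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else { c_[i] <- 1L; i <- i + 1L }
  }
  out
}

# agreement of a labeling pair up to global sign
signAgreement <- function(y, truth) max(mean(y == truth), mean(y == -truth))

blobTruth <- function(gd) ifelse(gd$labels == 1, 1, -1)
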