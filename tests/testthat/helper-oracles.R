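# Independent brute-force oracles, deliberately written with explicit
# loops and textbook formulas, never sharing code with the package.

# Per-voxel Pearson chi-square from the 2x2 contingency table.
bruteChiSquare <- function(binary, term) {
  binary <- as.matrix(binary)
  out <- matrix(NA_real_, ncol(binary), 2)
  for (v in seq_len(ncol(binary))) {
    a <- sum(binary[term, v]); b <- sum(!binary[term, v])
    c_ <- sum(binary[!term, v]); d <- sum(!binary[!term, v])
    n <- a + b + c_ + d
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    if (den == 0) {
      out[v, ] <- c(0, 1)
    } else {
      chi2 <- n * (a * d - b * c_)^2 / den
      out[v, ] <- c(chi2, pchisq(chi2, 1, lower.tail = FALSE))
    }
  }
  out
}

# Benjamini-Hochberg step-up, straight from its definition.
bruteBh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(n)) if (p[o[i]] <= i / n * q) k <- i
  rej <- logical(n)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Smoothed-idf TF-IDF with L2 row normalization, dense loops only.
bruteTfidf <- function(counts) {
  n <- nrow(counts)
  w <- matrix(0, n, ncol(counts))
  for (t in seq_len(ncol(counts))) {
    df <- sum(counts[, t] > 0)
    idf <- log((1 + n) / (1 + df)) + 1
    for (d in seq_len(n)) w[d, t] <- counts[d, t] * idf
  }
  for (d in seq_len(n)) {
    nrm <- sqrt(sum(w[d, ]^2))
    if (nrm > 0) w[d, ] <- w[d, ] / nrm
  }
  w
}

# Voxels where the chi-square approximation is adequate for a given
# activation margin: every expected 2x2 cell count at least 5.
adequateVoxels <- function(binary, termPresent) {
  act <- Matrix::colSums(binary)
  n <- nrow(binary)
  nT <- sum(termPresent)
  pmin(act, n - act) * min(nT, n - nT) / n >= 5
}
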