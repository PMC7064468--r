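# Independent oracle implementations used to cross-check the package.
# Written deliberately as plain loops, separate from the vectorised code
# paths inside R/.

# Lin-Binns superiority index, loop form
oraclePi <- function(X) {
  E <- ncol(X)
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    s <- 0
    for (j in seq_len(E)) s <- s + (X[i, j] - max(X[, j]))^2
    out[i] <- s / (2 * E)
  }
  out
}

# Eberhart-Russell slope and deviation via per-line lm()
oracleER <- function(X) {
  I_j <- colMeans(X) - mean(colMeans(X))
  b <- numeric(nrow(X)); dev <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(X))) {
      num <- num + X[i, j] * I_j[j]
      den <- den + I_j[j]^2
    }
    b[i] <- num / den
    fit <- mean(X[i, ]) + b[i] * I_j
    dev[i] <- mean((X[i, ] - fit)^2)
  }
  list(slope = b, dev = dev)
}

# D-prime point estimate by the direct textbook formula
oracleDprime <- function(n11, n12, n21, n22) {
  n <- n11 + n12 + n21 + n22
  p <- (n11 + n12) / n; q <- (n11 + n21) / n
  D <- n11 / n - p * q
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else
          min(p * q, (1 - p) * (1 - q))
  abs(D) / dmax
}

# brute-force likelihood-grid CI for |D'|, plain loops
oracleDprimeCI <- function(n11, n12, n21, n22, conf = 0.95, step = 0.01) {
  n <- n11 + n12 + n21 + n22
  p <- (n11 + n12) / n; q <- (n11 + n21) / n
  D <- n11 / n - p * q
  s <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else
          min(p * q, (1 - p) * (1 - q))
  grid <- seq(0, 1, by = step)
  lik <- numeric(length(grid))
  for (g in seq_along(grid)) {
    Dg <- s * grid[g] * dmax
    pr <- c(p * q + Dg, p * (1 - q) - Dg, (1 - p) * q - Dg,
            (1 - p) * (1 - q) + Dg)
    pr[pr < 1e-10] <- 1e-10
    lik[g] <- exp(sum(c(n11, n12, n21, n22) * log(pr)) -
                  sum(c(n11, n12, n21, n22) * log(0.25)))
  }
  cum <- cumsum(lik) / sum(lik)
  a <- (1 - conf) / 2
  lo <- grid[min(which(cum >= a))]
  hi <- grid[min(which(cum >= 1 - a))]
  c(lo = lo, hi = hi)
}

# pair classification by the stated rule
oracleClassify <- function(lo, hi) {
  if (lo >= 0.6 && hi >= 0.95) "strong LD"
  else if (hi < 0.9) "strong recombination"
  else "inconclusive"
}

# exhaustive-enumeration block finder on a small single-chromosome panel:
# classifies every pair with the oracle CI, enumerates every contiguous
# span, applies the 95%-strong-LD-of-informative rule, then greedy
# longest-first / leftmost acceptance
oracleBlocks <- function(codes) {
  p <- ncol(codes)
  klass <- matrix(NA_character_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      gi <- codes[, i]; gj <- codes[, j]
      ok <- !is.na(gi) & !is.na(gj) & gi != 0 & gj != 0
      n11 <- sum(gi[ok] == 1 & gj[ok] == 1)
      n12 <- sum(gi[ok] == 1 & gj[ok] == -1)
      n21 <- sum(gi[ok] == -1 & gj[ok] == 1)
      n22 <- sum(gi[ok] == -1 & gj[ok] == -1)
      n <- n11 + n12 + n21 + n22
      pA <- if (n > 0) (n11 + n12) / n else 0
      pB <- if (n > 0) (n11 + n21) / n else 0
      if (n < 2 || pA %in% c(0, 1) || pB %in% c(0, 1)) {
        klass[i, j] <- "inconclusive"
      } else {
        ci <- oracleDprimeCI(n11, n12, n21, n22)
        klass[i, j] <- oracleClassify(ci["lo"], ci["hi"])
      }
    }
  }
  cand <- list()
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      cc <- character(0)
      for (i in a:(b - 1)) for (j in (i + 1):b) cc <- c(cc, klass[i, j])
      inf <- cc[cc != "inconclusive"]
      if (length(inf) >= 1 && sum(inf == "strong LD") / length(inf) >= 0.95)
        cand[[length(cand) + 1]] <- c(a, b)
    }
  }
  if (!length(cand)) return(matrix(numeric(0), 0, 2))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand[, 2] - cand[, 1]), cand[, 1]), , drop = FALSE]
  used <- rep(FALSE, p); acc <- list()
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (!any(used[a:b])) { used[a:b] <- TRUE; acc[[length(acc) + 1]] <- c(a, b) }
  }
  acc <- do.call(rbind, acc)
  acc[order(acc[, 1]), , drop = FALSE]
}

# rule-table classifier for consistency groups, written from the verbal
# definitions, taking a logical significance matrix (EYT x env)
oracleGroup <- function(sig) {
  eyts <- which(apply(sig, 1, any))
  if (length(eyts) == 0) return(NA_integer_)
  if (length(eyts) == 1) return(1L)
  envs <- which(apply(sig, 2, any))
  if (length(envs) == 1) return(2L)
  multi <- vapply(eyts, function(i) sum(sig[i, ]) >= 2, logical(1))
  if (all(multi)) return(3L)
  4L
}
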