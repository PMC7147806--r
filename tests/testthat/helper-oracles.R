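# independent oracles, deliberately implemented apart from the package

# minlike two-sided exact binomial by full enumeration of point masses
oracleBinom <- function(k, n, p0) {
  pm <- dbinom(0:n, n, p0)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}

# factorial-number-system unranking: the r-th (0-based) permutation of n
unrankPerm <- function(r, n) {
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    j <- r %/% f
    r <- r %% f
    out[i] <- avail[j + 1]
    avail <- avail[-(j + 1)]
  }
  out
}

# exact permutation distribution of the target-class proportion, by
# iterating every pairing of second ends across pairs
oraclePermDist <- function(a1, a2, chromMap, target, level) {
  n <- length(a1)
  props <- numeric(factorial(n))
  tg <- sort(target)
  for (r in seq_len(factorial(n)) - 1) {
    s2 <- a2[unrankPerm(r, n)]
    keep <- switch(level,
      all = rep(TRUE, n),
      no_intra_arm = a1 != s2,
      no_intra_chromosome = chromMap[a1] != chromMap[s2])
    hit <- keep & (pmin(a1, s2) == tg[1] & pmax(a1, s2) == tg[2])
    props[r + 1] <- if (sum(keep)) sum(hit) / sum(keep) else 0
  }
  props
}

# Welch two-sample t from the textbook formula
oracleWelch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Fisher two-sided p for a 2x2 table by hypergeometric enumeration
oracleFisher <- function(tab) {
  k1 <- tab[1, 1]; n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  m <- sum(tab[, 1])
  support <- max(0, m - n2):min(m, n1)
  pm <- dhyper(support, n1, n2, m)
  pobs <- dhyper(k1, n1, n2, m)
  sum(pm[pm <= pobs * (1 + 1e-7)])
}

# fine-grid Gaussian-KDE valley between the first two modes, by direct
# summation of kernels (independent of stats::density's FFT pipeline)
oracleKdeValley <- function(x, bw, nGrid = 4001) {
  grid <- seq(0, max(x), length.out = nGrid)
  y <- vapply(grid, function(g) mean(dnorm((g - x) / bw)) / bw,
              numeric(1))
  m <- length(y)
  mode <- c(y[1] > y[2],
            y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
            y[m] > y[m - 1])
  mode[y < 0.05 * max(y)] <- FALSE
  pk <- which(mode)
  if (length(pk) < 2) return(NA_real_)
  lo <- pk[1]; hi <- pk[2]
  grid[lo + which.min(y[(lo + 1):(hi - 1)])]
}

# per-bin mean of a bedGraph-style coverage by explicit interval overlap
oracleBinMean <- function(cov, arm, lo, hi) {
  sel <- as.character(GenomeInfoDb::seqnames(cov)) == arm
  s <- BiocGenerics::start(cov)[sel]; e <- BiocGenerics::end(cov)[sel]
  v <- cov$score[sel]
  tot <- 0
  for (i in seq_along(s)) {
    ov <- min(e[i], hi) - max(s[i], lo) + 1
    if (ov > 0) tot <- tot + ov * v[i]
  }
  tot / (hi - lo + 1)
}
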