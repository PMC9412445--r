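# Independent oracles used to check the implementation. Each recomputes
# its quantity from first principles, sharing no code with R/.

# Hamming-tapered one-sided periodogram band powers of a single window,
# via an explicit DFT sum (no fft()).
oracleWindowBandPowers <- function(x, fs, bands, floorVal = 1e-12) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  y <- w * x
  k <- 0:(n - 1)
  E <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(E %*% y)
  f <- k * fs / n
  p <- abs(X)^2 / (n * sum(w^2))
  side <- ifelse(f == 0 | f == fs / 2, 1, 2)
  sapply(seq_len(nrow(bands)), function(b) {
    sel <- f <= fs / 2 & f >= bands$low[b] & f <= bands$high[b]
    log10(max(sum(p[sel] * side[sel]), floorVal))
  })
}

# Closed-form two-class Gaussian discriminant: per-class linear scores
# delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k, predicting
# internal iff delta_int > delta_ext (ties to external).
oracleLdaPredict <- function(xtr, ytr, xte) {
  x1 <- xtr[ytr == "external", , drop = FALSE]
  x2 <- xtr[ytr == "internal", , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  n <- nrow(xtr)
  S <- ((nrow(x1) - 1) * stats::cov(x1) +
          (nrow(x2) - 1) * stats::cov(x2)) / (n - 2)
  Si <- solve(S)
  d1 <- xte %*% Si %*% mu1 - as.numeric(t(mu1) %*% Si %*% mu1) / 2 +
    log(nrow(x1) / n)
  d2 <- xte %*% Si %*% mu2 - as.numeric(t(mu2) %*% Si %*% mu2) / 2 +
    log(nrow(x2) / n)
  ifelse(as.vector(d2) > as.vector(d1), "internal", "external")
}

# Brute-force sliding majority vote: explicit window recount per index.
oracleSlidingPause <- function(preds, n = 40, threshold = 0.6) {
  need <- ceiling(threshold * n)
  vapply(seq_along(preds), function(i) {
    if (i < n) return(FALSE)
    sum(preds[(i - n + 1):i] == "internal") >= need
  }, logical(1))
}

# Run-length blocks by explicit scan.
oracleBlocks <- function(paused) {
  starts <- which(c(TRUE, paused[-1] != paused[-length(paused)]))
  ends <- c(starts[-1] - 1L, length(paused))
  data.frame(len = ends - starts + 1L, paused = paused[starts])
}

# Majority-coverage label of a window (t - 1, clipped at 0) .. t against
# a plan, by fine-grained midpoint sampling.
oracleLabel <- function(t, plan, step = 1e-3) {
  lo <- max(t - 1, 0)
  mids <- seq(lo + step / 2, t - step / 2, by = step)
  st <- sapply(mids, function(m) {
    i <- which(plan$start_s <= m & m < plan$end_s)
    if (length(i)) plan$state[i[1]] else NA
  })
  st <- st[!is.na(st)]
  if (!length(st)) return("none")
  ni <- sum(st == "internal"); ne <- sum(st == "external")
  if (ni > ne) "internal" else "external"
}

# Textbook Pearson r and its t-test p-value.
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Small labeled Gaussian dataset for classifier tests.
makeGaussianData <- function(n, d, sep, seed) {
  withr::with_seed(seed, {
    y <- rep(c("external", "internal"), length.out = n)
    x <- matrix(rnorm(n * d), n, d)
    x[y == "internal", 1] <- x[y == "internal", 1] + sep
    colnames(x) <- paste0("f", seq_len(d))
    list(x = x, y = y)
  })
}

# End-to-end synthetic accuracy at a given alpha shift scale (shuffled
# 5-fold CV on a frame-level session).
endToEndAccuracy <- function(shiftScale, seed, durS = 50) {
  plan <- makeSessionPlan(2, durS / 4, durS / 4, seed = seed)
  params <- generatorParams(internalShift = shiftScale * c(0.5, 1/6, 1/6, 1))
  sess <- synthesizeBandPower(plan, params, seed = seed)
  meanAccuracy(crossValidate(sess, seed = seed))
}
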