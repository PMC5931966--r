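# Brute-force 1-D Landweber loop, coded independently of the package's
# solver (explicit per-sample convolution loops, replicate boundary).
oracle_landweber_1d <- function(y, k, alpha, iters, floor = -1024) {
  n <- length(y)
  r <- (length(k) - 1) / 2
  conv1 <- function(x, kk) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_along(kk)) {
        ii <- i - (j - r - 1)
        ii <- min(max(ii, 1), n)
        acc <- acc + kk[j] * x[ii]
      }
      out[i] <- acc
    }
    out
  }
  x <- y
  for (it in seq_len(iters)) {
    e <- y - conv1(x, k)
    x <- x + alpha * conv1(e, rev(k))
    x[x < floor] <- floor
  }
  x
}
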