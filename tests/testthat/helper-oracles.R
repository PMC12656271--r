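# Independent brute-force GLCM oracle: enumerates pixel pairs directly and
# computes the eight metrics from the raw pair list. Shares no code with
# the package's co-occurrence implementation.

oracleWindowMetrics <- function(win, dx, dy, symmetric = TRUE) {
  nr <- nrow(win); nc <- ncol(win)
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + dy; c2 <- cc + dx
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      ii <- c(ii, win[r, cc]); jj <- c(jj, win[r2, c2])
      if (symmetric) { ii <- c(ii, win[r2, c2]); jj <- c(jj, win[r, cc]) }
    }
  }
  stopifnot(length(ii) > 0)
  w <- rep(1 / length(ii), length(ii))  # each raw pair has equal weight
  mu_i <- sum(ii * w); mu_j <- sum(jj * w)
  var_i <- sum((ii - mu_i)^2 * w); var_j <- sum((jj - mu_j)^2 * w)
  # entropy needs the aggregated cell probabilities, not raw pair weights
  key <- paste(ii, jj)
  p_cell <- tapply(w, key, sum)
  sds <- sqrt(var_i) * sqrt(var_j)
  c(mean = mu_i,
    var = var_i,
    hom = sum(w / (1 + (ii - jj)^2)),
    con = sum((ii - jj)^2 * w),
    dis = sum(abs(ii - jj) * w),
    et = -sum(p_cell * log(p_cell)),
    sem = sum(p_cell^2),
    cor = if (sds > 0) sum((ii - mu_i) * (jj - mu_j) * w) / sds else 0)
}

oracleSlidingMeans <- function(img, window, dx, dy, symmetric = TRUE,
                               stride = 1) {
  acc <- NULL
  for (r0 in seq(1, nrow(img) - window + 1, by = stride))
    for (c0 in seq(1, ncol(img) - window + 1, by = stride)) {
      m <- oracleWindowMetrics(img[r0:(r0 + window - 1),
                                   c0:(c0 + window - 1)], dx, dy,
                               symmetric)
      acc <- rbind(acc, m)
    }
  colMeans(acc)
}
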