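# Independent oracles used across the suite. Each deliberately avoids the
# package's own code paths.

# brute-force box count: explicit double loop over grid cells
brute_box_count <- function(edge, size) {
  nr <- nrow(edge); nc <- ncol(edge)
  count <- 0L
  for (r0 in seq(1, nr, by = size)) {
    for (c0 in seq(1, nc, by = size)) {
      cell <- edge[r0:min(r0 + size - 1, nr), c0:min(c0 + size - 1, nc)]
      if (any(cell != 0)) count <- count + 1L
    }
  }
  count
}

# AUC as the normalized Mann-Whitney U statistic, from ranks
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified-bootstrap implied z for an AUC difference on paired scores
boot_delong_z <- function(sa, sb, y, B = 1e5, seed = 1) {
  set.seed(seed)
  pos <- which(y == 1); neg <- which(y == 0)
  np <- length(pos); nn <- length(neg)
  auc1 <- function(s)
    mean(outer(s[pos], s[neg], ">") + 0.5 * outer(s[pos], s[neg], "=="))
  d0 <- auc1(sa) - auc1(sb)
  P <- matrix(sample(pos, B * np, replace = TRUE), B)
  N <- matrix(sample(neg, B * nn, replace = TRUE), B)
  acc_a <- acc_b <- numeric(B)
  for (i in 1:np) for (j in 1:nn) {
    acc_a <- acc_a + (sa[P[, i]] > sa[N[, j]]) + 0.5 * (sa[P[, i]] == sa[N[, j]])
    acc_b <- acc_b + (sb[P[, i]] > sb[N[, j]]) + 0.5 * (sb[P[, i]] == sb[N[, j]])
  }
  d0 / sd((acc_a - acc_b) / (np * nn))
}

# fixed 12-subject paired-score fixture (6 controls, 6 cases); scores from
# two correlated logistic-type models of a shared covariate
delong_fixture <- function() {
  list(y = rep(c(0L, 1L), each = 6),
       sa = c(0.506, 0.65, 0.369, 0.288, 0.792, 0.447,
              0.773, 0.397, 0.094, 0.561, 0.482, 0.789),
       sb = c(0.691, 0.53, 0.289, 0.631, 0.709, 0.25,
              0.779, 0.562, 0.073, 0.445, 0.66, 0.748))
}

# Spearman rho from the rank formula (no ties assumed)
spearman_brute <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# chi-square statistic for an r x c table from the textbook formula
chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# ICC(2,1) from the mean-squares formula, written independently
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  ssr <- k * sum((rowMeans(m) - mu)^2)
  ssc <- n * sum((colMeans(m) - mu)^2)
  sse <- sum((m - mu)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Hilbert curve polyline on a 2^order grid (cell centers), via the classic
# iterative d -> (x, y) mapping
hilbert_points <- function(order) {
  n <- 2L^order
  d2xy <- function(d) {
    x <- 0L; y <- 0L; t <- d; s <- 1L
    while (s < n) {
      rx <- bitwAnd(1L, t %/% 2L)
      ry <- bitwAnd(1L, bitwXor(t, rx))
      if (ry == 0L) {
        if (rx == 1L) { x <- s - 1L - x; y <- s - 1L - y }
        tmp <- x; x <- y; y <- tmp
      }
      x <- x + s * rx; y <- y + s * ry
      t <- t %/% 4L; s <- s * 2L
    }
    c(x, y)
  }
  t(vapply(0:(n * n - 1L), d2xy, integer(2)))
}

# small synthetic logistic dataset with known coefficients
sim_logistic <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  eta <- X %*% beta
  y <- rbinom(n, 1, plogis(eta))
  data.frame(y = y, X)
}
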