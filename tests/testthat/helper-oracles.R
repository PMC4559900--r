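# Independent oracles, deliberately naive implementations.

# Two-site DI for q = 2 by zooming 1-D grid search on the second site's
# factor ratio; the first site's factor follows from its marginal. Never
# shares code with the fixed-point implementation.
oracle_di_q2 <- function(W, pi_, pj_) {
  mismatch <- function(s) {
    y <- c(s, 1)
    x <- pi_ / as.vector(W %*% y)
    P <- W * outer(x, y)
    P <- P / sum(P)
    sum(abs(colSums(P) - pj_))
  }
  lo <- 1e-4; hi <- 1e4
  for (round in 1:60) {
    ss <- exp(seq(log(lo), log(hi), length.out = 41))
    b <- which.min(vapply(ss, mismatch, numeric(1)))
    lo <- ss[max(1, b - 1)]; hi <- ss[min(41, b + 1)]
  }
  s <- sqrt(lo * hi)
  y <- c(s, 1)
  x <- pi_ / as.vector(W %*% y)
  P <- W * outer(x, y)
  P <- P / sum(P)
  sum(P * log(P / outer(pi_, pj_)))
}

# brute-force O(M^2 L) reweighting
oracle_weights <- function(mat, theta) {
  M <- nrow(mat); L <- ncol(mat)
  w <- numeric(M)
  for (s in 1:M) {
    nb <- 0
    for (t in 1:M)
      if (sum(mat[s, ] == mat[t, ]) / L >= theta) nb <- nb + 1
    w[s] <- 1 / nb
  }
  w
}

# direct weighted counting of frequencies
oracle_freq <- function(mat, w, lambda, q) {
  M <- nrow(mat); L <- ncol(mat); meff <- sum(w)
  fi <- matrix(lambda / q, L, q)
  for (s in 1:M) for (i in 1:L)
    fi[i, mat[s, i] + 1] <- fi[i, mat[s, i] + 1] + w[s]
  fi <- fi / (lambda + meff)
  fij <- array(lambda / q^2, dim = c(L, L, q, q))
  for (s in 1:M) for (i in 1:L) for (j in 1:L)
    fij[i, j, mat[s, i] + 1, mat[s, j] + 1] <-
      fij[i, j, mat[s, i] + 1, mat[s, j] + 1] + w[s]
  fij <- fij / (lambda + meff)
  list(f_i = fi, f_ij = fij)
}

# exhaustive O(n^2) contact scan
oracle_contacts <- function(X, cutoff) {
  n <- nrow(X)
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (sqrt(sum((X[i, ] - X[j, ])^2)) < cutoff)
      out <- rbind(out, c(i - 1, j - 1))
  out
}

# quaternion-grid rigid superposition: coarse grid over rotation space,
# refined around the best cell. Slow but independent of the SVD route.
oracle_superpose_rmsd <- function(mobile, reference, n_grid = 12) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rmsd_of <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  gr <- seq(-1, 1, length.out = n_grid)
  best <- NULL; bv <- Inf
  for (w in gr) for (x in gr) for (y in gr) for (z in gr) {
    q <- c(w, x, y, z)
    if (sum(q^2) < 1e-6) next
    v <- rmsd_of(q)
    if (v < bv) { bv <- v; best <- q / sqrt(sum(q^2)) }
  }
  width <- 2 / (n_grid - 1)
  for (round in 1:25) {
    gr2 <- seq(-width, width, length.out = 7)
    improved <- FALSE
    for (dw in gr2) for (dx in gr2) for (dy in gr2) for (dz in gr2) {
      q <- best + c(dw, dx, dy, dz)
      if (sum(q^2) < 1e-6) next
      v <- rmsd_of(q)
      if (v < bv - 1e-12) { bv <- v; best <- q / sqrt(sum(q^2)); improved <- TRUE }
    }
    width <- width / 2
  }
  bv
}
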