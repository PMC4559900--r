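#' Sequence reweighting by similarity clustering
#'
#' Down-weights redundant sequences: each sequence gets weight
#' `1 / m`, where `m` is the number of alignment members (itself
#' included) whose fractional identity to it is at least `theta`.
#' The effective sequence count `Meff` is the sum of the weights.
#'
#' @param msa a `coev_msa`.
#' @param theta similarity threshold as a fraction of identical positions
#'   (gaps count as a matchable state). Default 0.8.
#' @return list with `weights` (length M) and `Meff`.
#' @export
compute_weights <- function(msa, theta = 0.8) {
  stopifnot(theta > 0, theta <= 1)
  w <- cpp_seq_weights(msa$sequences, theta)
  list(weights = w, Meff = sum(w))
}

#' Pseudocount-regularised frequency counts
#'
#' Weighted single-site and pairwise amino-acid frequencies with a
#' uniform pseudocount of total mass `lambda`:
#' `f_i(a) = (lambda/q + sum_s w_s d(a, s_i)) / (lambda + Meff)` and the
#' analogous pair expression with `lambda/q^2`. Same-site blocks follow
#' the convention `f_ii(a,b) = d_ab f_i(a)`.
#'
#' @param msa a `coev_msa`.
#' @param weights per-sequence weights from [compute_weights()]; default
#'   uniform.
#' @param lambda pseudocount mass; the conventional mean-field choice is
#'   `lambda = Meff`.
#' @param theta the reweighting threshold to record (metadata only).
#' @return object of class `coev_freq`: `f_i` (L x q), `f_ij`
#'   ((L q) x (L q), block `(i, j)` at rows `i*q + (1:q)`), `weights`,
#'   `Meff`, `lambda`, `theta`, `L`, `q`.
#' @export
compute_frequencies <- function(msa, weights = NULL, lambda = NULL,
                                theta = NA_real_) {
  M <- nrow(msa$sequences)
  L <- ncol(msa$sequences)
  q <- msa$q
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M, all(weights > 0))
  if (is.null(lambda)) lambda <- sum(weights)
  stopifnot(lambda >= 0)
  res <- cpp_frequencies(msa$sequences, weights, lambda, q)
  structure(list(f_i = res$f_i, f_ij = res$f_ij, weights = weights,
                 Meff = res$Meff, lambda = lambda, theta = theta,
                 L = L, q = q),
            class = "coev_freq")
}

#' Mean-field coupling inference
#'
#' Inverts the pseudocount-regularised connected-correlation matrix
#' `C(i,a; j,b) = f_ij(a,b) - f_i(a) f_j(b)` restricted to the q-1
#' non-gap states, yielding couplings `e_ij(a,b) = -(C^-1)` on
#' off-diagonal blocks, zero-padded to q states (gap state fixed to
#' zero: the gauge). Diagonal blocks of the inverse are single-site
#' terms, not couplings, and are discarded.
#'
#' @param freq a `coev_freq` from [compute_frequencies()].
#' @return object of class `coev_coupling`: `e_ij` (4-d array
#'   L x L x q x q) and `C`.
#' @export
invert_mean_field <- function(freq) {
  L <- freq$L; q <- freq$q
  nz <- q - 1L # non-gap states 1..q-1 enter the inverted block
  idx <- as.vector(outer(1:nz, (0:(L - 1)) * q, "+")) + 1L # skip state 0
  C <- freq$f_ij[idx, idx, drop = FALSE]
  fi_flat <- as.vector(t(freq$f_i[, 2:q, drop = FALSE]))
  C <- C - tcrossprod(fi_flat)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is singular; use a positive ",
         "pseudocount (lambda > 0). Underlying error: ",
         conditionMessage(e)))
  e_ij <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    ri <- (i - 1L) * nz + 1:nz
    for (j in seq_len(L)) {
      if (i == j) next
      e_ij[i, j, 2:q, 2:q] <- -Cinv[ri, (j - 1L) * nz + 1:nz]
    }
  }
  structure(list(e_ij = e_ij, C = C), class = "coev_coupling")
}

#' Direct information of one position pair
#'
#' Builds the two-site model
#' `P_dir(a,b) = exp(e_ij(a,b)) x_i(a) x_j(b) / Z` with auxiliary
#' single-site factors fixed by matching the marginals of `P_dir` to the
#' empirical `f_i`, `f_j` (fixed-point iteration; damping 0.5 is applied
#' if the iteration oscillates). DI is the mutual information of
#' `P_dir` against the factorised `f_i f_j`.
#'
#' @param coupling a `coev_coupling`.
#' @param freq the matching `coev_freq`.
#' @param i,j 1-based column indices, `i != j`.
#' @param tol fixed-point tolerance on the auxiliary marginals.
#' @param max_iter iteration cap.
#' @return nonnegative DI value (nats).
#' @export
direct_information <- function(coupling, freq, i, j, tol = 1e-6,
                               max_iter = 500L) {
  stopifnot(i != j)
  q <- freq$q
  W <- exp(coupling$e_ij[i, j, , ])
  pi_ <- freq$f_i[i, ]
  pj_ <- freq$f_i[j, ]
  mu <- match_marginals(W, pi_, pj_, tol, max_iter)
  P <- W * tcrossprod(mu$mu1, mu$mu2)
  P <- P / sum(P)
  ref <- tcrossprod(pi_, pj_)
  tiny <- 1e-100
  sum(P * log((P + tiny) / (ref + tiny)))
}

match_marginals <- function(W, pi_, pj_, tol = 1e-6, max_iter = 500L) {
  q <- length(pi_)
  mu1 <- rep(1 / q, q)
  mu2 <- rep(1 / q, q)
  prev_diff <- Inf
  for (it in seq_len(max_iter)) {
    s1 <- as.vector(W %*% mu2)
    s2 <- as.vector(crossprod(W, mu1))
    new1 <- pi_ / s1; new1 <- new1 / sum(new1)
    new2 <- pj_ / s2; new2 <- new2 / sum(new2)
    diff <- max(abs(new1 - mu1), abs(new2 - mu2))
    if (diff > prev_diff) { # oscillation: damp the update
      new1 <- 0.5 * (new1 + mu1)
      new2 <- 0.5 * (new2 + mu2)
      diff <- max(abs(new1 - mu1), abs(new2 - mu2))
    }
    mu1 <- new1; mu2 <- new2
    if (diff < tol)
      return(list(mu1 = mu1, mu2 = mu2, iterations = it))
    prev_diff <- diff
  }
  stop("marginal matching did not converge in ", max_iter,
       " iterations (last delta ", signif(prev_diff, 3), ")")
}

#' Rank position pairs by direct information
#'
#' Computes DI for every pair `(i, j)` with `j - i >= min_separation`
#' and returns them in descending DI order, ties broken lexicographically
#' by `(i, j)`.
#'
#' @param coupling a `coev_coupling`.
#' @param freq the matching `coev_freq`.
#' @param min_separation minimum column separation (default 2, i.e. only
#'   trivially adjacent pairs are excluded: homodimer interface signals
#'   can lie near the diagonal and are suppressed later by the
#'   monomer-contact filter, not here).
#' @return a `coev_diranking`: data frame with 0-based columns `i`, `j`
#'   and `DI`, sorted descending.
#' @export
rank_pairs <- function(coupling, freq, min_separation = 2L) {
  stopifnot(min_separation >= 0)
  L <- freq$L
  out <- list()
  n <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      if (j - i < min_separation) next
      n <- n + 1L
      out[[n]] <- c(i - 1L, j - 1L,
                    direct_information(coupling, freq, i, j))
    }
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "j", "DI")
  df$i <- as.integer(df$i); df$j <- as.integer(df$j)
  new_diranking(df)
}

new_diranking <- function(df) {
  stopifnot(all(c("i", "j", "DI") %in% names(df)))
  df <- df[order(-df$DI, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("coev_diranking", "data.frame")
  df
}

#' Run the full mfDCA stage on an alignment
#'
#' Convenience wrapper: reweighting, frequencies, mean-field inversion
#' and DI ranking with the conventional defaults (`theta = 0.8`,
#' `lambda = Meff`).
#'
#' @inheritParams compute_weights
#' @inheritParams rank_pairs
#' @param lambda pseudocount mass; default `Meff`.
#' @return list with `ranking`, `freq`, `coupling`, `Meff`.
#' @export
run_dca <- function(msa, theta = 0.8, lambda = NULL, min_separation = 2L) {
  wts <- compute_weights(msa, theta)
  freq <- compute_frequencies(msa, wts$weights, lambda %||% wts$Meff,
                              theta = theta)
  coupling <- invert_mean_field(freq)
  ranking <- rank_pairs(coupling, freq, min_separation)
  list(ranking = ranking, freq = freq, coupling = coupling,
       Meff = wts$Meff)
}

#' Write a DI ranking as TSV with a JSON sidecar
#'
#' The table has 0-based columns `i`, `j` and the DI value; the sidecar
#' `<path>.json` records theta, lambda, Meff and the state alphabet so
#' the ranking is self-describing.
#'
#' @param ranking a `coev_diranking`.
#' @param freq the `coev_freq` it came from (for the sidecar).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_di_table <- function(ranking, freq, path) {
  write.table(as.data.frame(ranking)[, c("i", "j", "DI")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(theta = freq$theta, lambda = freq$lambda,
               Meff = freq$Meff, q = freq$q,
               alphabet = if (freq$q == N_STATES) AA_ALPHABET1
                          else as.character(seq_len(freq$q) - 1L))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
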