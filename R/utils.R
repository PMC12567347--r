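# Internal numerical helpers.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
# via Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
#' @keywords internal
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch).
#' @keywords internal
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  bk <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bk
  J[cbind(i + 1, i)] <- bk
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2, weights = (b - a) / 2 * w[ord])
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit sub-seed derived from a master seed and a stream label.
#' @keywords internal
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629L)
}
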