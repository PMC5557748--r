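# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Brute-force marginal posterior of (sigma2_A, sigma2_e) on a log-spaced
# grid, with the fixed effects integrated analytically under a flat
# prior; direct dense-V linear algebra (no eigenbasis). The data are
# standardized to unit variance exactly as the sampler standardizes them.
grid_posterior_mean_h2 <- function(y, App, shape = 0.001, rate = 0.001,
                                   ngrid = 200, lo = 1e-6, hi = 1e4) {
  y <- y / stats::sd(y)
  n <- length(y)
  X <- matrix(1, n, 1)
  vy <- stats::var(y)
  sa <- exp(seq(log(lo * vy), log(hi * vy), length.out = ngrid))
  se <- sa
  loglik <- function(s2a, s2e) {
    V <- s2a * App + diag(s2e, n)
    ch <- chol(V)
    Vi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    Vi_X <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
    XtViX <- crossprod(X, Vi_X)
    bhat <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% bhat
    Vi_r <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
    -0.5 * (2 * sum(log(diag(ch))) + log(det(XtViX)) + sum(r * Vi_r))
  }
  lp <- matrix(NA_real_, ngrid, ngrid)
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      lp[i, j] <- loglik(sa[i], se[j]) -
        (shape + 1) * log(sa[i]) - rate / sa[i] -
        (shape + 1) * log(se[j]) - rate / se[j] +
        log(sa[i]) + log(se[j])   # Jacobian of the log-spaced grid
    }
  }
  lp <- lp - max(lp)
  w <- exp(lp)
  h2 <- outer(sa, se, function(a, b) a / (a + b))
  sum(w * h2) / sum(w)
}

# hand-coded median-of-ratios size factors (independent of the package's
# vectorized implementation)
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ratios <- counts[ref, j] / geo
    sf[j] <- stats::median(ratios)
  }
  sf / prod(sf)^(1 / length(sf))
}

# scalar brute-force evaluation of the similarity-sensitive diversity,
# written directly from the defining sum
oracle_qdz <- function(p, Z, q) {
  zp <- numeric(length(p))
  for (i in seq_along(p)) {
    acc <- 0
    for (j in seq_along(p)) acc <- acc + Z[i, j] * p[j]
    zp[i] <- acc
  }
  s <- which(p > 0)
  if (is.infinite(q)) return(1 / max(zp[s]))
  if (q == 1) return(exp(-sum(p[s] * log(zp[s]))))
  total <- 0
  for (i in s) total <- total + p[i] * zp[i]^(q - 1)
  total^(1 / (1 - q))
}

# connected components of the graph with edges where distance <= cut
# (single-pass union-find; oracle for well-separated candidate groups)
oracle_threshold_components <- function(d, cut) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] <= cut) parent[find(j)] <- find(i)
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(d), roots)
}

# pedigree fixtures
toy_fullsib_pedigree <- function(n_off = 10) {
  pedigree(c("F1", "F2", paste0("O", seq_len(n_off))),
           c(NA, NA, rep("F1", n_off)), c(NA, NA, rep("F2", n_off)))
}

random_pedigree <- function(n_founders, n_off, seed) {
  set.seed(seed)
  ids <- sprintf("I%03d", seq_len(n_founders + n_off))
  sire <- dam <- rep(NA_character_, n_founders + n_off)
  for (k in seq_len(n_off)) {
    i <- n_founders + k
    pick <- sample.int(i - 1L, 2L)
    sire[i] <- ids[pick[1L]]
    dam[i] <- ids[pick[2L]]
  }
  pedigree(ids, sire, dam)
}
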