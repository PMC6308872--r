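# Brute-force oracle for the dip statistic: direct encoding of
# D = min over unimodal CDFs U of sup |F_n - U|.  For each candidate mode
# position m the closest unimodal CDF is found by optimizing its values at
# the data points (piecewise-linear between points, convex left of the
# mode, concave right of it, an atom permitted at the mode); the dip is the
# minimum over modes.  The minimax program is solved as a quadratic program
# (quadprog) with a vanishing ridge, which keeps it exact to ~1e-6.  Only
# used at small n with distinct values.
dip_qp_oracle <- function(x) {
  stopifnot(requireNamespace("quadprog", quietly = TRUE))
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n == 1) return(0)
  stopifnot(!anyNA(x), !any(duplicated(x)))

  best <- Inf
  for (m in seq_len(n)) {
    # variables: u_i (i != m), v = U(x_m^-), w = U(x_m), t
    others <- setdiff(seq_len(n), m)
    nv <- length(others) + 3L
    iu <- function(i) match(i, others)
    ivv <- length(others) + 1L
    iw <- length(others) + 2L
    it <- nv

    rows <- list(); rhs <- numeric(0)
    ge <- function(row, b0) {           # row %*% z >= b0
      rows[[length(rows) + 1L]] <<- row
      rhs[length(rhs) + 1L] <<- b0
    }
    z <- function() numeric(nv)

    for (i in others) {
      r <- z(); r[iu(i)] <- -1; r[it] <- 1; ge(r, -(i - 1) / n)  # u_i - t <= (i-1)/n
      r <- z(); r[iu(i)] <- 1; r[it] <- 1; ge(r, i / n)          # u_i + t >= i/n
    }
    r <- z(); r[ivv] <- -1; r[it] <- 1; ge(r, -(m - 1) / n)
    r <- z(); r[ivv] <- 1; r[it] <- 1; ge(r, (m - 1) / n)
    r <- z(); r[iw] <- -1; r[it] <- 1; ge(r, -m / n)
    r <- z(); r[iw] <- 1; r[it] <- 1; ge(r, m / n)

    chain_idx <- c(if (m > 1) vapply(seq_len(m - 1), iu, integer(1)),
                   ivv, iw,
                   if (m < n) vapply((m + 1):n, iu, integer(1)))
    chain_x <- c(x[seq_len(m - 1)], x[m], x[m], if (m < n) x[(m + 1):n])
    K <- length(chain_idx)
    for (k in seq_len(K - 1)) {                       # nondecreasing
      r <- z(); r[chain_idx[k + 1]] <- 1; r[chain_idx[k]] <- -1; ge(r, 0)
    }
    r <- z(); r[chain_idx[1]] <- 1; ge(r, 0)          # u >= 0
    r <- z(); r[chain_idx[K]] <- -1; ge(r, -1)        # u <= 1
    r <- z(); r[it] <- 1; ge(r, 0)

    curv <- function(k, sign) {  # sign +1: convex triple, -1: concave
      i0 <- chain_idx[k - 1]; i1 <- chain_idx[k]; i2 <- chain_idx[k + 1]
      d1 <- chain_x[k] - chain_x[k - 1]; d2 <- chain_x[k + 1] - chain_x[k]
      s <- d1 + d2
      r <- z(); r[i2] <- sign * d1 / s; r[i1] <- -sign; r[i0] <- sign * d2 / s
      ge(r, 0)
    }
    if (m >= 3) for (k in 2:(m - 1)) curv(k, +1)
    if (K >= m + 3) for (k in (m + 2):(K - 1)) curv(k, -1)

    A <- t(do.call(rbind, rows))
    Dmat <- diag(1e-9, nv)
    dvec <- numeric(nv); dvec[it] <- -1            # minimize t
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, A, rhs, meq = 0),
      error = function(e) NULL)
    if (!is.null(sol)) {
      tval <- sol$solution[it]
      viol <- max(0, max(rhs - drop(t(A) %*% sol$solution)))
      if (viol < 1e-7 && tval < best) best <- tval
    }
  }
  best
}
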