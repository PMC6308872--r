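#' Hartigan-Hartigan dip statistic
#'
#' The dip of a sample is the maximum distance between its empirical CDF and
#' the closest unimodal CDF, i.e. `D = min over unimodal U of sup |F_n - U|`.
#' It is computed exactly by the greatest-convex-minorant / least-concave-
#' majorant algorithm: the candidate modal interval is shrunk iteratively,
#' comparing the minorant fitted left of it and the majorant fitted right of
#' it against the empirical CDF, until no placement of the modal interval
#' can reduce the maximum deviation.  For `n = 2` distinct points the dip is
#' `0.25`; for a sample with all values equal it is `0`.
#'
#' @param x Numeric vector (unsorted is fine).
#' @return The dip statistic, a value in `[0, 0.25]`.
#' @seealso [dip_test()] for a Monte Carlo p-value.
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1 || anyNA(x)) stop("dip_stat(): need a complete, non-empty sample")
  if (n == 1 || x[n] == x[1]) return(0)

  # mn[j]: preceding touch point of the greatest convex minorant of the ecdf
  mn <- integer(n); mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # mj[k]: following touch point of the least concave majorant
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L; high <- n
  dip <- 1  # deviations carried in units of 1/n counts; halved at the end
  gcm <- integer(n); lcm <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > n + 2L) break  # safety; the interval strictly shrinks in practice

    gcm[1] <- high; i <- 1L
    while (gcm[i] > low) { gcm[i + 1L] <- mn[gcm[i]]; i <- i + 1L }
    ig <- i; l_gcm <- i; ix <- ig - 1L

    lcm[1] <- low; i <- 1L
    while (lcm[i] < high) { lcm[i + 1L] <- mj[lcm[i]]; i <- i + 1L }
    ih <- i; l_lcm <- i; iv <- 2L

    # largest gap between the minorant and majorant inside [low, high]
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # next change point comes from the majorant
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          # next change point comes from the minorant
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx > d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else d <- 1

    if (d < dip) break

    # deviation of the ecdf above the convex minorant on [low, gcm[ig]]
    dl <- 0
    if (ig != l_gcm) {
      for (j in ig:(l_gcm - 1L)) {
        temp <- 1
        jb <- gcm[j + 1L]; je <- gcm[j]
        if (je - jb > 1L && x[je] != x[jb]) {
          slope <- (je - jb) / (x[je] - x[jb])
          for (jr in jb:je) {
            t1 <- (jr - jb + 1) - (x[jr] - x[jb]) * slope
            if (t1 > temp) temp <- t1
          }
        }
        if (dl < temp) dl <- temp
      }
    }
    # deviation of the ecdf below the concave majorant on [lcm[ih], high]
    du <- 0
    if (ih != l_lcm) {
      for (j in ih:(l_lcm - 1L)) {
        temp <- 1
        jb <- lcm[j]; je <- lcm[j + 1L]
        if (je - jb > 1L && x[je] != x[jb]) {
          slope <- (je - jb) / (x[je] - x[jb])
          for (jr in jb:je) {
            t1 <- (x[jr] - x[jb]) * slope - (jr - jb - 1)
            if (t1 > temp) temp <- t1
          }
        }
        if (du < temp) du <- temp
      }
    }

    dipnew <- max(dl, du)
    if (dip < dipnew) dip <- dipnew
    # stop when the modal interval no longer shrinks
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / (2 * n)
}

#' Dip test of unimodality with a Monte Carlo p-value
#'
#' Computes [dip_stat()] for the sample and calibrates it against `n_null`
#' samples of the same size drawn from the uniform distribution (the
#' asymptotically least favourable unimodal null).  The p-value uses the
#' add-one permutation estimator `(1 + #{D_null >= D}) / (1 + n_null)` and
#' is reproducible for a given `seed`.
#'
#' @param x Numeric sample.
#' @param n_null Number of null replicates (default 2000).
#' @param seed Optional integer seed for the null draws; the caller's RNG
#'   state is left untouched.
#' @return List with `statistic` (the dip `D`), `p_value`, `n`, `n_null`.
#' @export
dip_test <- function(x, n_null = 2000, seed = NULL) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  D <- dip_stat(x)
  nulls <- with_preserved_rng(seed, {
    vapply(seq_len(n_null), function(i) dip_stat(stats::runif(n)), numeric(1))
  })
  list(statistic = D,
       p_value = (1 + sum(nulls >= D)) / (1 + n_null),
       n = n, n_null = n_null)
}

# Evaluate `expr` under an optional seed without disturbing the caller's
# global RNG stream.
with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
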