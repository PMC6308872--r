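#' Kernel-density peak of a metabolic-expansibility distribution
#'
#' Estimates the mode of the interspecific ME distribution from a Gaussian
#' kernel density on a 512-point grid spanning the data plus three
#' bandwidths on either side, with the normal-reference (Silverman)
#' bandwidth.  When the density is "twin-peaked" -- two local maxima both
#' within `subpeak_tol` (relative density) of the global maximum -- the peak
#' is reported as the mean of the two subpeak locations and the result is
#' flagged `subpeaks_averaged`; the raw argmax is always reported too.
#'
#' @param values Numeric sample (n >= 8, non-degenerate).
#' @param subpeak_tol Relative-density tolerance for recognising a second
#'   subpeak (default 0.05).
#' @param bw Bandwidth or rule, passed to [stats::density()] (default
#'   `"nrd0"`, the normal-reference rule).
#' @return List with `peak`, `peak_raw`, `subpeaks_averaged`, `subpeaks`
#'   (data frame of qualifying local maxima), `density` (data frame `x`,
#'   `y`) and `bw`.
#' @export
kde_peak <- function(values, subpeak_tol = 0.05, bw = "nrd0") {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 8)
    stop("kde_peak(): need at least 8 values")
  if (stats::sd(values) == 0)
    stop("kde_peak(): zero variance")
  d <- stats::density(values, bw = bw, n = 512, cut = 3)
  y <- d$y
  k <- length(y)
  # local maxima (endpoints included)
  is_max <- c(y[1] >= y[2], y[2:(k - 1)] >= y[1:(k - 2)] &
                y[2:(k - 1)] >= y[3:k], y[k] >= y[k - 1])
  # collapse flat plateaus to a single representative
  cand <- which(is_max)
  if (length(cand) > 1) {
    keep <- c(TRUE, diff(cand) > 1 | y[cand[-1]] != y[cand[-length(cand)]])
    cand <- cand[keep]
  }
  ymax <- max(y)
  qual <- cand[y[cand] >= (1 - subpeak_tol) * ymax]
  peak_raw <- d$x[which.max(y)]
  averaged <- FALSE
  peak <- peak_raw
  if (length(qual) >= 2) {
    top2 <- qual[order(y[qual], decreasing = TRUE)][1:2]
    peak <- mean(d$x[top2])
    averaged <- TRUE
  }
  list(peak = peak, peak_raw = peak_raw, subpeaks_averaged = averaged,
       subpeaks = data.frame(x = d$x[qual], density = y[qual]),
       density = data.frame(x = d$x, y = y), bw = d$bw)
}

#' D'Agostino test of skewness
#'
#' Moment skewness `b1 = m3 / m2^(3/2)` with the D'Agostino (1970)
#' normalizing transformation to an approximate standard normal `z` and a
#' two-sided p-value.
#'
#' @param values Numeric sample (n >= 8).
#' @return List with `b1`, `z`, `p_value`, `n`.
#' @export
skewness_test <- function(values) {
  x <- as.numeric(values[!is.na(values)])
  n <- length(x)
  if (n < 8) stop("skewness_test(): need at least 8 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness_test(): zero variance")
  b1 <- mean((x - m)^3) / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  list(b1 = b1, z = z, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Bonett-Seier test of Geary's kurtosis
#'
#' Geary's metric is the ratio of the mean absolute deviation to the
#' population standard deviation, `g = mean|x - xbar| / s_n`; it equals
#' `sqrt(2/pi) ~ 0.7979` for a normal distribution and decreases for heavy
#' tails.  The Bonett-Seier (2002) transformation
#' `omega = 13.29 (ln s_n - ln mean|x - xbar|)`,
#' `z = sqrt((n + 2)/2) (omega - 3) / 3.54` is approximately standard
#' normal under normality; the p-value is two-sided.
#'
#' @param values Numeric sample (n >= 8).
#' @return List with `geary`, `z`, `p_value`, `n`.
#' @export
kurtosis_test <- function(values) {
  x <- as.numeric(values[!is.na(values)])
  n <- length(x)
  if (n < 8) stop("kurtosis_test(): need at least 8 values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("kurtosis_test(): zero variance")
  tau <- mean(abs(x - m))
  geary <- tau / s
  omega <- 13.29 * (log(s) - log(tau))
  z <- sqrt((n + 2) / 2) * (omega - 3) / 3.54
  list(geary = geary, z = z, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Randomization null interval for the ME distribution
#'
#' Shuffles the assignment of cold-boundary temperatures to species while
#' keeping each species' own physiology (`t_lc`, `t_b`, conductance, BMR),
#' recomputes metabolic expansibility for every permutation, and returns the
#' percentile interval of the chosen summary statistic across replicates.
#' A summary of the observed ME falling outside this interval indicates that
#' boundary temperatures covary with physiology, as expected under a
#' metabolic constraint.
#'
#' @param phys Data frame with `t_lc`, `t_b`, `bmr` and optionally
#'   `conductance` (derived from the other columns when absent).
#' @param t_min Vector of observed cold-boundary temperatures, one per row
#'   of `phys`.
#' @param stat `"median"` or `"mean"`.
#' @param n_reps Number of permutation replicates (default 1000).
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param probs Interval endpoints (default 2.5th and 97.5th percentiles).
#' @return List with `lower`, `upper`, `observed`, `stats` (replicate
#'   values), `stat`, `n_reps`.
#' @export
randomization_null <- function(phys, t_min, stat = c("median", "mean"),
                               n_reps = 1000, seed = NULL,
                               probs = c(0.025, 0.975)) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(phys), nrow(phys) >= 2,
            length(t_min) == nrow(phys))
  f <- match.fun(stat)
  cond <- if (!is.null(phys$conductance) && !all(is.na(phys$conductance)))
    ifelse(is.na(phys$conductance),
           estimate_conductance(phys$bmr, phys$t_b, phys$t_lc),
           phys$conductance)
  else estimate_conductance(phys$bmr, phys$t_b, phys$t_lc)
  me_of <- function(tm)
    metabolic_expansibility(mr_at_cold_boundary(tm, phys$t_lc, cond, phys$bmr),
                            phys$bmr)
  observed <- f(me_of(t_min))
  reps <- with_preserved_rng(seed, {
    vapply(seq_len(n_reps),
           function(i) f(me_of(sample(t_min))), numeric(1))
  })
  q <- stats::quantile(reps, probs = probs, names = FALSE)
  list(lower = q[1], upper = q[2], observed = observed, stats = reps,
       stat = stat, n_reps = n_reps)
}

#' Full shape summary of a metabolic-expansibility distribution
#'
#' Bundles the kernel-density peak (with subpeak averaging), central
#' moments, the D'Agostino skewness test, the Bonett-Seier kurtosis test,
#' and Hartigan's dip test for one taxon's ME values.
#'
#' @param values Numeric ME sample (n >= 8).
#' @param subpeak_tol Passed to [kde_peak()].
#' @param dip_reps Null replicates for [dip_test()] (default 2000).
#' @param seed Optional seed for the dip null draws.
#' @return List of class `me_distribution_summary`.
#' @export
me_distribution_summary <- function(values, subpeak_tol = 0.05,
                                    dip_reps = 2000, seed = NULL) {
  x <- as.numeric(values[!is.na(values)])
  if (length(x) < 8)
    stop("me_distribution_summary(): need at least 8 values")
  pk <- kde_peak(x, subpeak_tol = subpeak_tol)
  sk <- skewness_test(x)
  ku <- kurtosis_test(x)
  dp <- dip_test(x, n_null = dip_reps, seed = seed)
  structure(list(
    peak = pk$peak, peak_raw = pk$peak_raw,
    subpeaks_averaged = pk$subpeaks_averaged,
    median = stats::median(x), mean = mean(x), sd = stats::sd(x),
    skewness = sk$b1, skew_z = sk$z, skew_p = sk$p_value,
    geary = ku$geary, kurt_z = ku$z, kurt_p = ku$p_value,
    dip_D = dp$statistic, dip_p = dp$p_value,
    n = length(x)), class = "me_distribution_summary")
}

#' @export
print.me_distribution_summary <- function(x, ...) {
  cat(sprintf("ME distribution (n = %d)\n", x$n))
  cat(sprintf("  peak %.3f%s  median %.3f  mean %.3f (sd %.3f)\n",
              x$peak, if (x$subpeaks_averaged) " (subpeaks averaged)" else "",
              x$median, x$mean, x$sd))
  cat(sprintf("  skewness %.3f (z = %.2f, p = %.3g)\n",
              x$skewness, x$skew_z, x$skew_p))
  cat(sprintf("  Geary kurtosis %.3f (z = %.2f, p = %.3g)\n",
              x$geary, x$kurt_z, x$kurt_p))
  cat(sprintf("  dip D = %.4f (p = %.3g)\n", x$dip_D, x$dip_p))
  invisible(x)
}
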