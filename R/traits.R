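#' Ordinary least-squares trait model for metabolic expansibility
#'
#' Fits `me_crb ~ predictors` by least squares and reports the coefficient
#' table, sequential (type-I) ANOVA in the declared predictor order, and
#' r-squared.  Categorical predictors use treatment coding against their
#' first factor level (alphabetical unless the factor sets its own levels).
#' Body mass is conventionally supplied as `log10_mass`.
#'
#' @param data Data frame holding the response and predictors.
#' @param predictors Character vector of predictor terms, in the order the
#'   sequential ANOVA should use.
#' @param response Response column name (default `"me_crb"`).
#' @return List with `fit` (the `lm`), `coefficients` (data frame with
#'   estimates, SE, t, p), `anova` (sequential F table), `r_squared`,
#'   `residuals`.
#' @export
fit_trait_model <- function(data, predictors = c("log10_mass", "diet",
                                                 "nocturnal", "torpor"),
                            response = "me_crb") {
  stopifnot(is.data.frame(data), response %in% names(data))
  miss <- setdiff(predictors, names(data))
  if (length(miss))
    stop("fit_trait_model(): missing predictor columns: ",
         paste(miss, collapse = ", "))
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  mm <- stats::model.matrix(fit)
  if (fit$rank < ncol(mm)) {
    dropped <- colnames(mm)[is.na(stats::coef(fit))]
    stop("fit_trait_model(): rank-deficient design; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co$term <- rownames(co)
  rownames(co) <- NULL
  list(fit = fit,
       coefficients = co[, c("term", "estimate", "se", "t", "p")],
       anova = stats::anova(fit),
       r_squared = s$r.squared,
       residuals = stats::residuals(fit))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param log_likelihood Model log-likelihood.
#' @param k Number of estimated parameters (including any scale
#'   parameter counted by the likelihood).
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (any(n <= k + 1))
    stop("aicc(): requires n > k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# expand term subsets respecting marginality: an interaction enters only
# with both its main effects
model_subsets <- function(terms) {
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  inters <- setdiff(terms, mains)
  subs <- list(character(0))
  for (m in mains)
    subs <- c(subs, lapply(subs, function(s) c(s, m)))
  if (length(inters)) {
    for (ix in inters) {
      parts <- strsplit(ix, ":", fixed = TRUE)[[1]]
      subs <- c(subs, lapply(Filter(function(s) all(parts %in% s), subs),
                             function(s) c(s, ix)))
    }
  }
  subs
}

#' Exhaustive AICc model selection with model averaging
#'
#' Fits every subset of the supplied terms that respects marginality
#' (interactions only together with their main effects), ranks the models
#' by AICc, and reports Akaike weights `w_i = exp(-delta_i/2) / sum(...)`.
#' Coefficients are "full"-averaged over all models within `delta_max` of
#' the best model: a model that omits a term contributes a zero for that
#' term's coefficients, so averaged effects shrink toward zero in
#' proportion to the support for models excluding them.
#'
#' @param data Data frame with the response and predictors.
#' @param terms Character vector of candidate terms; interactions written
#'   `"a:b"`.
#' @param response Response column name (default `"me_crb"`).
#' @param delta_max AICc window for averaging (default 6).
#' @param max_models Guard against subset explosion (default 4096 fitted
#'   models).
#' @return List with `models` (ranked data frame: terms, k, logLik, AICc,
#'   delta, weight), `coefficients` (named vector of averaged
#'   coefficients), `weights_used` (renormalized weights of the averaged
#'   set), `best` (formula string of the top model).
#' @export
dredge_and_average <- function(data, terms, response = "me_crb",
                               delta_max = 6, max_models = 4096) {
  stopifnot(is.data.frame(data), response %in% names(data))
  subs <- model_subsets(terms)
  if (length(subs) > max_models)
    stop("dredge_and_average(): ", length(subs), " candidate models exceed ",
         "max_models = ", max_models,
         "; reduce the term set or raise the guard")
  n <- nrow(data)
  # template coefficient names from the full model
  full_fml <- if (length(terms)) stats::reformulate(terms, response = response)
              else stats::as.formula(paste(response, "~ 1"))
  full_fit <- stats::lm(full_fml, data = data)
  coef_names <- names(stats::coef(full_fit))

  fits <- lapply(subs, function(s) {
    fml <- if (length(s)) stats::reformulate(s, response = response)
           else stats::as.formula(paste(response, "~ 1"))
    stats::lm(fml, data = data)
  })
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  k <- vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1))
  ic <- aicc(ll, k, n)
  ord <- order(ic)
  models <- data.frame(
    terms = vapply(subs, function(s)
      if (length(s)) paste(s, collapse = " + ") else "1", character(1)),
    k = k, logLik = ll, AICc = ic, stringsAsFactors = FALSE)[ord, ]
  models$delta <- models$AICc - models$AICc[1]
  w <- exp(-models$delta / 2)
  models$weight <- w / sum(w)
  rownames(models) <- NULL
  fits <- fits[ord]

  in_window <- models$delta <= delta_max
  win_w <- models$weight[in_window] / sum(models$weight[in_window])
  avg <- stats::setNames(numeric(length(coef_names)), coef_names)
  for (j in which(in_window)) {
    cf <- stats::coef(fits[[j]])
    avg[names(cf)] <- avg[names(cf)] + win_w[match(j, which(in_window))] * cf
  }
  list(models = models, coefficients = avg, weights_used = win_w,
       best = paste(response, "~", models$terms[1]))
}
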