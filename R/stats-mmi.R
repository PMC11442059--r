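#' @importFrom stats as.formula coef logLik model.matrix vcov setNames
NULL

.MMI_MAINS <- c("species", "morph", "substrate", "predator")

#' Enumerate marginality-respecting candidate models
#'
#' All models built from a set of main effects and their pairwise
#' interactions, subject to marginality (an interaction requires both its
#' parents) and always including the intercept. For 4 mains this yields
#' \eqn{\sum_S 2^{\binom{|S|}{2}} = 113} specifications.
#'
#' @param mains character vector of main-effect names.
#' @param max_order highest interaction order (only 1 or 2 supported).
#' @return a list of model specs, each `list(mains = ..., inters = ...)`
#'   where `inters` is a character vector like `"morph:predator"`.
#' @export
enumerate_candidates <- function(mains = .MMI_MAINS, max_order = 2) {
  stopifnot(max_order %in% c(1, 2))
  specs <- list()
  nm <- length(mains)
  for (msize in 0:nm) {
    main_sets <- if (msize == 0) list(character(0)) else
      utils::combn(mains, msize, simplify = FALSE)
    for (ms in main_sets) {
      inters <- character(0)
      if (max_order == 2 && length(ms) >= 2) {
        pairs <- utils::combn(ms, 2, simplify = FALSE)
        inters <- vapply(pairs, paste, character(1), collapse = ":")
      }
      isets <- list(character(0))
      if (length(inters)) {
        isets <- unlist(lapply(0:length(inters), function(k) {
          if (k == 0) list(character(0)) else
            utils::combn(inters, k, simplify = FALSE)
        }), recursive = FALSE)
      }
      for (is in isets) {
        specs[[length(specs) + 1]] <- list(mains = ms, inters = is)
      }
    }
  }
  specs
}

#' Formula for a model spec
#' @param spec a candidate spec from [enumerate_candidates()].
#' @param response response column name.
#' @param random random-effect term (default individual random intercept).
#' @export
spec_formula <- function(spec, response, random = "(1 | individual)") {
  rhs <- c(spec$mains, spec$inters)
  rhs <- if (length(rhs)) paste(rhs, collapse = " + ") else "1"
  stats::as.formula(paste(response, "~", rhs, "+", random))
}

# Reference levels matching the published coding: O. granulifera, green morph,
# bird predator, green-leaf substrate are the baselines.
.code_factors <- function(data) {
  refs <- list(species = "O. granulifera", morph = "green",
               predator = "bird", substrate = "green_leaf")
  for (v in names(refs)) {
    if (!v %in% names(data)) next
    f <- factor(data[[v]])
    if (refs[[v]] %in% levels(f)) f <- stats::relevel(f, ref = refs[[v]])
    data[[v]] <- f
  }
  data$individual <- factor(data$individual)
  data
}

#' Fit one random-intercept linear mixed model by maximum likelihood
#'
#' `y ~ fixed terms + (1 | individual)`, Gaussian, fitted by ML (not REML:
#' AICc comparisons across fixed-effect structures require ML). The parameter
#' count `k` is the number of fixed-effect coefficients plus 2 (random
#' intercept variance and residual variance).
#'
#' @param spec a candidate spec.
#' @param data contrast records (data.frame with `individual` and the factor
#'   predictors); factors are recoded to the standard reference levels.
#' @param response `"deltaS"` or `"deltaL"`.
#' @return a `lmm_fit` list: `spec`, `formula`, `fit` (merMod), `coefficients`
#'   (term/estimate/se), `loglik`, `k`, `n`.
#' @export
fit_lmm <- function(spec, data, response = c("deltaS", "deltaL")) {
  response <- match.arg(response)
  data <- .code_factors(data)
  fml <- spec_formula(spec, response)
  # singularity of the fixed-effect design is an input error, not a fit issue
  fixed_rhs <- c(spec$mains, spec$inters)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", if (length(fixed_rhs))
      paste(fixed_rhs, collapse = "+") else "1")), data)
  if (qr(X)$rank < ncol(X)) {
    stop("singular fixed-effect design for terms: ",
         paste(fixed_rhs, collapse = ", "), call. = FALSE)
  }
  fit <- lme4::lmer(fml, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(
    spec = spec,
    formula = fml,
    fit = fit,
    coefficients = data.frame(term = names(beta), estimate = as.numeric(beta),
                              se = as.numeric(se), stringsAsFactors = FALSE),
    loglik = as.numeric(stats::logLik(fit)),
    k = length(beta) + 2L,
    n = stats::nobs(fit)
  ), class = "lmm_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\,\ell + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param fit an `lmm_fit`, or a list with `loglik`, `k`, `n`.
#' @export
aicc <- function(fit) {
  ll <- fit$loglik; k <- fit$k; n <- fit$n
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights and evidence ratios for a candidate set
#'
#' \eqn{\Delta_i = AICc_i - \min AICc};
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}};
#' \eqn{ER_i = w_{best}/w_i}.
#'
#' @param fits list of `lmm_fit` objects.
#' @return the list with `aicc`, `delta_aicc`, `weight`, `evidence_ratio`
#'   added to each element, sorted by AICc (best first).
#' @export
weights_and_ratios <- function(fits) {
  stopifnot(length(fits) >= 1)
  ac <- vapply(fits, aicc, numeric(1))
  delta <- ac - min(ac)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  er <- max(w) / w
  for (i in seq_along(fits)) {
    fits[[i]]$aicc <- ac[i]
    fits[[i]]$delta_aicc <- delta[i]
    fits[[i]]$weight <- w[i]
    fits[[i]]$evidence_ratio <- er[i]
  }
  fits[order(ac)]
}

#' 95% (or other mass) confidence set of models
#'
#' The smallest weight-ordered prefix of the candidate set whose cumulative
#' Akaike weight reaches `mass`. Alternatively (`rule = "weight_floor"`) all
#' models with weight above a floor.
#'
#' @param fits output of [weights_and_ratios()].
#' @param mass cumulative weight target (default 0.95).
#' @param rule `"cumulative"` (default) or `"weight_floor"`.
#' @param floor weight floor for the alternative rule (default 0.01).
#' @export
confidence_set <- function(fits, mass = 0.95, rule = c("cumulative",
                                                       "weight_floor"),
                           floor = 0.01) {
  rule <- match.arg(rule)
  w <- vapply(fits, function(f) f$weight, numeric(1))
  o <- order(w, decreasing = TRUE)
  if (rule == "weight_floor") return(fits[o][w[o] > floor])
  cum <- cumsum(w[o])
  keep <- seq_len(min(which(cum >= mass - 1e-12)))
  fits[o][keep]
}

#' Model-averaged estimates, importance and strong-effect flags
#'
#' Weights are renormalized within the supplied (confidence) set. For each
#' fixed-effect coefficient: importance is the summed renormalized weight of
#' set members containing it; the estimate is the conditional average over
#' those members (weights renormalized again to that subset, matching a
#' per-term "number of models" column); the unconditional standard error is
#' \eqn{\sum_i \tilde w_i \sqrt{se_i^2 + (\beta_i - \bar\beta)^2}}; the 95% CI
#' is \eqn{\bar\beta \pm 1.96\,SE}. An effect is `strong` when its CI excludes
#' zero and `important` when importance >= `importance_threshold`.
#'
#' @param fits a confidence set from [confidence_set()].
#' @param importance_threshold importance cutoff (default 0.80).
#' @param mode `"conditional"` (default) or `"zero"`: with `"zero"`, models
#'   lacking a term contribute a 0 estimate (full-set averaging).
#' @return data.frame with columns `term`, `n_models`, `importance`,
#'   `lower_ci`, `upper_ci`, `estimate`, `se`, `strong`, `important`.
#' @export
model_average <- function(fits, importance_threshold = 0.80,
                          mode = c("conditional", "zero")) {
  mode <- match.arg(mode)
  w <- vapply(fits, function(f) f$weight, numeric(1))
  w <- w / sum(w)
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  rows <- lapply(terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% f$coefficients$term, logical(1))
    imp <- sum(w[has])
    est_i <- vapply(fits[has], function(f) {
      f$coefficients$estimate[f$coefficients$term == tm]
    }, numeric(1))
    se_i <- vapply(fits[has], function(f) {
      f$coefficients$se[f$coefficients$term == tm]
    }, numeric(1))
    if (mode == "conditional") {
      ws <- w[has] / sum(w[has])
    } else {
      # zero substitution: absent models contribute beta = 0, se = 0
      ws <- w[has]
      est_i <- c(est_i, 0); se_i <- c(se_i, 0); ws <- c(ws, 1 - sum(w[has]))
    }
    est <- sum(ws * est_i)
    se <- sum(ws * sqrt(se_i^2 + (est_i - est)^2))
    lo <- est - 1.96 * se
    hi <- est + 1.96 * se
    data.frame(term = tm, n_models = sum(has), importance = imp,
               lower_ci = lo, upper_ci = hi, estimate = est, se = se,
               strong = (lo > 0 | hi < 0),
               important = imp >= importance_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$importance, out$term), ]
}

#' Full information-theoretic multi-model inference on a contrast table
#'
#' Enumerates the marginality-respecting candidate set (113 models for the 4
#' predictors at pairwise order), fits each by ML, optionally keeps only the
#' best `cap` by AICc (the published workflow tabulated 100), computes Akaike
#' weights, extracts the `mass` confidence set and model-averages it.
#'
#' @param data contrast records (e.g. from [contrast_table()]); rows with
#'   `outlier_flag == TRUE` are dropped if that column is present.
#' @param response `"deltaS"` or `"deltaL"`.
#' @param mains main-effect names.
#' @param cap retain at most this many best-AICc models (default 100;
#'   `Inf` keeps all).
#' @param mass confidence-set cumulative weight (default 0.95).
#' @param importance_threshold importance cutoff (default 0.80).
#' @param mode averaging mode, see [model_average()].
#' @return list: `averaged` (the Table-style data.frame), `ranking`
#'   (per-model AICc/weight/ER table), `confidence_set_size`, `fits`.
#' @export
mmi <- function(data, response = c("deltaS", "deltaL"), mains = .MMI_MAINS,
                cap = 100, mass = 0.95, importance_threshold = 0.80,
                mode = "conditional") {
  response <- match.arg(response)
  if ("outlier_flag" %in% names(data)) data <- data[!data$outlier_flag, ]
  specs <- enumerate_candidates(mains)
  fits <- lapply(specs, fit_lmm, data = data, response = response)
  fits <- weights_and_ratios(fits)
  if (is.finite(cap) && length(fits) > cap) {
    fits <- weights_and_ratios(fits[seq_len(cap)])
  }
  ranking <- data.frame(
    model = vapply(fits, function(f) {
      rhs <- c(f$spec$mains, f$spec$inters)
      if (length(rhs)) paste(rhs, collapse = " + ") else "1"
    }, character(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    delta_aicc = vapply(fits, function(f) f$delta_aicc, numeric(1)),
    weight = vapply(fits, function(f) f$weight, numeric(1)),
    evidence_ratio = vapply(fits, function(f) f$evidence_ratio, numeric(1)),
    stringsAsFactors = FALSE
  )
  cset <- confidence_set(fits, mass = mass)
  averaged <- model_average(cset, importance_threshold = importance_threshold,
                            mode = mode)
  list(averaged = averaged, ranking = ranking,
       confidence_set_size = length(cset), fits = fits)
}
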