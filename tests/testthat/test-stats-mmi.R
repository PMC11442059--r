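# brute-force enumeration oracle: count marginality-respecting models
brute_count <- function(mains) {
  n <- length(mains)
  total <- 0
  for (m in 0:n) {
    sets <- choose(n, m)
    total <- total + sets * 2^choose(m, 2)
  }
  total
}

test_that("candidate enumeration respects marginality", {
  specs <- enumerate_candidates()
  expect_length(specs, 113)
  expect_equal(length(specs), brute_count(c("a", "b", "c", "d")))
  expect_length(enumerate_candidates("a"), 2)
  specs2 <- enumerate_candidates(c("a", "b"))
  expect_length(specs2, 5)
  forms <- vapply(specs2, function(s) {
    paste(c(s$mains, s$inters), collapse = "+")
  }, character(1))
  expect_setequal(forms, c("", "a", "b", "a+b", "a+b+a:b"))
  # every interaction's parents are present
  for (s in specs) {
    for (it in s$inters) {
      expect_true(all(strsplit(it, ":")[[1]] %in% s$mains))
    }
  }
})

test_that("AICc formula, asymptotics and penalty monotonicity", {
  expect_equal(aicc(list(loglik = 0, k = 3, n = 10)), 10)
  # n -> infinity limit is plain AIC (correction is 2k(k+1)/(n-k-1))
  expect_lt(abs(aicc(list(loglik = -5, k = 4, n = 1e9)) - (10 + 8)), 1e-6)
  expect_lt(aicc(list(loglik = -5, k = 2, n = 10)),
            aicc(list(loglik = -5, k = 3, n = 10)))
  expect_error(aicc(list(loglik = 0, k = 9, n = 10)), "AICc undefined")
})

test_that("Akaike weights, evidence ratios and confidence sets", {
  mk <- function(ll, k, n = 100) list(loglik = ll, k = k, n = n)
  one <- weights_and_ratios(list(mk(-10, 2)))
  expect_equal(one[[1]]$weight, 1)
  expect_equal(one[[1]]$evidence_ratio, 1)

  # delta = (0, 2): weights (0.7311, 0.2689), ER2 = e
  two <- weights_and_ratios(list(mk(-10, 2), mk(-11, 2)))
  expect_equal(vapply(two, `[[`, 0, "delta_aicc"), c(0, 2))
  expect_equal(vapply(two, `[[`, 0, "weight"),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(vapply(two, `[[`, 0, "weight"), c(0.7311, 0.2689),
               tolerance = 1e-4)
  expect_equal(two[[2]]$evidence_ratio, exp(1), tolerance = 1e-9)

  # weights invariant to adding a constant to all logliks; sum to 1
  set.seed(8)
  lls <- rnorm(10, -50, 3)
  w1 <- vapply(weights_and_ratios(lapply(lls, mk, k = 3)), `[[`, 0, "weight")
  w2 <- vapply(weights_and_ratios(lapply(lls + 17, mk, k = 3)), `[[`, 0,
               "weight")
  expect_equal(w1, w2, tolerance = 1e-9)
  expect_equal(sum(w1), 1, tolerance = 1e-12)

  # confidence sets
  cs <- function(w) {
    fits <- lapply(w, function(x) list(weight = x))
    length(confidence_set(fits))
  }
  expect_equal(cs(c(0.96, 0.04)), 1)
  expect_equal(cs(c(0.5, 0.3, 0.15, 0.05)), 3)
  expect_equal(cs(rep(1 / 20, 20)), 19)
  fits <- lapply(c(0.5, 0.3, 0.15, 0.04, 0.008, 0.002),
                 function(x) list(weight = x))
  expect_length(confidence_set(fits, rule = "weight_floor"), 4)
})

test_that("model averaging: importance, conditional estimates, strong flags", {
  mkfit <- function(w, terms, est, se) {
    list(weight = w,
         coefficients = data.frame(term = terms, estimate = est, se = se,
                                   stringsAsFactors = FALSE))
  }
  # term in all models with identical beta
  fits <- list(mkfit(0.6, "x", 2, 0.1), mkfit(0.4, "x", 2, 0.1))
  av <- model_average(fits)
  expect_equal(av$estimate, 2)
  expect_equal(av$se, 0.1)
  expect_equal(c(av$lower_ci, av$upper_ci), c(1.804, 2.196))
  expect_true(av$strong)
  expect_equal(av$importance, 1)

  # two models 0.7/0.3, beta 1/2, se 0.1/0.1: unconditional-SE oracle
  # SE = 0.7 sqrt(0.01 + 0.09) + 0.3 sqrt(0.01 + 0.49) = 0.4334912
  fits2 <- list(mkfit(0.7, "x", 1, 0.1), mkfit(0.3, "x", 2, 0.1))
  av2 <- model_average(fits2)
  expect_equal(av2$estimate, 1.3)
  expect_equal(av2$se, 0.7 * sqrt(0.1) + 0.3 * sqrt(0.5), tolerance = 1e-9)
  expect_equal(av2$se, 0.4334912, tolerance = 1e-6)
  expect_equal(av2$lower_ci, 1.3 - 1.96 * av2$se)
  expect_true(av2$strong)  # CI (0.450, 2.150) excludes zero

  # importance threshold: term carried by 83% of the weight is important
  fits3 <- list(mkfit(0.83, c("(Intercept)", "x"), c(0, 1), c(0.1, 0.6)),
                mkfit(0.17, "(Intercept)", 0, 0.1))
  av3 <- model_average(fits3)
  xrow <- av3[av3$term == "x", ]
  expect_equal(xrow$importance, 0.83)
  expect_true(xrow$important)
  expect_equal(xrow$n_models, 1)
  expect_false(xrow$strong)  # CI 1 +/- 1.96*0.6 covers zero

  # zero-substitution mode shrinks the estimate toward zero
  av3z <- model_average(fits3, mode = "zero")
  expect_equal(av3z$estimate[av3z$term == "x"], 0.83 * 1)
})

test_that("fit_lmm degenerates to OLS without individual variance", {
  set.seed(2)
  d <- generate_contrast_table(c("(Intercept)" = 5, morphred = 2),
                               sigma_individual = 0, sigma_resid = 1,
                               seed = 2)
  spec <- list(mains = c("morph"), inters = character(0))
  f <- fit_lmm(spec, d, "deltaS")
  # ML pushes the between-individual variance to (near) the zero boundary;
  # sampling noise in a single draw keeps it a hair above exactly 0
  expect_lt(unname(lme4::VarCorr(f$fit)$individual[1]), 0.05)
  ols <- lm(deltaS ~ morph, data = transform(d, morph = relevel(factor(morph),
                                                                "green")))
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-5)
  expect_equal(f$k, 4)  # 2 fixed + 2 variance parameters
  expect_equal(f$n, 648L)
})

test_that("fit_lmm loglik matches a dense marginal-likelihood oracle", {
  set.seed(3)
  d <- generate_contrast_table(c("(Intercept)" = 5, morphred = 2,
                                 predatorcrab = -1),
                               sigma_individual = 1, sigma_resid = 0.8,
                               seed = 3)
  # small subset keeps the dense 162x162 covariance cheap
  d <- d[d$individual %in% unique(d$individual)[1:18], ]
  spec <- list(mains = c("morph", "predator"), inters = character(0))
  f <- fit_lmm(spec, d, "deltaS")
  vc <- lme4::VarCorr(f$fit)
  sigma_b <- sqrt(unname(vc$individual[1]))
  sigma_e <- attr(vc, "sc")
  dd <- d
  dd$morph <- relevel(factor(dd$morph), "green")
  dd$predator <- relevel(factor(dd$predator), "bird")
  X <- model.matrix(~ morph + predator, dd)
  ll <- dense_lmm_loglik(dd$deltaS, X, dd$individual,
                         f$coefficients$estimate, sigma_b, sigma_e)
  expect_equal(f$loglik, ll, tolerance = 1e-6)
})

test_that("fit_lmm rejects aliased designs and codes reference levels", {
  d <- generate_contrast_table(c("(Intercept)" = 1), seed = 4)
  d$morph <- d$species  # species and morph now aliased? make a true alias:
  d$morph <- ifelse(d$species == "O. pumilio", "red", "green")
  spec <- list(mains = c("species", "morph"), inters = character(0))
  expect_error(fit_lmm(spec, d, "deltaS"), "singular")

  d2 <- generate_contrast_table(c("(Intercept)" = 1, predatorcrab = -1),
                                seed = 5)
  f <- fit_lmm(list(mains = "predator", inters = character(0)), d2, "deltaS")
  expect_setequal(f$coefficients$term,
                  c("(Intercept)", "predatorlizard", "predatorcrab"))
})

test_that("single-replicate parameter recovery through the full MMI", {
  truth <- c("(Intercept)" = 5, morphred = 3, predatorcrab = -2,
             "morphred:predatorcrab" = -2)
  d <- generate_contrast_table(truth, sigma_individual = 1, sigma_resid = 1,
                               seed = 7)
  res <- mmi(d, "deltaS")
  av <- res$averaged
  for (tm in names(truth)) {
    row <- av[av$term == tm, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$estimate - truth[[tm]]), 3 * row$se)
  }
  # crab coefficient negative, per the generating values (sign convention)
  expect_lt(av$estimate[av$term == "predatorcrab"], 0)
  # null species effect: CI covers zero
  sp <- av[av$term == "speciesO. pumilio", ]
  if (nrow(sp) == 1) expect_true(sp$lower_ci < 0 && sp$upper_ci > 0)
  expect_equal(sum(vapply(res$fits, `[[`, 0, "weight")), 1, tolerance = 1e-9)
})
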