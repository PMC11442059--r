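# shared fixtures and independent oracles

grid401 <- rnl_grid()

# a smooth synthetic reflectance on the working grid
smooth_refl <- function(center = 550, width = 60, amp = 0.4, base = 0.05,
                        label = "s") {
  spectrum(grid401, base + amp * exp(-(grid401 - center)^2 / (2 * width^2)),
           role = "reflectance", label = label)
}

flat_illum <- function() {
  spectrum(grid401, rep(1, length(grid401)), role = "irradiance", label = "flat")
}

# independent GLS oracle for the RNL chromatic distance:
# deltaS^2 = min_mu sum_i (df_i - mu)^2 / e_i^2 (uniform direction removed)
gls_delta_S <- function(df, e) {
  mu <- sum(df / e^2) / sum(1 / e^2)
  unname(sqrt(sum((df - mu)^2 / e^2)))
}

# explicit Vorobyev-Osorio tetrachromat closed form
tetra_delta_S <- function(df, e) {
  stopifnot(length(df) == 4, length(e) == 4)
  num <- e[1]^2 * e[2]^2 * (df[4] - df[3])^2 +
    e[1]^2 * e[3]^2 * (df[4] - df[2])^2 +
    e[1]^2 * e[4]^2 * (df[3] - df[2])^2 +
    e[2]^2 * e[3]^2 * (df[4] - df[1])^2 +
    e[2]^2 * e[4]^2 * (df[3] - df[1])^2 +
    e[3]^2 * e[4]^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  unname(sqrt(num / den))
}

# random positive quantum-catch object for a system
random_catch <- function(system, label = "rand") {
  q <- exp(stats::rnorm(nrow(system$receptors), 0, 0.5))
  names(q) <- system$receptors$name
  lum <- switch(system$luminance_rule$type,
                single = sum(q),
                summed = sum(q[system$luminance_rule$receptors]))
  structure(list(raw = q, relative = q / sum(q), lum = lum, label = label,
                 system = system$name, degenerate = FALSE),
            class = "quantum_catch")
}

# direct dense-covariance ML log-likelihood of a random-intercept model,
# evaluated at given (beta, sigma_b, sigma_e) - oracle for fit_lmm's loglik
dense_lmm_loglik <- function(y, X, individual, beta, sigma_b, sigma_e) {
  Z <- stats::model.matrix(~ 0 + factor(individual))
  V <- sigma_b^2 * tcrossprod(Z) + diag(sigma_e^2, length(y))
  r <- y - as.numeric(X %*% beta)
  ch <- chol(V)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}
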