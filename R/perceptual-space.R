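#' Perceptual-space coordinates whose distances equal the JND contrasts
#'
#' Log quantum catches are mapped through the whitening transform of the RNL
#' metric: with \eqn{M} the positive semidefinite matrix whose quadratic form
#' on log-catch differences gives \eqn{\Delta S^2}, coordinates are
#' \eqn{x_s = \Lambda^{1/2} U' f_s} (eigenpairs of \eqn{M}, the null uniform
#' direction dropped), centered across stimuli. Pairwise Euclidean distances
#' then reproduce [delta_S()] exactly. Orientation is fixed by a declared
#' convention: axes ordered by decreasing eigenvalue; axis 1 signed so the
#' stimulus with the largest relative LWS catch (the "reddest") is positive;
#' remaining axes signed so their largest-magnitude receptor loading is
#' positive.
#'
#' @param catches list of `quantum_catch` objects (>= 2) under one system.
#' @param system the `visual_system`.
#' @return an object of class `perceptual_coords`: `labels`, `coords`
#'   (stimuli x (n_receptors - 1), JND), `lum` (centered luminance coordinate
#'   in JND), `system`.
#' @export
jnd_coordinates <- function(catches, system) {
  stopifnot(length(catches) >= 2, inherits(system, "visual_system"))
  if (any(vapply(catches, function(q) q$system, character(1)) != system$name)) {
    stop("catches were computed under a different system", call. = FALSE)
  }
  raw <- t(vapply(catches, function(q) q$raw,
                  numeric(nrow(system$receptors))))
  if (any(raw <= 0)) stop("nonpositive quantum catch", call. = FALSE)
  f <- log(raw)
  M <- .rnl_metric(system$noise)
  eg <- eigen(M, symmetric = TRUE)
  n <- ncol(f)
  vals <- eg$values[seq_len(n - 1)]
  if (any(vals <= 1e-12)) {
    stop("degenerate RNL metric (duplicate receptors?)", call. = FALSE)
  }
  W <- eg$vectors[, seq_len(n - 1), drop = FALSE] %*% diag(sqrt(vals),
                                                           n - 1, n - 1)
  coords <- f %*% W
  coords <- sweep(coords, 2, colMeans(coords))
  # orientation convention
  lws <- which(system$receptors$name == "LWS")
  reddest <- which.max(raw[, lws] / rowSums(raw))
  if (coords[reddest, 1] < 0) {
    coords[, 1] <- -coords[, 1]
    W[, 1] <- -W[, 1]
  }
  if (n - 1 >= 2) {
    for (ax in 2:(n - 1)) {
      lead <- which.max(abs(W[, ax]))
      if (W[lead, ax] < 0) {
        coords[, ax] <- -coords[, ax]
        W[, ax] <- -W[, ax]
      }
    }
  }
  lum_raw <- vapply(catches, function(q) q$lum, numeric(1))
  lum <- log(lum_raw) / system$weber_luminance
  lum <- lum - mean(lum)
  structure(list(
    labels = vapply(catches, function(q) q$label, character(1)),
    coords = coords,
    lum = lum,
    system = system$name
  ), class = "perceptual_coords")
}

#' Two-dimensional chromatic-plus-luminance plane for a dichromat
#'
#' x is the signed chromatic coordinate, oriented so long-wavelength-dominated
#' stimuli sit to the left (negative) and short-wavelength-dominated stimuli
#' to the right (positive); |x_a - x_b| equals [delta_S()]. y is the centered
#' luminance coordinate \eqn{\ln(Q_L)/\omega_L} so |y_a - y_b| equals
#' [delta_L()].
#'
#' @inheritParams jnd_coordinates
#' @export
crab_plane <- function(catches, system) {
  stopifnot(inherits(system, "visual_system"))
  if (nrow(system$receptors) != 2) {
    stop("crab_plane requires a dichromatic system", call. = FALSE)
  }
  if (any(vapply(catches, function(q) q$system, character(1)) != system$name)) {
    stop("catches were computed under a different system", call. = FALSE)
  }
  raw <- t(vapply(catches, function(q) q$raw, numeric(2)))
  if (any(raw <= 0)) stop("nonpositive quantum catch", call. = FALSE)
  sws <- which(system$receptors$name == "SWS")
  lws <- which(system$receptors$name == "LWS")
  e <- system$noise
  x <- (log(raw[, sws]) - log(raw[, lws])) / sqrt(e[sws]^2 + e[lws]^2)
  x <- x - mean(x)
  lum_raw <- vapply(catches, function(q) q$lum, numeric(1))
  y <- log(lum_raw) / system$weber_luminance
  y <- y - mean(y)
  structure(list(
    labels = vapply(catches, function(q) q$label, character(1)),
    coords = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    lum = y,
    system = system$name
  ), class = "perceptual_coords")
}

#' Export perceptual coordinates as a data.frame
#' @param x a `perceptual_coords` object.
#' @param row.names,optional,... unused, for generic consistency.
#' @export
as.data.frame.perceptual_coords <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  df <- data.frame(label = x$labels, stringsAsFactors = FALSE)
  axes <- c("x", "y", "z")[seq_len(ncol(x$coords))]
  for (i in seq_len(ncol(x$coords))) df[[axes[i]]] <- x$coords[, i]
  df$lum <- x$lum
  df
}
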