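#' Quantum catches of a stimulus under a visual system
#'
#' \eqn{Q_i = \sum_\lambda R(\lambda) I(\lambda) S_i(\lambda) \Delta\lambda}
#' on the shared 1-nm grid. The achromatic (luminance) catch follows the
#' system's rule: either the same integral with a dedicated luminance curve
#' (avian double cone) or the sum of the named receptors' catches.
#'
#' @param R reflectance [spectrum()] on the system grid.
#' @param I illuminant [spectrum()] on the system grid.
#' @param system a `visual_system`.
#' @return an object of class `quantum_catch` with elements `raw` (named
#'   per-receptor catches), `relative` (`raw / sum(raw)`), `lum`, `label`,
#'   `system`, and a `degenerate` flag for all-zero stimuli.
#' @export
quantum_catch <- function(R, I, system) {
  stopifnot(inherits(R, "spectrum"), inherits(I, "spectrum"),
            inherits(system, "visual_system"))
  if (!identical(R$wl, system$grid) || !identical(I$wl, system$grid)) {
    stop("reflectance/illuminant grid does not match the visual-system grid",
         call. = FALSE)
  }
  flux <- R$value * I$value
  raw <- as.numeric(crossprod(system$sensitivities, flux))
  names(raw) <- system$receptors$name
  tot <- sum(raw)
  degenerate <- tot <= 0
  rel <- if (degenerate) rep(NA_real_, length(raw)) else raw / tot
  names(rel) <- names(raw)
  lum <- switch(system$luminance_rule$type,
    single = sum(flux * system$luminance_sensitivity),
    summed = sum(raw[system$luminance_rule$receptors]),
    stop("unknown luminance rule", call. = FALSE)
  )
  structure(list(raw = raw, relative = rel, lum = lum, label = R$label,
                 system = system$name, degenerate = degenerate),
            class = "quantum_catch")
}

# Coefficient matrix of the RNL quadratic form on log-catch differences:
# deltaS^2 = sum_{i<j} c_ij (df_i - df_j)^2  with
# c_ij = prod_{k not in {i,j}} e_k^2 / sum_i prod_{k != i} e_k^2
.rnl_coefs <- function(e) {
  n <- length(e)
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i]^2), numeric(1)))
  cij <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cij[i, j] <- prod(e[-c(i, j)]^2) / den
    }
  }
  cij
}

# The same form as an n x n PSD matrix M (kernel = the uniform direction),
# so deltaS^2 = df' M df. Used by the perceptual-space embedding.
.rnl_metric <- function(e) {
  n <- length(e)
  cij <- .rnl_coefs(e)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- -cij[i, j]
      M[i, i] <- M[i, i] + cij[i, j]
      M[j, j] <- M[j, j] + cij[i, j]
    }
  }
  M
}

#' Receptor-noise-limited chromatic contrast (JND)
#'
#' \eqn{\Delta f_i = \ln(Q_{i,a}/Q_{i,b})}; with receptor noises
#' \eqn{e_i = \omega_{ref}\sqrt{\eta_{ref}/\eta_i}} the contrast is
#' \deqn{\Delta S^2 = \frac{\sum_{i<j}\left(\prod_{k\notin\{i,j\}} e_k^2\right)
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i \prod_{k\neq i} e_k^2}}
#' which reduces to the familiar dichromat and tetrachromat closed forms.
#'
#' @param a,b `quantum_catch` objects under the same system.
#' @param system the `visual_system` used for both.
#' @return nonnegative chromatic distance in JND.
#' @export
delta_S <- function(a, b, system) {
  stopifnot(inherits(a, "quantum_catch"), inherits(b, "quantum_catch"))
  if (a$system != system$name || b$system != system$name) {
    stop("quantum catches were computed under a different system", call. = FALSE)
  }
  bad <- c(a$raw, b$raw) <= 0
  if (any(bad)) {
    stop("nonpositive quantum catch in receptor(s): ",
         paste(unique(names(c(a$raw, b$raw))[bad]), collapse = ", "),
         call. = FALSE)
  }
  df <- log(a$raw / b$raw)
  cij <- .rnl_coefs(system$noise)
  n <- length(df)
  s2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s2 <- s2 + cij[i, j] * (df[i] - df[j])^2
    }
  }
  unname(sqrt(s2))
}

#' Achromatic (luminance) contrast (JND)
#'
#' \eqn{\Delta L = |\ln(Q_{L,a}/Q_{L,b})| / \omega_L}.
#'
#' @inheritParams delta_S
#' @export
delta_L <- function(a, b, system) {
  stopifnot(inherits(a, "quantum_catch"), inherits(b, "quantum_catch"))
  if (a$lum <= 0 || b$lum <= 0) {
    stop("nonpositive luminance quantum catch", call. = FALSE)
  }
  abs(log(a$lum / b$lum)) / system$weber_luminance
}

#' Frog-versus-background contrast table
#'
#' One row per frog x visual system x substrate type, holding the chromatic
#' (`deltaS`) and achromatic (`deltaL`) contrast in JND.
#'
#' @param frogs [spectrum_set()] of one spectrum per frog (already averaged),
#'   with design columns `individual`, `species`, `morph`, `locality`.
#' @param backgrounds [spectrum_set()] of one mean spectrum per substrate
#'   type, with design column `type`.
#' @param I illuminant [spectrum()].
#' @param systems list of `visual_system` objects.
#' @param substrate_types the required substrate classes.
#' @return a data.frame of contrast records.
#' @export
contrast_table <- function(frogs, backgrounds, I, systems,
                           substrate_types = c("green_leaf", "leaf_litter",
                                               "trunk")) {
  stopifnot(inherits(frogs, "spectrum_set"), inherits(backgrounds, "spectrum_set"))
  if (!"type" %in% names(backgrounds$design)) {
    stop("background design needs a 'type' column", call. = FALSE)
  }
  missing <- setdiff(substrate_types, backgrounds$design$type)
  if (length(missing)) {
    stop("missing substrate type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (sys in systems) {
    bg_catch <- lapply(substrate_types, function(tp) {
      i <- which(backgrounds$design$type == tp)[1]
      quantum_catch(backgrounds$spectra[[i]], I, sys)
    })
    names(bg_catch) <- substrate_types
    for (fi in seq_along(frogs$spectra)) {
      fc <- quantum_catch(frogs$spectra[[fi]], I, sys)
      d <- frogs$design[fi, ]
      for (tp in substrate_types) {
        rows[[length(rows) + 1]] <- data.frame(
          individual = as.character(d$individual),
          species = as.character(d$species),
          morph = as.character(d$morph),
          locality = as.character(d$locality),
          predator = sys$name,
          substrate = tp,
          deltaS = delta_S(fc, bg_catch[[tp]], sys),
          deltaL = delta_L(fc, bg_catch[[tp]], sys),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Flag outlying contrast records (MAD rule)
#'
#' Within each locality x predator x substrate cell, a record is flagged when
#' its `deltaS` or `deltaL` lies more than `k` median absolute deviations
#' (scaled, consistent with the normal distribution) from the cell median.
#' Records are flagged, never deleted; exclusion is a downstream choice.
#' Cells with fewer than 4 records are left unflagged with a warning.
#'
#' @param records contrast data.frame from [contrast_table()].
#' @param k MAD multiplier (default 3); `Inf` disables flagging.
#' @return `records` with a logical `outlier_flag` column appended.
#' @export
flag_outliers <- function(records, k = 3) {
  records$outlier_flag <- FALSE
  if (!is.finite(k)) return(records)
  cells <- split(seq_len(nrow(records)),
                 interaction(records$locality, records$predator,
                             records$substrate, drop = TRUE))
  small <- FALSE
  for (idx in cells) {
    if (length(idx) < 4) { small <- TRUE; next }
    flag <- rep(FALSE, length(idx))
    for (col in c("deltaS", "deltaL")) {
      x <- records[[col]][idx]
      md <- stats::median(x)
      sc <- stats::mad(x, center = md)
      dev <- abs(x - md)
      flag <- flag | (dev > k * sc & dev > 0)
    }
    records$outlier_flag[idx] <- flag
  }
  if (small) warning("cells with fewer than 4 records were not screened",
                     call. = FALSE)
  records
}
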