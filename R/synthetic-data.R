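#' Default study design: 2 species x red/green morphs over 9 localities
#'
#' Mirrors the field layout the pipeline expects: four O. granulifera
#' localities (two green, two red) and five O. pumilio localities (three red,
#' two green), 8 males per locality, 4 dorsal readings per frog, and three
#' substrate classes (green leaf, leaf litter, trunk) with one object per
#' class per locality and 6 readings per object.
#'
#' @param n_males_per_locality males sampled per locality (default 8).
#' @param n_dorsal_reads replicate dorsum readings per frog (default 4).
#' @param n_substrate_reads replicate readings per substrate object (default 6).
#' @return a `study_design` list.
#' @export
default_design <- function(n_males_per_locality = 8, n_dorsal_reads = 4,
                           n_substrate_reads = 6) {
  localities <- data.frame(
    locality = c("DAM", "ESQ", "SAN", "PAL", "HIT", "ALM", "BAS", "CAY", "POP"),
    species = c(rep("O. granulifera", 4), rep("O. pumilio", 5)),
    morph = c("green", "green", "red", "red", "red", "red", "red",
              "green", "green"),
    stringsAsFactors = FALSE
  )
  structure(list(
    localities = localities,
    n_males_per_locality = n_males_per_locality,
    n_dorsal_reads = n_dorsal_reads,
    substrate_types = c("green_leaf", "leaf_litter", "trunk"),
    n_substrate_reads = n_substrate_reads
  ), class = "study_design")
}

#' Spectral shape parameters for the two dorsal color morphs
#'
#' Red dorsa are modeled as a long-pass reflectance edge
#' (baseline + plateau * logistic((wl - edge)/steepness)); green dorsa as a
#' mid-band Gaussian (baseline + amplitude * exp(-(wl - center)^2 / 2 width^2)).
#' `individual_sd` is the s.d. of a per-frog additive brightness offset;
#' `measurement_sd` that of per-read, per-wavelength noise.
#'
#' @param red_edge,red_steepness,red_plateau red long-pass edge position (nm),
#'   steepness (nm) and plateau height.
#' @param green_center,green_width,green_amplitude green band centre (nm),
#'   Gaussian width (nm) and amplitude.
#' @param baseline common baseline reflectance.
#' @param individual_sd,measurement_sd noise scales (reflectance units).
#' @export
morph_params <- function(red_edge = 590, red_steepness = 10,
                         red_plateau = 0.50, green_center = 550,
                         green_width = 40, green_amplitude = 0.35,
                         baseline = 0.04, individual_sd = 0.015,
                         measurement_sd = 0.008) {
  list(red_edge = red_edge, red_steepness = red_steepness,
       red_plateau = red_plateau, green_center = green_center,
       green_width = green_width, green_amplitude = green_amplitude,
       baseline = baseline, individual_sd = individual_sd,
       measurement_sd = measurement_sd)
}

#' One simulated dorsal reflectance reading
#'
#' @param morph `"red"` or `"green"`.
#' @param params from [morph_params()].
#' @param indiv_offset per-frog additive brightness offset.
#' @param grid wavelength grid.
#' @param label spectrum label.
#' @return a reflectance [spectrum()], clipped to \[0, 1\]. Uses the current
#'   RNG stream for the measurement noise.
#' @export
make_frog_spectrum <- function(morph, params = morph_params(),
                               indiv_offset = 0, grid = rnl_grid(),
                               label = morph) {
  shape <- switch(morph,
    red = params$baseline + params$red_plateau /
      (1 + exp(-(grid - params$red_edge) / params$red_steepness)),
    green = params$baseline + params$green_amplitude *
      exp(-(grid - params$green_center)^2 / (2 * params$green_width^2)),
    stop("unknown morph: ", morph, call. = FALSE)
  )
  v <- shape + indiv_offset +
    stats::rnorm(length(grid), 0, params$measurement_sd)
  spectrum(grid, pmin(pmax(v, 0), 1), role = "reflectance", label = label)
}

#' One simulated substrate reflectance reading
#'
#' green_leaf: green Gaussian (centre 555 nm) with a small near-infrared
#' rise; leaf_litter: monotonically increasing brown ramp; trunk: low, nearly
#' flat gray-brown. Each with per-read measurement noise.
#'
#' @param type one of `"green_leaf"`, `"leaf_litter"`, `"trunk"`.
#' @param measurement_sd per-read noise s.d.
#' @param grid wavelength grid.
#' @param label spectrum label.
#' @export
make_background_spectrum <- function(type, measurement_sd = 0.008,
                                     grid = rnl_grid(), label = type) {
  shape <- switch(type,
    green_leaf = 0.03 + 0.13 * exp(-(grid - 555)^2 / (2 * 40^2)) +
      0.25 / (1 + exp(-(grid - 690) / 8)),
    leaf_litter = 0.04 + 0.28 / (1 + exp(-(grid - 600) / 60)),
    trunk = 0.06 + 0.04 * (grid - 300) / 400,
    stop("unknown substrate type: ", type, call. = FALSE)
  )
  v <- shape + stats::rnorm(length(grid), 0, measurement_sd)
  spectrum(grid, pmin(pmax(v, 0), 1), role = "reflectance", label = label)
}

#' Simulate a full spectral study
#'
#' Generates fully labeled frog and substrate [spectrum_set()]s matching the
#' design (defaults: 9 x 8 x 4 = 288 frog spectra, 9 x 3 x 6 = 162 substrate
#' spectra) plus the bundled forest-shade illuminant. Deterministic under
#' `seed`.
#'
#' @param design a `study_design` (default [default_design()]).
#' @param params morph spectral parameters ([morph_params()]).
#' @param seed integer RNG seed.
#' @return list `frogs`, `substrates` (spectrum_sets), `illuminant`.
#' @export
generate_study <- function(design = default_design(), params = morph_params(),
                           seed = 1) {
  set.seed(seed)
  grid <- rnl_grid()
  frog_sp <- list(); frog_des <- list()
  for (li in seq_len(nrow(design$localities))) {
    loc <- design$localities[li, ]
    for (m in seq_len(design$n_males_per_locality)) {
      ind <- sprintf("%s_%02d", loc$locality, m)
      offset <- stats::rnorm(1, 0, params$individual_sd)
      for (r in seq_len(design$n_dorsal_reads)) {
        lab <- sprintf("%s_r%d", ind, r)
        frog_sp[[length(frog_sp) + 1]] <-
          make_frog_spectrum(loc$morph, params, offset, grid, lab)
        frog_des[[length(frog_des) + 1]] <- data.frame(
          label = lab, individual = ind, species = loc$species,
          morph = loc$morph, locality = loc$locality, type = "frog",
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  sub_sp <- list(); sub_des <- list()
  for (li in seq_len(nrow(design$localities))) {
    loc <- design$localities[li, ]
    for (tp in design$substrate_types) {
      obj <- sprintf("%s_%s", loc$locality, tp)
      for (r in seq_len(design$n_substrate_reads)) {
        lab <- sprintf("%s_r%d", obj, r)
        sub_sp[[length(sub_sp) + 1]] <-
          make_background_spectrum(tp, params$measurement_sd, grid, lab)
        sub_des[[length(sub_des) + 1]] <- data.frame(
          label = lab, individual = obj, species = NA_character_,
          morph = NA_character_, locality = loc$locality, type = tp,
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  list(frogs = spectrum_set(frog_sp, do.call(rbind, frog_des)),
       substrates = spectrum_set(sub_sp, do.call(rbind, sub_des)),
       illuminant = forest_shade_irradiance(grid))
}

#' Simulate a contrast table directly from a linear mixed model
#'
#' Builds the balanced design (individuals nested in localities, crossed with
#' 3 predators x 3 substrates; defaults give 72 x 9 = 648 rows), draws
#' `y = X beta + b_individual + e` with `b ~ N(0, sigma_individual^2)` and
#' `e ~ N(0, sigma_resid^2)`, and returns records ready for [fit_lmm()]/
#' [mmi()]. `beta` is a named vector of model-matrix coefficient names under
#' the standard reference coding (e.g. `"(Intercept)"`, `"morphred"`,
#' `"morphred:predatorcrab"`); unnamed coefficients default to 0.
#'
#' @param beta named numeric vector of true coefficients.
#' @param sigma_individual random-intercept s.d.
#' @param sigma_resid residual s.d.
#' @param design a `study_design`.
#' @param seed integer RNG seed.
#' @param response name of the simulated response column (default `deltaS`).
#' @return a data.frame of contrast records with the simulated response.
#' @export
generate_contrast_table <- function(beta, sigma_individual = 1,
                                    sigma_resid = 1,
                                    design = default_design(), seed = 1,
                                    response = "deltaS") {
  set.seed(seed)
  loc <- design$localities
  inds <- do.call(rbind, lapply(seq_len(nrow(loc)), function(li) {
    data.frame(individual = sprintf("%s_%02d", loc$locality[li],
                                    seq_len(design$n_males_per_locality)),
               species = loc$species[li], morph = loc$morph[li],
               locality = loc$locality[li], stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(ind_row = seq_len(nrow(inds)),
                      predator = c("bird", "lizard", "crab"),
                      substrate = design$substrate_types,
                      stringsAsFactors = FALSE)
  data <- cbind(inds[grid$ind_row, ], grid[c("predator", "substrate")])
  rownames(data) <- NULL
  data <- .code_factors(data)
  X <- stats::model.matrix(
    ~ species * morph + species * substrate + species * predator +
      morph * substrate + morph * predator + substrate * predator, data)
  bvec <- stats::setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(beta), names(bvec))
  if (length(unknown)) {
    stop("beta names not in the design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bvec[names(beta)] <- beta
  b_ind <- stats::setNames(stats::rnorm(nrow(inds), 0, sigma_individual),
                           inds$individual)
  y <- as.numeric(X %*% bvec) + b_ind[as.character(data$individual)] +
    stats::rnorm(nrow(data), 0, sigma_resid)
  data[[response]] <- as.numeric(y)
  data$individual <- as.character(data$individual)
  data$species <- as.character(data$species)
  data$morph <- as.character(data$morph)
  data$predator <- as.character(data$predator)
  data$substrate <- as.character(data$substrate)
  data
}
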