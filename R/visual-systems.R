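#' Visual pigment absorbance template (vitamin-A1 rhodopsin nomogram)
#'
#' Govardovskii-style A1 template: alpha band
#' \deqn{S(x) = 1/(e^{69.7(a-x)} + e^{28(0.922-x)} + e^{-14.9(1.104-x)} + 0.674)}
#' with \eqn{x = \lambda_{max}/\lambda} and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}, plus the
#' standard beta band (amplitude 0.26, centre \eqn{189 + 0.315\lambda_{max}},
#' width \eqn{-40.5 + 0.195\lambda_{max}}). Peak-normalized to 1 on the grid.
#'
#' @param lambda_max peak absorbance wavelength (nm), in \[330, 700\].
#' @param grid wavelength grid (nm), default [rnl_grid()].
#' @return a [spectrum()] (role `"irradiance"` slot reused as a generic curve;
#'   the role is irrelevant for sensitivities and set to `"reflectance"`).
#' @export
pigment_template <- function(lambda_max, grid = rnl_grid()) {
  if (lambda_max < 330 || lambda_max > 700) {
    stop("lambda_max out of supported range [330, 700] nm", call. = FALSE)
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band (A1): Govardovskii et al. constants
  lambda_mb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lambda_mb) / b)^2)
  s <- alpha + beta
  spectrum(grid, s / max(s), role = "reflectance",
           label = sprintf("A1_%gnm", lambda_max))
}

#' Apply an oil-droplet long-pass filter to a sensitivity curve
#'
#' Transmission is a logistic long-pass
#' \eqn{T(\lambda) = 1/(1 + e^{-slope(\lambda - cutoff)})} (T = 0.5 at the
#' cutoff); the filtered curve is re-peak-normalized.
#'
#' @param sensitivity a [spectrum()] sensitivity curve.
#' @param cutoff cut-off wavelength (nm).
#' @param slope steepness in 1/nm (default 0.04).
#' @export
oil_droplet_filter <- function(sensitivity, cutoff, slope = 0.04) {
  stopifnot(inherits(sensitivity, "spectrum"))
  trans <- 1 / (1 + exp(-slope * (sensitivity$wl - cutoff)))
  v <- sensitivity$value * trans
  spectrum(sensitivity$wl, v / max(v), role = sensitivity$role,
           label = sensitivity$label)
}

# Internal constructor shared by the three builders.
# receptors: data.frame(name, lambda_max, oil_cutoff (NA = none), rel_density)
# weber_anchor: receptor name whose noise equals weber_chromatic
.visual_system <- function(name, receptors, weber_chromatic, weber_anchor,
                           luminance_rule, weber_luminance,
                           oil_slope = 0.04, grid = rnl_grid()) {
  sens <- vapply(seq_len(nrow(receptors)), function(i) {
    s <- pigment_template(receptors$lambda_max[i], grid)
    if (!is.na(receptors$oil_cutoff[i])) {
      s <- oil_droplet_filter(s, receptors$oil_cutoff[i], slope = oil_slope)
    }
    s$value
  }, numeric(length(grid)))
  colnames(sens) <- receptors$name
  eta <- receptors$rel_density
  eta_ref <- eta[match(weber_anchor, receptors$name)]
  noise <- weber_chromatic * sqrt(eta_ref / eta)
  names(noise) <- receptors$name
  lum_sens <- NULL
  if (luminance_rule$type == "single") {
    lum_sens <- pigment_template(luminance_rule$lambda_max, grid)$value
  }
  structure(list(
    name = name,
    receptors = receptors,
    grid = grid,
    sensitivities = sens,
    weber_chromatic = weber_chromatic,
    weber_anchor = weber_anchor,
    noise = noise,
    luminance_rule = luminance_rule,
    weber_luminance = weber_luminance,
    luminance_sensitivity = lum_sens,
    oil_slope = oil_slope
  ), class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system '%s': %d receptors (%s), Weber %s = %g, lum Weber = %g>\n",
              x$name, nrow(x$receptors),
              paste(x$receptors$lambda_max, collapse = "/"),
              x$weber_anchor, x$weber_chromatic, x$weber_luminance))
  invisible(x)
}

#' Average UV-sensitive avian visual system
#'
#' Tetrachromat: UVS 370, SWS 458, MWS 547, LWS 600 nm; relative receptor
#' densities 1 : 1.9 : 2.7 : 2.7; no oil-droplet filtering of the templates;
#' chromatic Weber fraction 0.1 anchored at LWS. Achromatic channel: double
#' cone modeled as a single pigment peaking at 563 nm, Weber 0.05.
#'
#' @param oil_slope ignored for the bird (kept for a uniform signature).
#' @param grid wavelength grid.
#' @export
build_bird_system <- function(oil_slope = 0.04, grid = rnl_grid()) {
  rec <- data.frame(
    name = c("UVS", "SWS", "MWS", "LWS"),
    lambda_max = c(370, 458, 547, 600),
    oil_cutoff = NA_real_,
    rel_density = c(1, 1.9, 2.7, 2.7),
    stringsAsFactors = FALSE
  )
  .visual_system("bird", rec, weber_chromatic = 0.1, weber_anchor = "LWS",
                 luminance_rule = list(type = "single", lambda_max = 563),
                 weber_luminance = 0.05, oil_slope = oil_slope, grid = grid)
}

#' Anoline lizard visual system
#'
#' Tetrachromat (A. cristatellus-like): UVS 370, SWS 495, MWS 550, LWS 590 nm
#' with oil-droplet cutoffs 330/371/463/507 nm; densities 1 : 1 : 1 : 3;
#' chromatic Weber fraction 0.05 anchored at LWS. Achromatic channel: summed
#' quantum catch of the two longest-wavelength receptors (MWS + LWS),
#' Weber 0.05.
#'
#' @param oil_slope logistic oil-droplet slope (1/nm), default 0.04.
#' @param grid wavelength grid.
#' @export
build_lizard_system <- function(oil_slope = 0.04, grid = rnl_grid()) {
  rec <- data.frame(
    name = c("UVS", "SWS", "MWS", "LWS"),
    lambda_max = c(370, 495, 550, 590),
    oil_cutoff = c(330, 371, 463, 507),
    rel_density = c(1, 1, 1, 3),
    stringsAsFactors = FALSE
  )
  .visual_system("lizard", rec, weber_chromatic = 0.05, weber_anchor = "LWS",
                 luminance_rule = list(type = "summed",
                                       receptors = c("MWS", "LWS")),
                 weber_luminance = 0.05, oil_slope = oil_slope, grid = grid)
}

#' Fiddler-crab visual system
#'
#' Dichromat: SWS 430, LWS 590 nm; relative densities 1 : 2; no oil droplets;
#' chromatic Weber fraction 0.12 anchored at LWS. Achromatic channel: summed
#' quantum catch of both receptors, Weber 0.12.
#'
#' @param oil_slope ignored for the crab.
#' @param grid wavelength grid.
#' @export
build_crab_system <- function(oil_slope = 0.04, grid = rnl_grid()) {
  rec <- data.frame(
    name = c("SWS", "LWS"),
    lambda_max = c(430, 590),
    oil_cutoff = NA_real_,
    rel_density = c(1, 2),
    stringsAsFactors = FALSE
  )
  .visual_system("crab", rec, weber_chromatic = 0.12, weber_anchor = "LWS",
                 luminance_rule = list(type = "summed",
                                       receptors = c("SWS", "LWS")),
                 weber_luminance = 0.12, oil_slope = oil_slope, grid = grid)
}

#' Build all three predator visual systems
#' @param oil_slope logistic oil-droplet slope for the lizard.
#' @export
build_all_systems <- function(oil_slope = 0.04) {
  list(bird = build_bird_system(oil_slope),
       lizard = build_lizard_system(oil_slope),
       crab = build_crab_system(oil_slope))
}

#' Bundled forest-shade-like illuminant
#'
#' A smooth synthetic stand-in for a forest-shade irradiance measurement:
#' relative photon flux peaked in the mid (green) wavelengths with strong
#' attenuation below 400 nm, positive everywhere, max-normalized. Analyses of
#' real field data should supply the measured illuminant instead (any wide
#' CSV read with [read_spectra()] and `role = "irradiance"`).
#'
#' @param grid wavelength grid.
#' @export
forest_shade_irradiance <- function(grid = rnl_grid()) {
  base <- 0.12 + exp(-((grid - 560)^2) / (2 * 95^2))
  uvcut <- 1 / (1 + exp(-(grid - 410) / 25))
  v <- base * uvcut + 0.01
  spectrum(grid, v / max(v), role = "irradiance", label = "forest_shade")
}

#' Serialize a visual system definition to YAML
#'
#' Only the defining parameters are written (receptor table, Weber fractions,
#' luminance rule, oil slope); sensitivity curves are rebuilt on read.
#'
#' @param sys a `visual_system`.
#' @param path output YAML path.
#' @export
visual_system_to_yaml <- function(sys, path) {
  stopifnot(inherits(sys, "visual_system"))
  obj <- list(
    name = sys$name,
    receptors = lapply(seq_len(nrow(sys$receptors)), function(i) {
      r <- sys$receptors[i, ]
      list(name = r$name, lambda_max = r$lambda_max,
           oil_cutoff = if (is.na(r$oil_cutoff)) NULL else r$oil_cutoff,
           rel_density = r$rel_density)
    }),
    weber_chromatic = sys$weber_chromatic,
    weber_anchor = sys$weber_anchor,
    luminance_rule = sys$luminance_rule,
    weber_luminance = sys$weber_luminance,
    oil_slope = sys$oil_slope
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Rebuild a visual system from a YAML definition
#' @param path YAML file written by [visual_system_to_yaml()].
#' @param grid wavelength grid.
#' @export
visual_system_from_yaml <- function(path, grid = rnl_grid()) {
  obj <- yaml::read_yaml(path)
  rec <- do.call(rbind, lapply(obj$receptors, function(r) {
    data.frame(name = r$name, lambda_max = r$lambda_max,
               oil_cutoff = if (is.null(r$oil_cutoff)) NA_real_ else r$oil_cutoff,
               rel_density = r$rel_density, stringsAsFactors = FALSE)
  }))
  lum <- obj$luminance_rule
  if (lum$type == "summed") lum$receptors <- unlist(lum$receptors)
  .visual_system(obj$name, rec, obj$weber_chromatic, obj$weber_anchor,
                 lum, obj$weber_luminance, obj$oil_slope, grid = grid)
}
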