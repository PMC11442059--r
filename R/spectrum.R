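#' Spectrum objects
#'
#' A `spectrum` is a wavelength-indexed curve: either a reflectance (a
#' dimensionless proportion, nominally in \[0, 1\] but up to ~1.2 for shiny
#' surfaces) or a relative photon irradiance. Wavelengths are stored in
#' nanometres on a strictly increasing grid.
#'
#' @param wl numeric vector of wavelengths (nm), strictly increasing.
#' @param value numeric vector of the same length; reflectance proportion or
#'   relative irradiance.
#' @param role one of `"reflectance"` or `"irradiance"`.
#' @param label free-text identifier.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wl, value, role = c("reflectance", "irradiance"),
                     label = "") {
  role <- match.arg(role)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) != length(value)) {
    stop("wavelength and value vectors differ in length", call. = FALSE)
  }
  if (anyNA(wl)) stop("non-numeric or missing wavelength", call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE)) {
    o <- order(wl)
    if (anyDuplicated(wl)) {
      stop("duplicate wavelengths in spectrum '", label, "'", call. = FALSE)
    }
    warning("wavelengths not sorted in spectrum '", label,
            "'; re-sorting ascending", call. = FALSE)
    wl <- wl[o]
    value <- value[o]
  }
  structure(list(wl = wl, value = value, role = role, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s' (%s): %d points, %g-%g nm>\n",
              x$label, x$role, length(x$wl), min(x$wl), max(x$wl)))
  invisible(x)
}

#' The standard 1-nm working grid, 300-700 nm inclusive (401 points)
#' @export
rnl_grid <- function() as.numeric(300:700)

#' A set of spectra with per-spectrum study metadata
#'
#' @param spectra a list of [spectrum()] objects.
#' @param design a data.frame with one row per spectrum. Column `label` is
#'   mandatory and must match the spectra; the usual study columns are
#'   `individual`, `species`, `morph`, `locality`, `type` and `replicate`.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, design = NULL) {
  stopifnot(is.list(spectra))
  labels <- vapply(spectra, function(s) s$label, character(1))
  if (is.null(design)) {
    design <- data.frame(label = labels, stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(design)) {
    stop("design table must have a 'label' column", call. = FALSE)
  }
  design <- design[match(labels, design$label), , drop = FALSE]
  if (anyNA(design$label)) {
    missing <- labels[is.na(design$label)]
    stop("design table lacks rows for spectra: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  rownames(design) <- NULL
  # replicate-count sanity: 4 dorsal reads per frog, 6 per substrate object
  if (all(c("individual", "replicate") %in% names(design))) {
    tab <- table(design$individual[!is.na(design$individual)])
    if (length(tab) && any(tab > 6)) {
      warning("some individuals/objects have more than 6 replicate spectra",
              call. = FALSE)
    }
  }
  structure(list(spectra = spectra, design = design), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra, design columns: %s>\n",
              length(x$spectra), paste(names(x$design), collapse = ", ")))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' Read spectra from a CSV file
#'
#' Two dialects are supported. `wide`: the first column is wavelength and
#' every further column is one spectrum, named by its header. `long`: columns
#' `(label, wavelength, value)`. Percent-scale reflectances (maximum > 2) are
#' auto-detected and divided by 100 with a warning.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param role `"reflectance"` (default) or `"irradiance"`.
#' @param design optional design `data.frame` or path to a design CSV with a
#'   `label` column matching the spectrum names.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"),
                         role = "reflectance", design = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(design)) {
    design <- utils::read.csv(design, stringsAsFactors = FALSE)
  }
  if (dialect == "wide") {
    wl <- suppressWarnings(as.numeric(raw[[1]]))
    if (anyNA(wl)) {
      stop("non-numeric wavelength at row(s) ",
           paste(utils::head(which(is.na(wl)), 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    spectra <- lapply(names(raw)[-1], function(nm) {
      spectrum(wl, .rescale_percent(as.numeric(raw[[nm]]), role, nm),
               role = role, label = nm)
    })
  } else {
    names(raw)[1:3] <- c("label", "wavelength", "value")
    wl <- suppressWarnings(as.numeric(raw$wavelength))
    if (anyNA(wl)) {
      stop("non-numeric wavelength at row(s) ",
           paste(utils::head(which(is.na(wl)), 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    if (anyDuplicated(paste(raw$label, wl))) {
      stop("duplicate (label, wavelength) pairs in ", path, call. = FALSE)
    }
    spectra <- lapply(split(seq_len(nrow(raw)), raw$label), function(idx) {
      lab <- raw$label[idx[1]]
      spectrum(wl[idx], .rescale_percent(as.numeric(raw$value[idx]), role, lab),
               role = role, label = lab)
    })
    spectra <- unname(spectra)
  }
  spectrum_set(spectra, design)
}

.rescale_percent <- function(v, role, label) {
  if (role == "reflectance" && max(v, na.rm = TRUE) > 2) {
    warning("spectrum '", label,
            "' looks percent-scaled (max > 2); dividing by 100", call. = FALSE)
    v <- v / 100
  }
  v
}

#' Trim a spectrum to the working wavelength window
#'
#' @param s a [spectrum()].
#' @param lo,hi inclusive bounds in nm (defaults 300 and 700).
#' @return the spectrum restricted to `[lo, hi]`.
#' @export
trim_spectrum <- function(s, lo = 300, hi = 700) {
  stopifnot(inherits(s, "spectrum"))
  if (min(s$wl) > lo || max(s$wl) < hi) {
    stop(sprintf("spectrum '%s' covers %g-%g nm; cannot trim to [%g, %g]",
                 s$label, min(s$wl), max(s$wl), lo, hi), call. = FALSE)
  }
  keep <- s$wl >= lo & s$wl <= hi
  spectrum(s$wl[keep], s$value[keep], role = s$role, label = s$label)
}

#' Set negative reflectance values (spectrometer noise) to zero
#' @param s a reflectance [spectrum()].
#' @export
clip_negatives <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$role != "reflectance") {
    stop("clip_negatives applies to reflectance spectra only", call. = FALSE)
  }
  s$value <- pmax(s$value, 0)
  s
}

#' LOESS-smooth a spectrum
#'
#' Locally weighted regression (degree-2 local polynomials, tricube weights,
#' single pass) evaluated back on the input grid; the result is clipped at 0
#' for reflectance spectra.
#'
#' @param s a [spectrum()].
#' @param span fraction of points in each local window (default 0.2).
#' @export
loess_smooth <- function(s, span = 0.2) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$wl)
  if (n < 10) stop("need at least 10 points to smooth", call. = FALSE)
  if (span * n < 4) {
    stop(sprintf("span %g leaves fewer than 4 points per window (n = %d)",
                 span, n), call. = FALSE)
  }
  fit <- stats::loess(value ~ wl, data = data.frame(wl = s$wl, value = s$value),
                      span = span, degree = 2, family = "gaussian",
                      surface = "direct")
  sm <- as.numeric(stats::predict(fit, newdata = data.frame(wl = s$wl)))
  if (s$role == "reflectance") sm <- pmax(sm, 0)
  spectrum(s$wl, sm, role = s$role, label = s$label)
}

#' Linearly interpolate a spectrum onto the standard 1-nm grid
#'
#' @param s a [spectrum()].
#' @param step grid step in nm (default 1).
#' @param lo,hi grid bounds (defaults 300, 700). Extrapolation is an error.
#' @export
interpolate_to_grid <- function(s, step = 1, lo = 300, hi = 700) {
  stopifnot(inherits(s, "spectrum"))
  if (min(s$wl) > lo || max(s$wl) < hi) {
    stop(sprintf("spectrum '%s' covers %g-%g nm; refusing to extrapolate to [%g, %g]",
                 s$label, min(s$wl), max(s$wl), lo, hi), call. = FALSE)
  }
  grid <- seq(lo, hi, by = step)
  v <- stats::approx(s$wl, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v, role = s$role, label = s$label)
}

#' Average replicate spectra within groups
#'
#' Pointwise arithmetic mean of all spectra sharing the same values of the
#' grouping columns. All members of a group must sit on identical grids. The
#' group size is recorded in the output design column `n_averaged`.
#'
#' @param set a [spectrum_set()].
#' @param by character vector of design column names to group by.
#' @return a [spectrum_set()] with one mean spectrum per group.
#' @export
average_replicates <- function(set, by) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!all(by %in% names(set$design))) {
    stop("grouping columns not in design: ",
         paste(setdiff(by, names(set$design)), collapse = ", "), call. = FALSE)
  }
  key <- interaction(set$design[by], drop = TRUE, sep = "|")
  groups <- split(seq_along(set$spectra), key)
  out_sp <- vector("list", length(groups))
  out_design <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    wl0 <- set$spectra[[idx[1]]]$wl
    for (i in idx[-1]) {
      if (!identical(set$spectra[[i]]$wl, wl0)) {
        stop("mismatched wavelength grids within group '",
             names(groups)[g], "'", call. = FALSE)
      }
    }
    vals <- vapply(idx, function(i) set$spectra[[i]]$value, numeric(length(wl0)))
    mean_v <- if (length(idx) == 1) as.numeric(vals) else rowMeans(vals)
    lab <- gsub("\\|", "_", names(groups)[g])
    out_sp[[g]] <- spectrum(wl0, mean_v, role = set$spectra[[idx[1]]]$role,
                            label = lab)
    d <- set$design[idx[1], by, drop = FALSE]
    d$label <- lab
    d$n_averaged <- length(idx)
    out_design[[g]] <- d
  }
  spectrum_set(out_sp, do.call(rbind, out_design))
}

#' Run the standard preprocessing chain on every spectrum of a set
#'
#' trim (300-700 nm) -> clip negatives -> LOESS smooth -> interpolate to the
#' 1-nm grid. Averaging is a separate, explicit step ([average_replicates()]).
#'
#' @param set a [spectrum_set()].
#' @param span LOESS span (default 0.2).
#' @param lo,hi trim bounds.
#' @export
preprocess_spectra <- function(set, span = 0.2, lo = 300, hi = 700) {
  stopifnot(inherits(set, "spectrum_set"))
  set$spectra <- lapply(set$spectra, function(s) {
    s <- trim_spectrum(s, lo, hi)
    if (s$role == "reflectance") s <- clip_negatives(s)
    s <- loess_smooth(s, span = span)
    interpolate_to_grid(s, lo = lo, hi = hi)
  })
  set
}

#' Write a spectrum set to a wide CSV (first column wavelength)
#' @param set a [spectrum_set()] on a common grid.
#' @param path output path.
#' @export
write_spectra <- function(set, path) {
  wl <- set$spectra[[1]]$wl
  df <- data.frame(wl = wl)
  for (s in set$spectra) {
    if (!identical(s$wl, wl)) stop("spectra not on a common grid", call. = FALSE)
    df[[s$label]] <- s$value
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
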