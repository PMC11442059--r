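#' Pipeline configuration
#'
#' Defaults equal the published settings: LOESS span 0.2, 300-700 nm window,
#' 95% confidence-set mass, 0.80 importance threshold, candidate cap 100,
#' 3-MAD outlier flagging.
#'
#' @param frog_spectra,substrate_spectra,illuminant,design_table input CSV
#'   paths (ignored when `simulate = TRUE`).
#' @param out_dir output directory.
#' @param simulate generate synthetic inputs instead of reading files.
#' @param span LOESS span.
#' @param lo,hi wavelength window (nm).
#' @param systems which predator systems to run.
#' @param outlier_k MAD multiplier (`Inf` disables); `use_outlier_rule`
#'   toggles flagging entirely.
#' @param mass,importance_threshold,averaging_mode,cap statistics options.
#' @param seed integer seed for the synthetic generator.
#' @export
pipeline_config <- function(frog_spectra = NULL, substrate_spectra = NULL,
                            illuminant = NULL, design_table = NULL,
                            out_dir = "rnlvision_out", simulate = FALSE,
                            span = 0.2, lo = 300, hi = 700,
                            systems = c("bird", "lizard", "crab"),
                            use_outlier_rule = TRUE, outlier_k = 3,
                            mass = 0.95, importance_threshold = 0.80,
                            averaging_mode = "conditional", cap = 100,
                            seed = 1) {
  structure(list(
    frog_spectra = frog_spectra, substrate_spectra = substrate_spectra,
    illuminant = illuminant, design_table = design_table,
    out_dir = out_dir, simulate = simulate, span = span, lo = lo, hi = hi,
    systems = systems, use_outlier_rule = use_outlier_rule,
    outlier_k = outlier_k, mass = mass,
    importance_threshold = importance_threshold,
    averaging_mode = averaging_mode, cap = cap, seed = seed
  ), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full conspicuousness pipeline
#'
#' Stages: load (or simulate) spectra -> preprocess (trim, clip, LOESS,
#' 1-nm grid) -> average replicates (frogs per individual, substrates per
#' type) -> quantum catches and JND contrasts for each predator -> outlier
#' flagging -> perceptual coordinates per predator -> multi-model inference
#' for deltaS and deltaL. Writes cleaned spectra, the contrast table, one
#' coordinate CSV per predator, the two model-averaged estimate tables, the
#' model-ranking table and a YAML run manifest into `config$out_dir`. On any
#' stage failure the partially written outputs of this run are removed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all in-memory results and `files`, the
#'   paths written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name) {
    path <- file.path(out, name)
    fn(path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    inputs <- .stage("load", {
      if (isTRUE(config$simulate)) {
        generate_study(seed = config$seed)
      } else {
        if (is.null(config$frog_spectra) || is.null(config$substrate_spectra) ||
            is.null(config$illuminant)) {
          stop("input paths missing (frog_spectra, substrate_spectra, ",
               "illuminant) and simulate = FALSE")
        }
        list(
          frogs = read_spectra(config$frog_spectra, "wide",
                               design = config$design_table),
          substrates = read_spectra(config$substrate_spectra, "wide",
                                    design = config$design_table),
          illuminant = interpolate_to_grid(
            read_spectra(config$illuminant, "wide",
                         role = "irradiance")$spectra[[1]],
            lo = config$lo, hi = config$hi)
        )
      }
    })
    clean <- .stage("preprocess", {
      list(frogs = preprocess_spectra(inputs$frogs, config$span,
                                      config$lo, config$hi),
           substrates = preprocess_spectra(inputs$substrates, config$span,
                                           config$lo, config$hi))
    })
    averaged <- .stage("average", {
      list(frogs = average_replicates(clean$frogs,
                                      c("individual", "species", "morph",
                                        "locality")),
           substrates = average_replicates(clean$substrates, "type"))
    })
    emit(function(p) write_spectra(averaged$frogs, p), "cleaned_frogs.csv")
    emit(function(p) write_spectra(averaged$substrates, p),
         "cleaned_substrates.csv")
    systems <- .stage("systems", build_all_systems()[config$systems])
    contrasts <- .stage("contrasts", {
      tab <- contrast_table(averaged$frogs, averaged$substrates,
                            inputs$illuminant, systems)
      if (isTRUE(config$use_outlier_rule)) {
        tab <- flag_outliers(tab, k = config$outlier_k)
      } else {
        tab$outlier_flag <- FALSE
      }
      tab
    })
    emit(function(p) utils::write.csv(contrasts, p, row.names = FALSE),
         "contrasts.csv")
    coords <- .stage("perceptual_space", {
      lapply(systems, function(sys) {
        qc <- lapply(averaged$frogs$spectra, quantum_catch,
                     I = inputs$illuminant, system = sys)
        pc <- if (nrow(sys$receptors) == 2) crab_plane(qc, sys) else
          jnd_coordinates(qc, sys)
        as.data.frame(pc)
      })
    })
    for (nm in names(coords)) {
      local({
        nm_ <- nm
        emit(function(p) utils::write.csv(coords[[nm_]], p, row.names = FALSE),
             sprintf("coords_%s.csv", nm_))
      })
    }
    stats <- .stage("stats", {
      keep <- contrasts[!contrasts$outlier_flag, ]
      lapply(c(deltaS = "deltaS", deltaL = "deltaL"), function(resp) {
        mmi(keep, resp, cap = config$cap, mass = config$mass,
            importance_threshold = config$importance_threshold,
            mode = config$averaging_mode)
      })
    })
    emit(function(p) utils::write.csv(stats$deltaS$averaged, p,
                                      row.names = FALSE),
         "averaged_deltaS.csv")
    emit(function(p) utils::write.csv(stats$deltaL$averaged, p,
                                      row.names = FALSE),
         "averaged_deltaL.csv")
    emit(function(p) {
      rk <- rbind(cbind(response = "deltaS", stats$deltaS$ranking),
                  cbind(response = "deltaL", stats$deltaL$ranking))
      utils::write.csv(rk, p, row.names = FALSE)
    }, "model_ranking.csv")
    emit(function(p) {
      manifest <- unclass(config)
      manifest$version <- as.character(utils::packageVersion("rnlvision"))
      manifest$files <- basename(written)
      yaml::write_yaml(manifest, p)
    }, "manifest.yaml")
    invisible(list(inputs = inputs, clean = clean, averaged = averaged,
                   contrasts = contrasts, coords = coords, stats = stats,
                   files = written))
  }, error = on_fail)
}
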