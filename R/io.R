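## Standard-format I/O: CSV traces with JSON sidecars, YAML experiment
## manifests, JSON result documents.

#' Write / read a current trace as two-column CSV
#'
#' Traces are serialised as `time_s,current_A` CSV at full float64 text
#' precision, with an optional JSON sidecar (`<path>.json`) carrying
#' the condition metadata. Reading validates the grid: uniform spacing
#' (relative deviation < 1e-6), no missing values; violations are
#' rejected with the offending row numbers.
#'
#' @param trace a [signal_trace()].
#' @param path CSV file path.
#' @param sidecar write `<path>.json` metadata.
#' @return `write_trace`: the path, invisibly. `read_trace`: a
#'   [signal_trace()].
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(time_s = sprintf("%.17g", trace$t),
                   current_A = sprintf("%.17g", trace$current))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && length(trace$metadata)) {
    md <- trace$metadata
    md$noiseless <- NULL  # bulky derived payload stays out of sidecars
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "current_A")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns time_s, current_A")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$current_A))
  if (length(bad))
    stop("non-finite values at rows: ", paste(utils::head(bad, 10), collapse = ", "))
  dtv <- diff(df$time_s)
  rel <- abs(dtv - stats::median(dtv)) / stats::median(dtv)
  if (any(rel > 1e-6))
    stop("non-uniform time grid at rows: ",
         paste(utils::head(which(rel > 1e-6) + 1, 10), collapse = ", "))
  md <- list()
  sc <- paste0(path, ".json")
  if (file.exists(sc)) md <- jsonlite::read_json(sc, simplifyVector = TRUE)
  signal_trace(df$time_s, df$current_A, md)
}

#' Write / read / validate an experiment manifest (YAML)
#'
#' The manifest describes one experiment set: schema version, geometry,
#' per-condition initial concentrations (strings with unit suffixes are
#' accepted), flow rate and trace file path, analysis options and the
#' seed.
#'
#' @param experiment a [times_experiment()].
#' @param dir output directory (created if needed); traces are written
#'   as `condition_<j>.csv` alongside `manifest.yaml`.
#' @return `write_experiment`: the manifest path, invisibly.
#'   `read_experiment`: a [times_experiment()].
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "times_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conds <- lapply(seq_along(experiment$conditions), function(j) {
    cd <- experiment$conditions[[j]]
    f <- sprintf("condition_%d.csv", j)
    write_trace(cd$trace, file.path(dir, f))
    list(x_mol_m3 = cd$x, y_mol_m3 = cd$y,
         flow_ul_min = cd$flow_ul_min %||% NA, trace = f)
  })
  g <- experiment$geometry
  man <- list(schema_version = 1L,
              geometry = list(half_height_m = g$L, width_m = g$w,
                              electrode_area_m2 = g$A, viscosity_pa_s = g$mu,
                              temperature_k = g$T, zeta_potential_v = g$zeta,
                              ionic_strength_mol_m3 = g$ionic_strength,
                              relative_permittivity = g$eps_r),
              conditions = conds,
              metadata = experiment$metadata)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' @rdname write_experiment
#' @param path manifest YAML path.
#' @export
read_experiment <- function(path) {
  man <- validate_manifest(path)
  base <- dirname(path)
  g <- man$geometry
  geometry <- channel_geometry(g$half_height_m, g$width_m,
                               g$electrode_area_m2, g$viscosity_pa_s,
                               g$temperature_k, g$zeta_potential_v,
                               g$ionic_strength_mol_m3,
                               g$relative_permittivity)
  conds <- lapply(man$conditions, function(cd)
    list(x = concentration_si(cd$x_mol_m3), y = concentration_si(cd$y_mol_m3),
         flow_ul_min = cd$flow_ul_min,
         trace = read_trace(file.path(base, cd$trace))))
  times_experiment(conds, geometry = geometry,
                   metadata = man$metadata %||% list())
}

#' @rdname write_experiment
#' @export
validate_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  for (f in c("schema_version", "geometry", "conditions"))
    if (is.null(man[[f]])) stop("manifest missing field: ", f)
  if (length(man$conditions) < 1) stop("manifest has no conditions")
  xs <- vapply(man$conditions, function(cd)
    concentration_si(cd$x_mol_m3), numeric(1))
  ys <- vapply(man$conditions, function(cd)
    concentration_si(cd$y_mol_m3), numeric(1))
  if (sum(xs > 0 & ys == 0) != 1)
    stop("manifest must contain exactly one protein-only condition")
  if (sum(xs == 0 & ys > 0) != 1)
    stop("manifest must contain exactly one ligand-only condition")
  base <- dirname(path)
  for (cd in man$conditions) {
    if (is.null(cd$trace)) stop("condition missing trace path")
    if (!file.exists(file.path(base, cd$trace)))
      stop("trace file not found: ", cd$trace)
  }
  invisible(man)
}

#' Serialise a fit to a result document (JSON)
#'
#' The result document carries the modal K_D (and replicate mean and
#' sd when available), the histogram, the dwell-time table, discard
#' diagnostics and provenance (scenario, seed, package version). It
#' round-trips through [read_result()].
#'
#' @param fit a `kd_fit` or `kd_fit_replicates`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_result <- function(fit, path) {
  doc <- if (inherits(fit, "kd_fit_replicates")) {
    list(kind = "replicates",
         kd_mode_mol_m3 = fit$mean, kd_sd_mol_m3 = fit$sd,
         kd_modes_mol_m3 = fit$kd_modes,
         fits = lapply(fit$fits, kd_fit_doc))
  } else kd_fit_doc(fit)
  doc$provenance <- c(doc$provenance,
                      list(package = "timesig",
                           version = as.character(utils::packageVersion("timesig"))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

kd_fit_doc <- function(fit) {
  list(kind = "single",
       kd_mode_mol_m3 = fit$kd_mode,
       kd_mode_uM = concentration_as(fit$kd_mode, "uM"),
       kd_samples_mol_m3 = fit$kd_samples,
       histogram = list(breaks_mol_m3 = fit$histogram$breaks,
                        counts = fit$histogram$counts),
       tau_s = fit$tau_s,
       diagnostics = list(n_analyzed = fit$n_analyzed,
                          n_retained = fit$n_retained,
                          n_discarded = fit$n_discarded,
                          flags = as.list(table(fit$flags))),
       provenance = fit$experiment$metadata)
}

#' @rdname write_result
#' @export
read_result <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
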