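## The K_D pipeline: singles -> per-timepoint solve -> histogram mode,
## packaged as a classed model fit.

#' Control parameters for the K_D pipeline
#'
#' @param n_bins log-spaced histogram bins.
#' @param bracket_mol_l K_D search bracket, mol/L.
#' @param n_scan root pre-scan grid size.
#' @param t_min,t_max analysis window, s. The defaults take the full
#'   record, matching the 1000-of-1000 timepoint analysis of a
#'   1 kHz x 1 s trace; set `t_min` to the diffusion time and `t_max`
#'   to a fraction of the dwell time to enforce the quasi-steady /
#'   short-time validity regimes explicitly.
#' @param min_samples minimum retained K_D samples for the histogram.
#' @param use_third use a third mixture (when present) to disambiguate
#'   multiple roots.
#' @return list of class `kd_control`.
#' @export
kd_control <- function(n_bins = 50, bracket_mol_l = c(1e-12, 1e-2),
                       n_scan = 64, t_min = 0, t_max = Inf,
                       min_samples = 50, use_third = TRUE) {
  structure(list(n_bins = n_bins, bracket_mol_l = bracket_mol_l,
                 n_scan = n_scan, t_min = t_min, t_max = t_max,
                 min_samples = min_samples, use_third = use_third),
            class = "kd_control")
}

#' Assemble an experiment set
#'
#' A named set of measurement conditions, each an initial protein
#' concentration `x`, ligand concentration `y` (mol/m^3, or strings
#' with unit suffix, see [concentration_si()]), a flow rate and a
#' [signal_trace()]. K_D inference needs at least four conditions
#' including exactly one protein-only (`y = 0`) and one ligand-only
#' (`x = 0`), all on a common sampling grid.
#'
#' @param conditions list of lists with fields `x`, `y`, `trace` and
#'   optionally `flow_ul_min`, `name`.
#' @param geometry a [channel_geometry()].
#' @param metadata free-form provenance list.
#' @return Object of class `times_experiment`.
#' @export
times_experiment <- function(conditions, geometry = channel_geometry(),
                             metadata = list()) {
  stopifnot(length(conditions) >= 1)
  conditions <- lapply(conditions, function(cd) {
    cd$x <- concentration_si(cd$x); cd$y <- concentration_si(cd$y)
    stopifnot(cd$x >= 0, cd$y >= 0, inherits(cd$trace, "signal_trace"))
    cd
  })
  t0 <- conditions[[1]]$trace$t
  for (cd in conditions)
    if (length(cd$trace$t) != length(t0) || any(abs(cd$trace$t - t0) > 1e-9))
      stop("all conditions must share one sampling grid")
  structure(list(conditions = conditions, geometry = geometry,
                 metadata = metadata),
            class = "times_experiment")
}

#' @export
print.times_experiment <- function(x, ...) {
  cat(sprintf("<times_experiment: %d conditions, %d samples @ %.6g Hz>\n",
              length(x$conditions), length(x$conditions[[1]]$trace$t),
              x$conditions[[1]]$trace$sampling_rate))
  for (cd in x$conditions)
    cat(sprintf("  x = %.6g, y = %.6g mol/m^3%s\n", cd$x, cd$y,
                if (!is.null(cd$name)) paste0("  (", cd$name, ")") else ""))
  invisible(x)
}

classify_conditions <- function(experiment) {
  xs <- vapply(experiment$conditions, `[[`, numeric(1), "x")
  ys <- vapply(experiment$conditions, `[[`, numeric(1), "y")
  list(protein_only = which(xs > 0 & ys == 0),
       ligand_only = which(xs == 0 & ys > 0),
       mixtures = which(xs > 0 & ys > 0), x = xs, y = ys)
}

#' Fit the dissociation constant from a four-condition experiment
#'
#' The full inverse pipeline: unit responses `G_P`, `G_L` from the two
#' single-species conditions, per-timepoint elimination solve for
#' `K_D` from the first two mixture conditions (a third, when present,
#' disambiguates multiple roots), outlier rejection, log-binned
#' histogram and mode estimation, `G_C(t)` evaluated at the modal
#' `K_D`, and a dwell-time fit per condition.
#'
#' @param experiment a [times_experiment()] (or list of them for
#'   replicate runs, see [fit_kd_replicates()]).
#' @param control a [kd_control()].
#' @return Object of class `kd_fit` with fields `kd_mode` (mol/m^3),
#'   `kd_samples`, `histogram`, `G_P`, `G_L`, `G_C`, `t`, `tau_s`
#'   (data frame per condition), `flags`, `n_retained`, `n_analyzed`,
#'   `control`, `experiment`.
#' @examples
#' \donttest{
#' scen <- reference_scenarios()$trypsin_paba
#' expt <- generate_experiment_set(scen, seed = 7)
#' fit <- fit_kd(expt)
#' coef(fit)          # modal K_D, mol/m^3
#' summary(fit)
#' }
#' @export
fit_kd <- function(experiment, control = kd_control()) {
  stopifnot(inherits(experiment, "times_experiment"))
  cls <- classify_conditions(experiment)
  if (length(cls$protein_only) != 1 || length(cls$ligand_only) != 1)
    stop("experiment needs exactly one protein-only and one ligand-only condition")
  if (length(cls$mixtures) < 2)
    stop("experiment needs at least two mixture conditions")
  conds <- experiment$conditions
  po <- conds[[cls$protein_only]]; lo <- conds[[cls$ligand_only]]
  singles <- unit_responses_from_singles(po$trace, po$x, lo$trace, lo$y)
  t <- singles$t
  win <- which(t >= control$t_min & t <= control$t_max)
  if (length(win) < control$min_samples)
    stop("analysis window retains too few timepoints")

  m1 <- conds[[cls$mixtures[1]]]; m2 <- conds[[cls$mixtures[2]]]
  third <- NULL
  if (control$use_third && length(cls$mixtures) >= 3) {
    m3 <- conds[[cls$mixtures[3]]]
    third <- list(i = m3$trace$current[win], x = m3$x, y = m3$y)
  }
  sol <- solve_kd_timepoint(m1$trace$current[win], m2$trace$current[win],
                            singles$G_P[win], singles$G_L[win],
                            m1$x, m1$y, m2$x, m2$y, third = third,
                            bracket_mol_l = control$bracket_mol_l,
                            n_scan = control$n_scan)
  hist <- kd_histogram_mode(sol$kd, n_bins = control$n_bins,
                            min_samples = control$min_samples)
  kd_mode <- hist$kd_mode

  n1 <- equilibrium_complex(m1$x, m1$y, kd_mode)$n_C
  G_C <- (m1$trace$current - (m1$x - n1) * singles$G_P -
            (m1$y - n1) * singles$G_L) / n1

  tau <- do.call(rbind, lapply(seq_along(conds), function(i) {
    tf <- fit_tau(conds[[i]]$trace)
    data.frame(condition = i, x = conds[[i]]$x, y = conds[[i]]$y,
               flow_ul_min = conds[[i]]$flow_ul_min %||% NA_real_,
               tau_s = tf$tau_s, se = tf$se, ok = tf$ok)
  }))

  structure(list(kd_mode = kd_mode, kd_samples = sol$kd,
                 histogram = hist, flags = sol$flag,
                 n_analyzed = length(win), n_retained = hist$n,
                 n_discarded = sol$discarded,
                 G_P = singles$G_P, G_L = singles$G_L, G_C = G_C, t = t,
                 tau_s = tau, control = control, experiment = experiment,
                 call = match.call()),
            class = "kd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pick a readable display unit for a mol/m^3 concentration
format_conc <- function(x) {
  if (!is.finite(x)) return(format(x))
  molar <- x / 1e3
  if (molar >= 1e-4) sprintf("%.4g mM", molar * 1e3)
  else if (molar >= 1e-7) sprintf("%.4g uM", molar * 1e6)
  else sprintf("%.4g nM", molar * 1e9)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("TIMES dissociation-constant fit\n")
  cat(sprintf("  K_D (histogram mode): %s  [%.6g mol/m^3]\n",
              format_conc(x$kd_mode), x$kd_mode))
  cat(sprintf("  timepoints analyzed: %d, retained: %d, discarded: %d\n",
              x$n_analyzed, x$n_retained, x$n_discarded))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) c(K_D = object$kd_mode)

#' @export
summary.kd_fit <- function(object, ...) {
  s <- object$kd_samples[is.finite(object$kd_samples)]
  out <- list(kd_mode = object$kd_mode,
              kd_quartiles = stats::quantile(s, c(0.25, 0.5, 0.75)),
              n_analyzed = object$n_analyzed,
              n_retained = object$n_retained,
              n_discarded = object$n_discarded,
              flag_table = table(object$flags),
              tau_s = object$tau_s)
  class(out) <- "summary.kd_fit"
  out
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat("TIMES dissociation-constant fit\n")
  cat(sprintf("  K_D (histogram mode): %s\n", format_conc(x$kd_mode)))
  q <- x$kd_quartiles
  cat(sprintf("  per-timepoint K_D quartiles: %s / %s / %s\n",
              format_conc(q[1]), format_conc(q[2]), format_conc(q[3])))
  cat(sprintf("  timepoints: %d analyzed, %d retained, %d discarded\n",
              x$n_analyzed, x$n_retained, x$n_discarded))
  cat("  dwell-time fits per condition:\n")
  print(x$tau_s, row.names = FALSE)
  invisible(x)
}

#' Plot the K_D histogram of a fit
#'
#' @param x a `kd_fit`.
#' @param unit display unit for the abscissa.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.kd_fit <- function(x, unit = c("uM", "nM", "mM", "M"), ...) {
  unit <- match.arg(unit)
  h <- x$histogram
  mids <- sqrt(h$breaks[-1] * h$breaks[-length(h$breaks)])
  graphics::barplot(h$counts, names.arg = signif(concentration_as(mids, unit), 2),
                    xlab = bquote(K[D] ~ "(" * .(unit) * ")"),
                    ylab = "count", border = NA, ...)
  invisible(x)
}

#' Replicate-averaged dissociation constant
#'
#' Runs [fit_kd()] on each experiment of a replicate list and reports
#' the arithmetic mean and sample standard deviation of the modal
#' estimates, the convention for repeated instrument runs.
#'
#' @param experiments list of [times_experiment()] objects.
#' @param control a [kd_control()].
#' @return Object of class `kd_fit_replicates`: `fits`, `kd_modes`,
#'   `mean`, `sd`.
#' @export
fit_kd_replicates <- function(experiments, control = kd_control()) {
  stopifnot(length(experiments) >= 2)
  fits <- lapply(experiments, fit_kd, control = control)
  modes <- vapply(fits, `[[`, numeric(1), "kd_mode")
  structure(list(fits = fits, kd_modes = modes,
                 mean = mean(modes), sd = stats::sd(modes)),
            class = "kd_fit_replicates")
}

#' @export
print.kd_fit_replicates <- function(x, ...) {
  cat(sprintf("Replicate K_D: %s +/- %s (n = %d)\n",
              format_conc(x$mean), format_conc(x$sd), length(x$kd_modes)))
  invisible(x)
}

#' @export
coef.kd_fit_replicates <- function(object, ...)
  c(K_D = object$mean, sd = object$sd)
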