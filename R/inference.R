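## Inverse analyses: Tikhonov kernel deconvolution, exponential
## dwell-time fitting, and the per-timepoint dissociation-constant
## solver with histogram-mode estimation.

#' Recover the per-molecule charge kernel by regularised deconvolution
#'
#' Given a measured current trace and a model of the molecular flux
#' J(t), invert the discrete convolution `Q(t) = A (q * J)(t)` (with
#' `Q` the cumulative integral of the current) for the kernel samples
#' q(t) by Tikhonov regularisation:
#' `min_q ||A C q - Q||^2 + lambda^2 ||q||^2` where `C` is the causal
#' (trapezoid) convolution operator built from J. The recovered kernel
#' is reported normalised to unit peak magnitude, as kernels are
#' conventionally plotted.
#'
#' @param trace a [signal_trace()].
#' @param J flux series on the trace grid, 1/(m^2 s); must be nonzero
#'   over a support window.
#' @param A electrode area, m^2.
#' @param lambda regularisation parameter (same scale as `A C`;
#'   0 = unregularised).
#' @param condition_warn warn when the estimated condition number of
#'   the regularised normal matrix exceeds this.
#' @return list of class `kernel_estimate`: `t`, `q` (unit peak),
#'   `q_raw` (C), `residual_norm`, `condition`.
#' @export
deconvolve_kernel <- function(trace, J, A, lambda = 0,
                              condition_warn = 1e10) {
  stopifnot(inherits(trace, "signal_trace"), length(J) == length(trace$t))
  if (all(J == 0)) stop("flux J is identically zero: kernel unidentifiable")
  dt <- 1 / trace$sampling_rate
  n <- length(J)
  Q <- cumtrapz_uniform(trace$current, dt)
  # causal trapezoid convolution matrix in the kernel samples:
  # (Cq)_k = dt * sum_{j=0}^{k} w_j q_{k-j} J_j, w half at both ends
  C <- matrix(0, n, n)
  for (k in seq_len(n)) {
    j <- 0:(k - 1)          # flux index (0-based)
    w <- rep(1, k); w[1] <- 0.5; w[k] <- 0.5
    C[k, k - j] <- dt * w * J[j + 1]
  }
  M <- A * C
  G <- crossprod(M) + diag(lambda^2, n)
  cond <- kappa(G, exact = FALSE)
  if (is.finite(cond) && cond > condition_warn)
    warning(sprintf("deconvolution ill-conditioned (cond ~ %.3g)", cond))
  q_raw <- solve(G, crossprod(M, Q))[, 1]
  resid <- sqrt(sum((M %*% q_raw - Q)^2))
  peak <- max(abs(q_raw))
  q <- if (peak > 0) q_raw / peak else q_raw
  structure(list(t = trace$t, q = q, q_raw = q_raw,
                 residual_norm = resid, condition = cond),
            class = "kernel_estimate")
}

#' Fit the surface dwell time from the relaxation tail of a trace
#'
#' Fits a single-exponential relaxation `i(t) = A0 exp(-(t - t1)/tau) + c`
#' to the final decay segment of the trace by Levenberg-Marquardt least
#' squares. The fitted segment is the final monotone relaxation: the
#' record is smoothed lightly, and the segment runs from the extremum
#' of largest magnitude after the last zero crossing of the smoothed
#' signal (for a crossing-free, monotone trace: from the global peak of
#' |i|) to the end; when the trace is biphasic the segment start is
#' then refined iteratively (half a fitted time constant forward,
#' twice) so that fast kernel transients riding on the relaxation do
#' not bias the fit. Degenerate inputs (no decaying tail, negative or
#' wildly uncertain tau) are flagged as failures rather than returning
#' a silent value.
#'
#' @param trace a [signal_trace()], or a numeric current vector with
#'   `t` supplied.
#' @param t time grid when `trace` is a bare vector.
#' @param smooth_frac width of the running-mean smoother used only for
#'   segment selection, as a fraction of the record length.
#' @param max_rel_se flag failure when se(tau)/tau exceeds this.
#' @return Object of class `tau_fit`: `tau_s`, `se`, `A0`, `c`, `ok`,
#'   `reason`, `segment` (index range), `fitted`, `residuals`.
#' @export
fit_tau <- function(trace, t = NULL, smooth_frac = 0.005,
                    max_rel_se = 0.5) {
  if (inherits(trace, "signal_trace")) {
    y <- trace$current; t <- trace$t
  } else {
    y <- trace
    stopifnot(!is.null(t), length(t) == length(y))
  }
  n <- length(y)
  fail <- function(reason) structure(
    list(tau_s = NA_real_, se = NA_real_, A0 = NA_real_, c = NA_real_,
         ok = FALSE, reason = reason, segment = NA, fitted = NULL,
         residuals = NULL), class = "tau_fit")

  peak <- max(abs(y))
  if (peak == 0) return(fail("flat signal"))
  # locate the final monotone relaxation on a lightly smoothed copy
  w <- max(3L, round(smooth_frac * n))
  sm <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ok_idx <- which(!is.na(sm))
  sm[seq_len(ok_idx[1] - 1)] <- sm[ok_idx[1]]
  if (ok_idx[length(ok_idx)] < n)
    sm[(ok_idx[length(ok_idx)] + 1):n] <- sm[ok_idx[length(ok_idx)]]
  # high-frequency noise level; smoothed-trace fluctuations scale by 1/sqrt(w)
  noise_hf <- stats::sd(diff(y)) / sqrt(2)
  thresh <- max(5 * noise_hf / sqrt(w), 0.1 * max(abs(sm)))
  cross <- which(sm[-1] * sm[-n] < 0)
  # keep only zero crossings with a significant smoothed extremum on
  # both sides (a genuine lobe transition, not a noise wiggle) and a
  # long enough tail to characterise a relaxation
  cross <- cross[vapply(cross, function(z) {
    if (n - z < max(50, round(0.1 * n))) return(FALSE)
    s_post <- sign(sm[z + 1])
    if (s_post == 0) return(FALSE)
    pre <- max(1, z - round(0.1 * n)):z
    max(s_post * sm[(z + 1):n]) >= thresh &&
      max(-s_post * sm[pre]) >= thresh
  }, logical(1))]
  i1 <- if (length(cross) == 0) which.max(abs(y)) else {
    z <- max(cross) + 1L
    z - 1L + which.max(abs(sm[z:n]))
  }
  if (n - i1 < 10) return(fail("tail too short"))
  dt <- t[2] - t[1]

  fit_from <- function(i1) {
    ts <- t[i1:n] - t[i1]
    ys <- y[i1:n]
    span <- ts[length(ts)]
    # starting values from the segment ends + log-linear slope
    c0 <- mean(ys[max(1, length(ys) - round(0.1 * length(ys))):length(ys)])
    a0 <- ys[1] - c0
    if (abs(a0) < .Machine$double.eps) return(NULL)
    amp <- abs(ys - c0) / abs(a0)
    pos <- which(amp > 0.05 & seq_along(amp) > 1)
    tau0 <- if (length(pos) > 5) {
      fitl <- stats::lm(log(amp[pos]) ~ ts[pos])
      sl <- unname(stats::coef(fitl)[2])
      if (is.finite(sl) && sl < 0) -1 / sl else span / 3
    } else span / 3
    best <- NULL
    for (tau_try in unique(c(tau0, span / 20, span / 5, span / 2))) {
      f <- tryCatch(
        minpack.lm::nlsLM(ys ~ A0 * exp(-ts / tau) + c,
                          start = list(A0 = a0, tau = tau_try, c = c0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f) && is.finite(stats::coef(f)["tau"]) &&
          stats::coef(f)["tau"] > 0 &&
          (is.null(best) || stats::deviance(f) < stats::deviance(best)))
        best <- f
    }
    best
  }

  fit <- fit_from(i1)
  if (is.null(fit)) return(fail("nonlinear fit failed"))
  # fast kernel components riding on the segment head bias a
  # one-exponential fit low; restart the segment half a fitted time
  # constant past the lobe base and refit (fixed-point iteration) -- a
  # pure exponential is invariant under this, while contamination
  # decays away
  base <- i1
  for (pass in 1:3) {
    tau_hat <- unname(stats::coef(fit)["tau"])
    i1_new <- base + as.integer(round(0.5 * tau_hat / dt))
    i1_new <- min(i1_new, n - max(30L, round(0.03 * n)))
    if (i1_new <= base || i1_new == i1) break
    refit <- fit_from(i1_new)
    if (is.null(refit)) break
    i1 <- i1_new
    fit <- refit
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  tau_hat <- unname(cf["tau"])
  if (!is.finite(tau_hat) || tau_hat <= 0) return(fail("non-positive tau"))
  if (tau_hat > 50 * (t[n] - t[i1])) return(fail("tau beyond data span"))
  if (!is.finite(se) || se / tau_hat > max_rel_se)
    return(fail("tau not identified (relative stderr too large)"))
  structure(list(tau_s = tau_hat, se = unname(se), A0 = unname(cf["A0"]),
                 c = unname(cf["c"]), ok = TRUE, reason = "ok",
                 segment = c(i1, n), fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Surface dwell time tau_s = %.4g s (se %.2g s)\n",
                x$tau_s, x$se))
  else cat("tau_s fit failed:", x$reason, "\n")
  invisible(x)
}

#' @export
coef.tau_fit <- function(object, ...) c(tau_s = object$tau_s)

#' @export
residuals.tau_fit <- function(object, ...) object$residuals

#' Unit-concentration responses from the single-species conditions
#'
#' In the protein-only condition the signal is `x G_P(t)`, in the
#' ligand-only condition `y G_L(t)`; dividing by the known loading
#' concentrations yields the unit responses directly.
#'
#' @param protein_only [signal_trace()] of the protein-only condition.
#' @param x protein concentration in that condition, mol/m^3, > 0.
#' @param ligand_only [signal_trace()] of the ligand-only condition.
#' @param y ligand concentration in that condition, mol/m^3, > 0.
#' @return list `G_P`, `G_L` (A per mol/m^3) on the common grid `t`.
#' @export
unit_responses_from_singles <- function(protein_only, x, ligand_only, y) {
  stopifnot(inherits(protein_only, "signal_trace"),
            inherits(ligand_only, "signal_trace"))
  if (x <= 0 || y <= 0) stop("single-condition concentrations must be > 0")
  if (length(protein_only$t) != length(ligand_only$t) ||
      any(abs(protein_only$t - ligand_only$t) > 1e-9))
    stop("single-species traces are not on a common grid")
  list(G_P = protein_only$current / x, G_L = ligand_only$current / y,
       t = protein_only$t)
}

# Residual of the second mixture equation after eliminating G_C through
# the first: vectorised over timepoints for a scalar K_D (mol/m^3).
kd_residual <- function(K_D, i1, i2, G_P, G_L, x1, y1, x2, y2) {
  n1 <- equilibrium_complex(x1, y1, K_D)$n_C
  n2 <- equilibrium_complex(x2, y2, K_D)$n_C
  if (n1 <= 0) return(rep(NA_real_, length(i1)))
  G_C <- (i1 - (x1 - n1) * G_P - (y1 - n1) * G_L) / n1
  i2 - (x2 - n2) * G_P - (y2 - n2) * G_L - n2 * G_C
}

#' Solve for the dissociation constant at single timepoints
#'
#' At each timepoint the two mixture equations
#' `i_m = n_P(m) G_P + n_L(m) G_L + n_C(m) G_C`, m = 1, 2, share the
#' unknowns `K_D` (through the equilibrium concentrations) and `G_C`.
#' `G_C` is eliminated through mixture 1 and the root of the remaining
#' scalar equation in `K_D` is found by a bracketed search over
#' `log10 K_D` (default 1 pM to 10 mM). Timepoints with no bracketed
#' sign change, or a root pinned at the bracket edge, are discarded
#' (these are the noise spikes that become histogram outliers). When a
#' third mixture is supplied it disambiguates multiple roots (smallest
#' residual on the third equation); otherwise the smallest root is
#' kept and flagged.
#'
#' @param i1,i2 mixture current series (A) on the common grid.
#' @param G_P,G_L unit responses from
#'   [unit_responses_from_singles()].
#' @param x1,y1,x2,y2 initial concentrations of the two mixtures,
#'   mol/m^3; the two designs must differ and both must contain both
#'   species.
#' @param third optional list `(i, x, y)` of a third mixture used for
#'   root disambiguation.
#' @param bracket_mol_l K_D search bracket in mol/L (converted
#'   internally), default `c(1e-12, 1e-2)`.
#' @param n_scan pre-scan grid size for sign changes.
#' @param tol relative root tolerance on log10(K_D).
#' @return list: `kd` (mol/m^3, NA where discarded), `flag` (character
#'   per timepoint: "ok", "no_root", "edge", "multiple"), counts in
#'   `discarded`.
#' @export
solve_kd_timepoint <- function(i1, i2, G_P, G_L, x1, y1, x2, y2,
                               third = NULL,
                               bracket_mol_l = c(1e-12, 1e-2),
                               n_scan = 64, tol = 1e-10) {
  if (x1 <= 0 || y1 <= 0 || x2 <= 0 || y2 <= 0)
    stop("both mixtures must contain protein and ligand (x, y > 0)")
  if (x1 == x2 && y1 == y2) stop("mixture designs must differ")
  n <- length(i1)
  stopifnot(length(i2) == n, length(G_P) == n, length(G_L) == n)

  lgrid <- seq(log10(bracket_mol_l[1] * 1e3), log10(bracket_mol_l[2] * 1e3),
               length.out = n_scan)
  R <- vapply(lgrid, function(lk)
    kd_residual(10^lk, i1, i2, G_P, G_L, x1, y1, x2, y2), numeric(n))
  kd <- rep(NA_real_, n)
  flag <- rep("no_root", n)
  fk <- function(lk, k) kd_residual(10^lk, i1[k], i2[k], G_P[k], G_L[k],
                                    x1, y1, x2, y2)
  for (k in seq_len(n)) {
    rk <- R[k, ]
    sgn <- sign(rk)
    ch <- which(sgn[-1] * sgn[-n_scan] < 0)
    if (length(ch) == 0) {
      zero <- which(rk == 0)
      if (length(zero)) { kd[k] <- 10^lgrid[zero[1]]; flag[k] <- "ok" }
      next
    }
    roots <- vapply(ch, function(j) {
      r <- stats::uniroot(fk, c(lgrid[j], lgrid[j + 1]), k = k,
                          tol = tol, f.lower = rk[j], f.upper = rk[j + 1])
      r$root
    }, numeric(1))
    if (length(roots) > 1) {
      if (!is.null(third)) {
        res3 <- vapply(roots, function(lk) {
          K <- 10^lk
          n1 <- equilibrium_complex(x1, y1, K)$n_C
          n3 <- equilibrium_complex(third$x, third$y, K)$n_C
          G_C <- (i1[k] - (x1 - n1) * G_P[k] - (y1 - n1) * G_L[k]) / n1
          abs(third$i[k] - (third$x - n3) * G_P[k] -
                (third$y - n3) * G_L[k] - n3 * G_C)
        }, numeric(1))
        root <- roots[which.min(res3)]
      } else root <- min(roots)
      flag[k] <- "multiple"
    } else {
      root <- roots[1]
      flag[k] <- "ok"
    }
    # discard roots pinned at the bracket edge
    if (root < lgrid[1] + 0.5 * diff(lgrid[1:2]) ||
        root > lgrid[n_scan] - 0.5 * diff(lgrid[1:2])) {
      kd[k] <- NA_real_
      flag[k] <- "edge"
    } else kd[k] <- 10^root
  }
  list(kd = kd, flag = flag,
       discarded = sum(is.na(kd)))
}

#' Histogram-mode estimate of the dissociation constant
#'
#' Bins the retained per-timepoint K_D samples into log10-spaced bins
#' and reports the arithmetic mean of the samples in the most populated
#' bin (ties broken towards the lower bin). Outliers flagged upstream
#' (NA samples) are excluded before binning.
#'
#' @param kd_samples per-timepoint K_D values, mol/m^3 (NAs dropped).
#' @param n_bins number of log-spaced bins.
#' @param min_samples minimum retained samples required.
#' @return list: `breaks` (bin edges, mol/m^3), `counts`, `kd_mode`
#'   (mean of modal bin), `modal_bin`, `n`.
#' @export
kd_histogram_mode <- function(kd_samples, n_bins = 50, min_samples = 50) {
  s <- kd_samples[is.finite(kd_samples) & kd_samples > 0]
  if (length(s) < min_samples)
    stop(sprintf("too few retained K_D samples (%d < %d)",
                 length(s), min_samples))
  ls <- log10(s)
  rng <- range(ls)
  if (diff(rng) == 0) {
    v <- 10^rng[1]
    return(list(breaks = 10^(rng[1] + c(-0.5, 0.5) * 1e-6),
                counts = length(s), kd_mode = v, modal_bin = 1L,
                n = length(s)))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(ls, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  modal <- which.max(counts)  # which.max takes the first (lower) tie
  list(breaks = 10^edges, counts = counts,
       kd_mode = mean(s[bin == modal]), modal_bin = modal, n = length(s))
}
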