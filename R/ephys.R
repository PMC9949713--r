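#' Quality-control filter for recorded cells
#'
#' Keeps cells with input resistance at or above \code{r_in_min} (megaohm)
#' and cell-attached seal resistance at or above \code{r_seal_min}
#' (gigaohm); both boundaries are inclusive. Cells with missing metadata
#' are discarded with reason \code{"missing"}.
#'
#' @param cells Data frame with columns \code{cell}, \code{r_in_mohm},
#'   \code{r_seal_gohm}.
#' @param r_in_min Minimum input resistance, megaohm (default 300).
#' @param r_seal_min Minimum seal resistance, gigaohm (default 1).
#' @return \code{cells} with added logical \code{kept} and character
#'   \code{reason} columns.
#' @export
qc_filter <- function(cells, r_in_min = 300, r_seal_min = 1) {
  stopifnot(all(c("cell", "r_in_mohm", "r_seal_gohm") %in% names(cells)))
  miss <- is.na(cells$r_in_mohm) | is.na(cells$r_seal_gohm)
  low_rin <- !miss & cells$r_in_mohm < r_in_min
  low_seal <- !miss & cells$r_seal_gohm < r_seal_min
  cells$kept <- !miss & !low_rin & !low_seal
  cells$reason <- ""
  cells$reason[miss] <- "missing"
  cells$reason[low_rin] <- "r_in"
  cells$reason[low_seal & !low_rin] <- "r_seal"
  cells$reason[low_seal & low_rin] <- "r_in,r_seal"
  cells
}

#' Nernst equilibrium potential
#'
#' \eqn{V = (1000 R T / z F) \ln(c_{out}/c_{in})} in millivolt, with
#' \eqn{R = 8.314} J/(mol K) and \eqn{F = 96485} C/mol.
#'
#' @param c_out,c_in Extra-/intracellular concentration (mM), positive.
#' @param z Ionic valence (non-zero integer).
#' @param temperature_k Temperature in kelvin (default 295.15, room
#'   temperature).
#' @return Potential in mV.
#' @examples
#' nernst_potential(5, 210, z = 1)    # potassium, ~ -95 mV
#' @export
nernst_potential <- function(c_out, c_in, z, temperature_k = 295.15) {
  if (any(c_out <= 0) || any(c_in <= 0)) stop("concentrations must be positive")
  if (any(z == 0)) stop("valence must be non-zero")
  R <- 8.314; F <- 96485
  1000 * R * temperature_k / (z * F) * log(c_out / c_in)
}

#' Recording solution ion totals
#'
#' Per-ion totals (mM) of the extracellular artificial-seawater and
#' intracellular KCl/glucose recipes used for the whole-cell recordings.
#' Chloride is the sum over all chloride salts in each recipe.
#'
#' @return Data frame \code{ion}, \code{valence}, \code{out_mm},
#'   \code{in_mm}.
#' @export
solution_recipes <- function() {
  # out: 486 NaCl + 5 KCl + 13.6 CaCl2 + 9.8 MgCl2; in: 210 KCl + 696 glucose
  data.frame(
    ion = c("Na", "K", "Ca", "Mg", "Cl"),
    valence = c(1, 1, 2, 2, -1),
    out_mm = c(486, 5, 13.6, 9.8, 486 + 5 + 2 * 13.6 + 2 * 9.8),
    in_mm = c(NA, 210, NA, NA, 210),
    stringsAsFactors = FALSE
  )
}

#' Predicted reversal potentials for ideal selective channels
#'
#' Nernst predictions for an ideal potassium-, chloride-, and monovalent
#' cation-selective channel under the recording solutions (see
#' \code{\link{solution_recipes}}). The monovalent cation prediction pools
#' Na and K on each side.
#'
#' @param temperature_k Temperature in kelvin.
#' @return Named numeric vector (mV): \code{K}, \code{Cl}, \code{X} for the
#'   pooled monovalent cation.
#' @export
predicted_reversal_potentials <- function(temperature_k = 295.15) {
  s <- solution_recipes()
  k <- s[s$ion == "K", ]
  cl <- s[s$ion == "Cl", ]
  na_out <- s$out_mm[s$ion == "Na"]
  c(K = nernst_potential(k$out_mm, k$in_mm, 1, temperature_k),
    Cl = nernst_potential(cl$out_mm, cl$in_mm, -1, temperature_k),
    X = nernst_potential(na_out + k$out_mm, k$in_mm, 1, temperature_k))
}

#' Estimate the unitary current amplitude of a segment
#'
#' Fits the all-points amplitude histogram with an equal-variance Gaussian
#' mixture of 1 to \code{max_components} components, selected by BIC. One
#' component means no resolvable channel activity. Otherwise the unitary
#' amplitude is the median spacing between adjacent level means, signed by
#' the direction of the open levels relative to the baseline (the mode of
#' the all-points histogram).
#'
#' @param segment Numeric current trace (pA).
#' @param voltage Command voltage (mV), carried into the result.
#' @param sampling_khz Sampling rate (kHz); used to enforce the minimum
#'   segment duration of 50 ms.
#' @param max_components Mixture component cap (default 4, allowing for
#'   short-lived subconductance levels without unbounded model growth).
#' @param max_points At most this many points are used for the mixture fit
#'   (even subsampling); default 5000.
#' @param min_weight Components with a smaller mixing proportion are not
#'   counted as resolved levels (default 0.02); this discards the sparse
#'   filter-transition samples between levels.
#' @return List with \code{voltage}, \code{i} (pA, \code{NA} when no
#'   activity), \code{n_levels}, \code{level_means}, \code{baseline},
#'   \code{active}.
#' @export
estimate_unitary_amplitude <- function(segment, voltage, sampling_khz,
                                       max_components = 4,
                                       max_points = 5000,
                                       min_weight = 0.02) {
  n <- length(segment)
  if (n / sampling_khz < 50) {
    stop("segment shorter than 50 ms (", round(n / sampling_khz, 1), " ms)")
  }
  pts <- if (n > max_points) segment[seq(1L, n, length.out = max_points)] else segment
  fit <- mclust::Mclust(pts, G = 1:max_components, modelNames = "E",
                        verbose = FALSE)
  means <- as.numeric(fit$parameters$mean)
  wts <- as.numeric(fit$parameters$pro)
  sdev <- sqrt(fit$parameters$variance$sigmasq[1])
  keep <- wts >= min_weight
  means <- means[keep]; wts <- wts[keep]
  o <- order(means); means <- means[o]; wts <- wts[o]
  # merge means closer than the amplitude resolution (3 noise SDs)
  while (length(means) > 1L && any(diff(means) < 3 * sdev)) {
    j <- which.min(diff(means))
    w <- wts[j] + wts[j + 1L]
    means[j] <- (means[j] * wts[j] + means[j + 1L] * wts[j + 1L]) / w
    wts[j] <- w
    means <- means[-(j + 1L)]; wts <- wts[-(j + 1L)]
  }
  # the closed level dominates the all-points histogram
  baseline <- means[which.max(wts)]
  if (length(means) == 1L) {
    return(list(voltage = voltage, i = NA_real_, n_levels = 1L,
                level_means = means, baseline = baseline, active = FALSE))
  }
  spacing <- stats::median(diff(means))
  far <- means[which.max(abs(means - baseline))]
  i <- spacing * sign(far - baseline)
  list(voltage = voltage, i = i, n_levels = length(means),
       level_means = means, baseline = baseline, active = TRUE)
}

#' Half-amplitude idealization of a single-channel trace
#'
#' Assigns each sample to occupancy level k when the current lies within
#' half a unitary amplitude of \code{baseline + k * i}, merges dwells
#' shorter than twice the filter rise time (0.3321 / f_c) into their
#' neighbours, and reports the dwell sequence and the maximum number of
#' simultaneously open channels.
#'
#' @param segment Numeric current trace (pA).
#' @param i Unitary amplitude (pA, non-zero; sign gives current direction).
#' @param baseline Closed-level current (pA).
#' @param sampling_khz Sampling rate (kHz).
#' @param filter_khz Low-pass filter cutoff (kHz); sets the dead time.
#' @return List with \code{levels} (per-sample), \code{dwells} (data frame
#'   \code{level}, \code{start_ms}, \code{duration_ms}), \code{N} (max
#'   level) and \code{open_fraction} (time-averaged level / N).
#' @export
idealize <- function(segment, i, baseline, sampling_khz, filter_khz) {
  if (i == 0) stop("unitary amplitude i must be non-zero")
  lev <- as.integer(round((segment - baseline) / i))
  lev[lev < 0L] <- 0L
  dead_ms <- 2 * 0.3321 / filter_khz
  min_samp <- max(1L, ceiling(dead_ms * sampling_khz))
  r <- rle(lev)
  # merge unresolvably short dwells into the longer neighbour
  repeat {
    short <- which(r$lengths < min_samp)
    if (!length(short) || length(r$lengths) == 1L) break
    j <- short[which.min(r$lengths[short])]
    into <- if (j == 1L) 2L
            else if (j == length(r$lengths)) j - 1L
            else if (r$lengths[j - 1L] >= r$lengths[j + 1L]) j - 1L else j + 1L
    r$values[j] <- r$values[into]
    merged <- rle(inverse.rle(r))
    r <- merged
  }
  lev2 <- inverse.rle(r)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  dwells <- data.frame(level = r$values,
                       start_ms = starts / sampling_khz,
                       duration_ms = r$lengths / sampling_khz)
  N <- max(lev2)
  list(levels = lev2, dwells = dwells, N = N,
       open_fraction = if (N > 0) mean(lev2) / N else 0)
}

#' Fit the unitary current-voltage relationship
#'
#' Ordinary least squares line \eqn{i = g (V - V_{rev})}. The slope in
#' pA/mV equals nS and is reported as a conductance in pS; the reversal
#' potential is minus the intercept over the slope.
#'
#' @param points Data frame with columns \code{V} (mV) and \code{i} (pA),
#'   at two or more distinct voltages.
#' @return Object of class \code{iv_fit}: list with \code{g_ps},
#'   \code{v_rev_mv}, \code{points}, \code{fit} (the underlying \code{lm}).
#' @examples
#' fit_iv(data.frame(V = c(-100, -50), i = c(-34, -17)))
#' @export
fit_iv <- function(points) {
  stopifnot(all(c("V", "i") %in% names(points)))
  if (length(unique(points$V)) < 2L) stop("need at least 2 distinct voltages")
  fit <- stats::lm(i ~ V, data = points)
  slope <- unname(stats::coef(fit)["V"])        # pA/mV = nS
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  structure(list(g_ps = slope * 1000,
                 v_rev_mv = -intercept / slope,
                 points = points, fit = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("Unitary I-V fit: slope conductance %.1f pS, reversal %.2f mV (n = %d points)\n",
              x$g_ps, x$v_rev_mv, nrow(x$points)))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) {
  c(g_ps = object$g_ps, v_rev_mv = object$v_rev_mv)
}

#' @export
residuals.iv_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.iv_fit <- function(x, ...) {
  plot(x$points$V, x$points$i, xlab = "Voltage (mV)",
       ylab = "Unitary current (pA)", pch = 19, ...)
  graphics::abline(x$fit, col = "grey40")
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Channel open probability from integral current
#'
#' \eqn{P_o = I / (N i)}; values outside [0, 1] are clamped with the raw
#' value retained.
#'
#' @param I Integral (mean) current, pA.
#' @param N Number of channels (>= 1).
#' @param i Unitary amplitude, pA (non-zero).
#' @return List with \code{p_o}, \code{p_o_raw}, \code{I}, \code{N},
#'   \code{i}.
#' @export
open_probability <- function(I, N, i) {
  if (N < 1) stop("N must be >= 1")
  if (i == 0) stop("unitary amplitude i must be non-zero")
  raw <- I / (N * i)
  list(p_o = min(max(raw, 0), 1), p_o_raw = raw, I = I, N = N, i = i)
}

#' Unitary amplitude and I-V analysis of a sweep set
#'
#' Groups sweeps by command voltage, concatenates the traces per voltage,
#' estimates the unitary amplitude at each voltage, and fits the I-V line
#' through the voltages with resolvable activity.
#'
#' @param sweeps A sweep set as produced by
#'   \code{\link{simulate_patch_traces}} or \code{\link{read_sweep_set}}.
#' @param max_components Passed to \code{\link{estimate_unitary_amplitude}}.
#' @return List with \code{amplitudes} (data frame \code{V}, \code{i},
#'   \code{n_levels}, \code{active}) and \code{iv} (an \code{iv_fit}, or
#'   \code{NULL} when fewer than two active voltages).
#' @export
analyze_sweeps <- function(sweeps, max_components = 4) {
  volts <- vapply(sweeps$sweeps, function(s) s$voltage_mv, numeric(1))
  rows <- list()
  for (v in sort(unique(volts))) {
    seg <- unlist(lapply(sweeps$sweeps[volts == v],
                         function(s) s$current_pa), use.names = FALSE)
    est <- estimate_unitary_amplitude(seg, v, sweeps$sampling_khz,
                                      max_components = max_components)
    rows[[length(rows) + 1L]] <- data.frame(
      V = v, i = est$i, n_levels = est$n_levels, active = est$active)
  }
  amp <- do.call(rbind, rows)
  act <- amp[amp$active, , drop = FALSE]
  iv <- if (nrow(act) >= 2L && length(unique(act$V)) >= 2L) {
    fit_iv(data.frame(V = act$V, i = act$i))
  } else NULL
  list(amplitudes = amp, iv = iv)
}
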