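# Time integration of the fluctuation system and regime diagnostics.
#
# Integration uses deSolve's adaptive stiff-capable lsoda with tight
# tolerances (rtol 1e-9, atol 1e-12, up to 50000 internal steps).  A
# root function terminates integration once a fluctuation exceeds ten
# times the total monomer concentration: beyond that the perturbation
# variables have lost physical meaning and the trajectory is flagged
# divergent.

#' Integrate the fluctuation system
#'
#' Solves the `(x, z)` fluctuation equations from a small initial
#' perturbation and reconstructs the physical concentrations
#' `X = Xe + x`, `Y = Ye - x - z`, `Z = Ze + z`; the reconstruction
#' conserves `X + Y + Z = M` identically.  Defaults mirror the published
#' simulation: `x0 = z0 = 1e-6`, `t` from 0 to 3300.
#'
#' @inheritParams fluct_rhs
#' @param x0,z0 initial fluctuations
#' @param t_max integration end time
#' @param dt reporting grid spacing (the integrator steps adaptively and
#'   interpolates onto this grid)
#' @param rtol,atol relative and absolute integration tolerances
#' @param ceiling multiple of `M` beyond which a fluctuation terminates
#'   the run with a divergence flag
#' @param maxsteps maximum internal integrator steps per output interval
#' @return an object of class `cmt_trajectory`: a data.frame with columns
#'   `t, x, z, y, X, Y, Z` and attributes `params`, `variant`, `steady`,
#'   `diverged`, `end_time`, `settings`
#' @export
#' @examples
#' tr <- integrate_fluctuations(preset_params("fig2_code", p = 0.008),
#'                              t_max = 500)
#' head(tr)
integrate_fluctuations <- function(params,
                                   variant = c("fig2_code", "paper_eq"),
                                   x0 = 1e-6, z0 = 1e-6, t_max = 3300,
                                   dt = 1, rtol = 1e-9, atol = 1e-12,
                                   ceiling = 10, maxsteps = 50000L) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "cmt_params"), t_max > 0, dt > 0,
            rtol > 0, atol > 0)
  steady <- steady_state(params)
  lim <- ceiling * params$M
  deriv <- function(t, y, parms) list(fluct_rhs(y, params, steady, variant))
  # root 1: divergence ceiling; root 2: the field has decayed to numerical
  # silence (stops the run before the decaying coordinate underflows)
  root <- function(t, y, parms) {
    f <- fluct_rhs(y, params, steady, variant)
    c(max(abs(y)) - lim, max(abs(f), abs(y[1])) - 1e-140)
  }
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::lsodar(y = c(x = x0, z = z0), times = times,
                         func = deriv, parms = NULL, rtol = rtol,
                         atol = atol, maxsteps = maxsteps,
                         rootfunc = root)
  iroot <- attr(sol, "iroot")
  sol <- as.data.frame(sol)
  names(sol)[1] <- "t"
  sol <- sol[stats::complete.cases(sol), , drop = FALSE]
  ended_early <- nrow(sol) > 0 && sol$t[nrow(sol)] < t_max - dt / 2
  converged <- ended_early && length(iroot) >= 2 && iroot[2] == 1
  diverged <- ended_early && !converged
  out <- data.frame(t = sol$t, x = sol$x, z = sol$z,
                    y = -sol$x - sol$z,
                    X = steady[["Xe"]] + sol$x,
                    Y = steady[["Ye"]] - sol$x - sol$z,
                    Z = steady[["Ze"]] + sol$z)
  structure(out, class = c("cmt_trajectory", "data.frame"),
            params = params, variant = variant, steady = steady,
            diverged = diverged, converged = converged,
            end_time = sol$t[nrow(sol)],
            settings = list(x0 = x0, z0 = z0, t_max = t_max, dt = dt,
                            rtol = rtol, atol = atol, ceiling = ceiling,
                            maxsteps = maxsteps))
}

#' @export
print.cmt_trajectory <- function(x, ...) {
  cat(sprintf("Fluctuation trajectory (%s variant), %d points on [0, %g]%s\n",
              attr(x, "variant"), nrow(x), attr(x, "end_time"),
              if (attr(x, "diverged")) " -- DIVERGED (terminated early)"
              else ""))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Plot a fluctuation trajectory
#'
#' Line plot of the reconstructed concentrations X, Y, Z over the
#' reporting window, in the style of the published figure (X black,
#' Y red, Z blue).
#'
#' @param x a `cmt_trajectory`
#' @param window time window to display, default `c(0, 1000)`
#' @param ... further arguments passed to [graphics::matplot()]
#' @export
plot.cmt_trajectory <- function(x, window = c(0, 1000), ...) {
  d <- as.data.frame(x)
  d <- d[d$t >= window[1] & d$t <= window[2], ]
  graphics::matplot(d$t, d[, c("X", "Y", "Z")], type = "l", lty = 1,
                    col = c("black", "red", "blue"),
                    xlab = "time", ylab = "concentration", ...)
  graphics::legend("topright", legend = c("X", "Y", "Z"), lty = 1,
                   col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}

#' Classify a trajectory as attenuated, sustained or divergent
#'
#' The envelope ratio compares the largest |x| over the last third of
#' the integrated window with the largest |x| over the first third.  A
#' trajectory is `divergent` when its divergence flag is set (the
#' integration hit the fluctuation ceiling) or the ratio exceeds
#' `divergent_min`; `attenuated` when the ratio is below
#' `attenuated_max`; otherwise `sustained`.  Monotonically decaying
#' trajectories (no oscillation) are classified by the same ratio.
#'
#' @param traj a `cmt_trajectory`
#' @param attenuated_max envelope-ratio threshold below which the
#'   fluctuation counts as attenuated
#' @param divergent_min envelope-ratio threshold above which it counts
#'   as divergent
#' @return an object of class `cmt_regime` with fields `label`,
#'   `envelope_ratio`, `n_peaks`, `peak_times`, `divergence_time`
#' @export
diagnose_regime <- function(traj, attenuated_max = 0.5, divergent_min = 2) {
  stopifnot(inherits(traj, "cmt_trajectory"))
  if (nrow(traj) < 10L)
    stop("insufficient data: trajectory has fewer than 10 points",
         call. = FALSE)
  x <- traj$x; t <- traj$t
  n <- length(x)
  third <- floor(n / 3)
  r <- max(abs(x[(n - third + 1):n])) / max(abs(x[1:third]))
  dx <- diff(x)
  peaks <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  diverged <- isTRUE(attr(traj, "diverged"))
  label <- if (diverged || r > divergent_min) "divergent"
  else if (r < attenuated_max) "attenuated"
  else "sustained"
  structure(list(label = label, envelope_ratio = r,
                 n_peaks = length(peaks), peak_times = t[peaks],
                 divergence_time = if (diverged) attr(traj, "end_time")
                 else NA_real_),
            class = "cmt_regime")
}

#' @export
print.cmt_regime <- function(x, ...) {
  cat(sprintf("Regime: %s (envelope ratio %.4g, %d peaks%s)\n",
              x$label, x$envelope_ratio, x$n_peaks,
              if (!is.na(x$divergence_time))
                sprintf(", diverged at t = %g", x$divergence_time) else ""))
  invisible(x)
}

.fig2_p_values <- c(0, 0.001, 0.002, 0.004, 0.008, 0.009, 0.01,
                    0.010705, 0.011)

#' Reproduce the nine-panel regime sweep
#'
#' Integrates the fluctuation system at the nine published cofactor
#' concentrations (0 to 0.011) and tabulates the regime diagnosis next
#' to the eigenvalue classification for each.
#'
#' @param preset parameter preset name, see [preset_params()]
#' @param p_values cofactor concentrations to sweep (defaults to the nine
#'   published values)
#' @param out_dir optional directory; when given, per-p trajectory CSVs
#'   and a summary CSV are written there
#' @param plot when `TRUE` a PNG per panel is written to `out_dir`
#' @inheritParams integrate_fluctuations
#' @return invisibly, a list with `trajectories` (list of
#'   `cmt_trajectory`), `summary` (data.frame with `p, regime,
#'   envelope_ratio, n_peaks, max_re_eigenvalue, stability_regime`)
#' @export
reproduce_fig2 <- function(preset = "fig2_code", p_values = .fig2_p_values,
                           out_dir = NULL, plot = FALSE,
                           variant = "fig2_code", t_max = 3300) {
  params <- preset_params(preset)
  trajs <- list()
  rows <- list()
  for (p in p_values) {
    pp <- set_p(params, p)
    tr <- integrate_fluctuations(pp, variant = variant, t_max = t_max)
    dg <- diagnose_regime(tr)
    st <- classify(pp, variant = variant)
    key <- format(p, digits = 12)
    trajs[[key]] <- tr
    rows[[key]] <- data.frame(p = p, regime = dg$label,
                              envelope_ratio = dg$envelope_ratio,
                              n_peaks = dg$n_peaks,
                              max_re_eigenvalue = max(Re(st$eigenvalues)),
                              stability_regime = st$regime)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trajectory_csv(tr, file.path(out_dir,
                                         sprintf("trajectory_p%s.csv", key)))
      if (plot) {
        grDevices::png(file.path(out_dir, sprintf("panel_p%s.png", key)),
                       width = 700, height = 500)
        plot(tr, main = sprintf("p = %s", key))
        grDevices::dev.off()
      }
    }
  }
  summ <- do.call(rbind, rows)
  rownames(summ) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summ, file.path(out_dir, "regime_summary.csv"),
                     row.names = FALSE)
  invisible(list(trajectories = trajs, summary = summ))
}

#' Write a trajectory as CSV
#'
#' Columns `t, x, z, y, X, Y, Z`; a comment header records the parameter
#' values and variant so the file is self-describing.
#'
#' @param traj a `cmt_trajectory`
#' @param path output file
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cmt_trajectory"))
  params <- attr(traj, "params")
  hdr <- sprintf("# variant=%s %s", attr(traj, "variant"),
                 paste(names(unclass(params)),
                       vapply(unclass(params), format, "", digits = 12),
                       sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(as.data.frame(traj), digits = 12), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
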