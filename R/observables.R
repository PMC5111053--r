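# Trajectory observables: centre-of-mass MSD, end-to-end autocorrelation,
# diffusion and relaxation estimators, scaling fits.

# default log-spaced integer lag grid (in frames)
.default_lags <- function(n_frames, n_lags = 60, max_frac = 0.5) {
  max_lag <- max(1L, as.integer(floor((n_frames - 1) * max_frac)))
  unique(as.integer(round(exp(seq(0, log(max_lag), length.out = n_lags)))))
}

.traj_of <- function(x) {
  if (inherits(x, "polylat_run")) x else as.list(x)
}

#' Mean-square displacement of the centre of mass
#'
#' For each lag tau, averages |r_cm(t + tau) - r_cm(t)|^2 over all available
#' time origins of one trajectory, using unwrapped centre-of-mass positions.
#' The \code{"xy"} component uses only the coordinates parallel to the
#' surface, matching the parallel diffusion coefficient \code{D_xy}.
#'
#' @param run a \code{\link{run_polymer}} result (or a list with
#'   \code{times} and \code{com}).
#' @param component \code{"xy"} (parallel) or \code{"xyz"} (full).
#' @param lags integer frame lags; default: ~60 log-spaced lags up to half
#'   the trajectory.
#' @return A data.frame of class \code{polylat_msd} with columns
#'   \code{lag_frames}, \code{lag_mcs}, \code{msd}, \code{n_origin}.
#' @export
msd_com <- function(run, component = c("xy", "xyz"), lags = NULL) {
  component <- match.arg(component)
  tr <- .traj_of(run)
  com <- tr$com
  nf <- nrow(com)
  if (is.null(lags)) lags <- .default_lags(nf)
  lags <- as.integer(lags)
  if (any(lags < 1) || any(lags >= nf))
    stop("lags must be in [1, n_frames - 1]")
  dt <- if (nf > 1) tr$times[2] - tr$times[1] else 1
  cols <- if (component == "xy") 1:2 else 1:3
  msd <- numeric(length(lags))
  n_origin <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    d <- com[(1 + lag):nf, cols, drop = FALSE] -
         com[1:(nf - lag), cols, drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    n_origin[k] <- nf - lag
  }
  structure(data.frame(lag_frames = lags, lag_mcs = lags * dt,
                       msd = msd, n_origin = n_origin),
            component = component, class = c("polylat_msd", "data.frame"))
}

#' End-to-end vector rotational autocorrelation function
#'
#' rho(tau) = <R(t + tau) . R(t)> / <R . R>, averaged over all time origins
#' of the trajectory; the normalisation uses the time-averaged <R . R> over
#' the whole production trajectory, so rho(0) = 1 by construction.
#'
#' @param run a \code{\link{run_polymer}} result (or a list with
#'   \code{times} and \code{end_to_end}).
#' @param lags integer frame lags (0 is added automatically).
#' @return A data.frame of class \code{polylat_acf} with columns
#'   \code{lag_frames}, \code{lag_mcs}, \code{rho}, \code{n_origin}.
#' @export
end_to_end_acf <- function(run, lags = NULL) {
  tr <- .traj_of(run)
  ree <- tr$end_to_end
  nf <- nrow(ree)
  norm <- mean(rowSums(ree^2))
  if (norm <= 0) stop("degenerate end-to-end ensemble: <R.R> = 0")
  if (is.null(lags)) lags <- .default_lags(nf)
  lags <- sort(unique(c(0L, as.integer(lags))))
  if (any(lags < 0) || any(lags >= nf))
    stop("lags must be in [0, n_frames - 1]")
  dt <- if (nf > 1) tr$times[2] - tr$times[1] else 1
  rho <- numeric(length(lags))
  n_origin <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    dots <- rowSums(ree[(1 + lag):nf, , drop = FALSE] *
                    ree[1:(nf - lag), , drop = FALSE])
    rho[k] <- mean(dots) / norm
    n_origin[k] <- nf - lag
  }
  structure(data.frame(lag_frames = lags, lag_mcs = lags * dt,
                       rho = rho, n_origin = n_origin),
            class = c("polylat_acf", "data.frame"))
}

# average a list of curves sharing one lag grid; value column `col`
.average_curves <- function(curves, col) {
  stopifnot(length(curves) >= 1)
  lag <- curves[[1]]$lag_mcs
  vals <- vapply(curves, function(cv) cv[[col]], numeric(length(lag)))
  out <- curves[[1]]
  out[[col]] <- if (is.matrix(vals)) rowMeans(vals) else mean(vals)
  out
}

#' Estimate the parallel diffusion coefficient D_xy
#'
#' Fits a straight line to the MSD over the fit window (by default the last
#' decade of available lags, where the MSD is diffusive) and returns
#' \code{D_xy = slope / 4}, the long-time limit of \code{<dr^2>_xy / (4 t)}.
#'
#' @param msd a \code{\link{msd_com}} curve (possibly replica-averaged).
#' @param window numeric \code{c(lo, hi)} in MCS; default
#'   \code{c(max/10, max)}.
#' @param min_r_squared linearity threshold; a lower fit quality signals a
#'   warning and marks the estimate as not OK.
#' @return A list of class \code{polylat_diffusion}: \code{d_xy},
#'   \code{slope_se}, \code{window}, \code{r_squared}, \code{n_points},
#'   \code{ok}.
#' @export
estimate_dxy <- function(msd, window = NULL, min_r_squared = 0.9) {
  stopifnot(is.data.frame(msd), all(c("lag_mcs", "msd") %in% names(msd)))
  if (is.null(window)) {
    hi <- max(msd$lag_mcs)
    window <- c(hi / 10, hi)
  }
  sel <- msd$lag_mcs >= window[1] & msd$lag_mcs <= window[2]
  pts <- msd[sel, , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 MSD points in the fit window")
  if (all(pts$msd == 0)) {
    return(structure(list(d_xy = 0, slope_se = 0, window = window,
                          r_squared = 1, n_points = nrow(pts), ok = TRUE),
                     class = "polylat_diffusion"))
  }
  fit <- lm(msd ~ lag_mcs, data = pts)
  slope <- coef(fit)[["lag_mcs"]]
  r2 <- suppressWarnings(summary(fit))$r.squared
  ok <- is.finite(r2) && r2 >= min_r_squared
  if (!ok) warning(sprintf("MSD fit linearity R^2 = %.3f below %.2f",
                           r2, min_r_squared))
  structure(list(d_xy = max(slope, 0) / 4,
                 slope_se = suppressWarnings(summary(fit))$coefficients["lag_mcs", "Std. Error"] / 4,
                 window = window, r_squared = r2, n_points = nrow(pts),
                 ok = ok),
            class = "polylat_diffusion")
}

#' @export
print.polylat_diffusion <- function(x, ...) {
  cat(sprintf("D_xy = %.6g (se %.2g) from %d points in [%g, %g] MCS, R^2 = %.4f\n",
              x$d_xy, x$slope_se, x$n_points, x$window[1], x$window[2],
              x$r_squared))
  invisible(x)
}

#' Estimate the rotational relaxation time tau_R
#'
#' The end-to-end autocorrelation decays exponentially over an intermediate
#' window; tau_R is estimated by a linear fit of \code{ln rho} versus lag
#' restricted to lags with \code{0.06 < rho < 0.30}, where a clean
#' exponential regime is reliably found, as \code{tau_R = -1/slope}.  By
#' default the fit is weighted by \code{rho^2}, the variance-stabilising
#' weight for a log-transformed curve whose absolute noise level is roughly
#' lag-independent; this keeps the noisiest points just above the lower
#' window edge from tilting the fit at small ensemble sizes.  An exact
#' exponential gives the same answer with either weighting.
#'
#' @param acf an \code{\link{end_to_end_acf}} curve (possibly
#'   replica-averaged).
#' @param window numeric \code{c(lo, hi)} bounds on rho.
#' @param min_points minimum number of curve points required inside the
#'   window (error otherwise).
#' @param weighting \code{"rho_sq"} (default) or \code{"none"}.
#' @return A list of class \code{polylat_relaxation}: \code{tau_r},
#'   \code{window_used} (lag range actually fitted), \code{r_squared},
#'   \code{n_points}.
#' @export
estimate_tau_r <- function(acf, window = c(0.06, 0.30), min_points = 3,
                           weighting = c("rho_sq", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(acf), all(c("lag_mcs", "rho") %in% names(acf)))
  sel <- acf$rho > window[1] & acf$rho < window[2] & acf$lag_frames > 0
  pts <- acf[sel, , drop = FALSE]
  if (nrow(pts) < min_points)
    stop(sprintf("only %d ACF points fall in the fit window (%g, %g)",
                 nrow(pts), window[1], window[2]))
  w <- if (weighting == "rho_sq") pts$rho^2 else rep(1, nrow(pts))
  fit <- lm(log(rho) ~ lag_mcs, data = pts, weights = w)
  slope <- coef(fit)[["lag_mcs"]]
  if (slope >= -sqrt(.Machine$double.eps))
    stop("ACF does not decay over the fit window")
  structure(list(tau_r = -1 / slope,
                 window_used = range(pts$lag_mcs),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n_points = nrow(pts)),
            class = "polylat_relaxation")
}

#' @export
print.polylat_relaxation <- function(x, ...) {
  cat(sprintf("tau_R = %.6g MCS from %d points in [%g, %g] MCS, R^2 = %.4f\n",
              x$tau_r, x$n_points, x$window_used[1], x$window_used[2],
              x$r_squared))
  invisible(x)
}

#' Fit a chain-length scaling exponent
#'
#' Ordinary least squares of \code{log(y)} on \code{log(n)}.  With
#' \code{decreasing = TRUE} the exponent is reported with positive sign for
#' a decreasing power law (convention for \code{D_xy ~ N^-alpha}); otherwise
#' the raw log-log slope is returned (convention for \code{tau_R ~ N^beta}).
#'
#' @param n_values chain lengths (>= 3 values).
#' @param y_values positive observable values, one per chain length.
#' @param decreasing report the negated slope (alpha convention).
#' @return A list of class \code{polylat_scaling}: \code{exponent},
#'   \code{prefactor}, \code{se}, \code{n_values}, \code{r_squared}.
#' @examples
#' fit_scaling_exponent(c(8, 16, 32, 64), 2 * c(8, 16, 32, 64)^-1.5,
#'                      decreasing = TRUE)$exponent  # 1.5
#' @export
fit_scaling_exponent <- function(n_values, y_values, decreasing = FALSE) {
  keep <- is.finite(n_values) & is.finite(y_values)
  n_values <- n_values[keep]; y_values <- y_values[keep]
  if (length(n_values) < 3) stop("need at least 3 chain lengths")
  if (any(y_values <= 0) || any(n_values <= 0))
    stop("scaling fit requires positive n and y")
  fit <- lm(log(y_values) ~ log(n_values))
  slope <- coef(fit)[[2]]
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[2, "Std. Error"]
  structure(list(exponent = if (decreasing) -slope else slope,
                 prefactor = exp(coef(fit)[[1]]),
                 se = se, n_values = n_values,
                 r_squared = sm$r.squared),
            class = "polylat_scaling")
}

#' @export
print.polylat_scaling <- function(x, ...) {
  cat(sprintf("scaling exponent = %.4f (se %.3f) over N = {%s}, R^2 = %.4f\n",
              x$exponent, x$se, paste(x$n_values, collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' Locate the coil-globule transition on the E_PP axis
#'
#' Given mean-square radii of gyration measured over a grid of intra-polymer
#' attraction strengths, returns the grid point where <R_G^2> drops most
#' steeply (most negative central finite difference).  The grid spacing is
#' reported as the resolution of the estimate.
#'
#' @param e_pp_values increasing grid of attraction strengths (kT).
#' @param mean_rg_sq mean-square radius of gyration at each grid point.
#' @return A list of class \code{polylat_transition}: \code{e_pp_transition},
#'   \code{resolution}, \code{slope}, and the table of central slopes.
#' @export
locate_coil_globule <- function(e_pp_values, mean_rg_sq) {
  stopifnot(length(e_pp_values) == length(mean_rg_sq))
  ord <- order(e_pp_values)
  e <- e_pp_values[ord]; r <- mean_rg_sq[ord]
  k <- length(e)
  if (k < 5) stop("need at least 5 grid points to locate an interior extremum")
  idx <- 2:(k - 1)
  slopes <- (r[idx + 1] - r[idx - 1]) / (e[idx + 1] - e[idx - 1])
  i_min <- which.min(slopes)
  if (slopes[i_min] >= 0)
    stop("<R_G^2> does not decrease anywhere on the grid")
  # the steepest-descent point must be a strict interior slope extremum
  # (strict up to float rounding, so an exactly linear curve counts as flat)
  eps <- 1e-8 * max(abs(slopes))
  if (i_min == 1 || i_min == length(slopes) ||
      !(slopes[i_min] < slopes[i_min - 1] - eps &&
        slopes[i_min] < slopes[i_min + 1] - eps))
    stop("no interior slope extremum: curve too close to linear on this grid")
  structure(list(e_pp_transition = e[idx[i_min]],
                 resolution = stats::median(diff(e)),
                 slope = slopes[i_min],
                 slopes = data.frame(e_pp = e[idx], slope = slopes)),
            class = "polylat_transition")
}

#' @export
print.polylat_transition <- function(x, ...) {
  cat(sprintf("coil-globule transition at E_PP = %g +/- %g (steepest descent %.3g)\n",
              x$e_pp_transition, x$resolution, x$slope))
  invisible(x)
}
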