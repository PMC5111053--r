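# Replica management, parameter sweeps and result files.

# deterministic, human-readable key identifying a sweep point
.point_key <- function(n, mode, e_pp, e_ps) {
  sprintf("%s_n%03d_epp%s_eps%s", mode, n,
          gsub("\\.", "p", format(e_pp)), gsub("\\.", "p", format(e_ps)))
}

#' Simulate one parameter point over independent replicas
#'
#' Runs \code{replicas} independent chains (distinct recorded RNG streams),
#' computes per-replica MSD and end-to-end ACF curves on a common lag grid,
#' averages the curves, and estimates \code{D_xy} and \code{tau_R} from the
#' averaged curves.  Uncertainties come from a bootstrap over replicas.
#'
#' Replica \code{i} uses stream seed \code{seed + i}; a sweep spaces its
#' per-point base seeds far enough apart that streams never collide.
#'
#' @inheritParams run_polymer
#' @param replicas number of independent replicas.
#' @param boot number of bootstrap resamples over replicas (0 disables).
#' @param msd_component \code{"xy"} (default, the parallel component) or
#'   \code{"xyz"}.
#' @param out_dir if non-NULL, write a JSON summary and CSV curve files
#'   there; if the summary for this point already exists the run is skipped
#'   and the stored summary is returned (resumable sweeps).
#' @return An object of class \code{polylat_point}: parameter set, replica
#'   seeds, \code{d_xy} and \code{tau_r} with bootstrap standard errors,
#'   \code{mean_rg_sq}, \code{mean_n_ps}, acceptance rate, desorbed
#'   fraction, and the averaged curves.
#' @export
run_point <- function(n, mode = c("bulk3d", "slab", "plane2d"),
                      e_pp = 0, e_ps = 0, replicas = 8, seed = 1,
                      protocol = NULL, box = NULL, boot = 100,
                      msd_component = "xy", out_dir = NULL) {
  mode <- match.arg(mode)
  key <- .point_key(n, mode, e_pp, e_ps)
  if (!is.null(out_dir)) {
    jf <- file.path(out_dir, paste0(key, ".json"))
    if (file.exists(jf)) return(.point_from_json(jf))
  }
  if (is.null(protocol)) protocol <- run_protocol(n, mode, e_ps = e_ps)
  if (is.null(box)) box <- box_spec(mode, n = n)
  t_start <- Sys.time()
  seeds <- seed + seq_len(replicas)
  msd_list <- vector("list", replicas)
  acf_list <- vector("list", replicas)
  rg_mean <- nps_mean <- acc <- des <- numeric(replicas)
  failed <- logical(replicas)
  for (i in seq_len(replicas)) {
    res <- tryCatch(
      run_polymer(n, mode, e_pp = e_pp, e_ps = e_ps, box = box,
                  protocol = protocol, seed = seeds[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      next
    }
    msd_list[[i]] <- msd_com(res, component = msd_component)
    if (n >= 2) acf_list[[i]] <- end_to_end_acf(res)
    rg_mean[i] <- mean(res$rg_sq)
    nps_mean[i] <- mean(res$n_ps)
    acc[i] <- res$acceptance_rate
    des[i] <- res$desorbed_fraction
  }
  if (sum(failed) * 2 > replicas)
    stop(sprintf("point %s: %d of %d replicas failed", key, sum(failed),
                 replicas))
  ok <- which(!failed)
  msd_list <- msd_list[ok]; acf_list <- acf_list[ok]

  est <- .estimate_point(msd_list, acf_list)
  bse <- c(d_xy = NA_real_, tau_r = NA_real_)
  if (boot > 0 && length(ok) > 1) {
    bs <- replicate(boot, {
      pick <- sample(length(ok), replace = TRUE)
      e <- .estimate_point(msd_list[pick], acf_list[pick], quiet = TRUE)
      c(e$d_xy, e$tau_r)
    })
    bse <- c(d_xy = sd(bs[1, ], na.rm = TRUE), tau_r = sd(bs[2, ], na.rm = TRUE))
  }
  out <- structure(list(
    key = key, n = n, mode = mode, e_pp = e_pp, e_ps = e_ps,
    replicas = length(ok), failed_replicas = sum(failed),
    replica_seeds = seeds,
    d_xy = est$d_xy, d_xy_se = bse[["d_xy"]],
    tau_r = est$tau_r, tau_r_se = bse[["tau_r"]],
    tau_note = est$tau_note,
    mean_rg_sq = mean(rg_mean[ok]),
    mean_rg_sq_se = sd(rg_mean[ok]) / sqrt(length(ok)),
    mean_n_ps = mean(nps_mean[ok]),
    acceptance_rate = mean(acc[ok]),
    desorbed_fraction = mean(des[ok]),
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"),
    msd = est$msd, acf = est$acf,
    protocol = protocol), class = "polylat_point")
  if (!is.null(out_dir)) .write_point(out, out_dir)
  out
}

# Plateau-corrected window fit of the averaged ACF.  At finite ensemble
# size the averaged curve carries a lag-correlated offset from each
# replica's finite-trajectory mean end-to-end vector (|mean R|^2 > 0), which
# can masquerade as a slow tail.  The offset is estimated from the far tail
# of the lag range (last quarter, where the true correlation has decayed)
# and subtracted; the correction is only accepted if it is self-consistent,
# i.e. the tail region lies beyond four corrected relaxation times,
# otherwise the uncorrected fit stands.
.fit_tau_corrected <- function(acf_avg) {
  fit_raw <- tryCatch(estimate_tau_r(acf_avg), error = function(e) e)
  tail_lo <- 0.75 * max(acf_avg$lag_mcs)
  offset <- mean(acf_avg$rho[acf_avg$lag_mcs >= tail_lo])
  corrected <- acf_avg
  corrected$rho <- corrected$rho - offset
  fit_c <- tryCatch(estimate_tau_r(corrected), error = function(e) e)
  if (!inherits(fit_c, "error") && 4 * fit_c$tau_r < tail_lo) {
    fit_c$plateau <- offset
    return(fit_c)
  }
  fit_raw
}

# estimates from averaged curves; tau_R failure is tolerated (recorded as NA)
.estimate_point <- function(msd_list, acf_list, quiet = FALSE) {
  msd_avg <- .average_curves(msd_list, "msd")
  dfit <- suppressWarnings(estimate_dxy(msd_avg))
  tau <- NA_real_; note <- NA_character_; acf_avg <- NULL
  acf_list <- acf_list[!vapply(acf_list, is.null, logical(1))]
  if (length(acf_list) > 0) {
    acf_avg <- .average_curves(acf_list, "rho")
    tfit <- .fit_tau_corrected(acf_avg)
    if (inherits(tfit, "error")) {
      note <- conditionMessage(tfit)
      if (!quiet) warning(sprintf("tau_R estimate failed: %s", note))
    } else tau <- tfit$tau_r
  } else note <- "no end-to-end vector for a single monomer"
  list(d_xy = dfit$d_xy, tau_r = tau, tau_note = note,
       msd = msd_avg, acf = acf_avg)
}

#' @export
print.polylat_point <- function(x, ...) {
  cat(sprintf("polylat_point %s (%d replicas)\n", x$key, x$replicas))
  cat(sprintf("  D_xy = %.4g +/- %.2g, tau_R = %.4g +/- %.2g MCS\n",
              x$d_xy, x$d_xy_se, x$tau_r, x$tau_r_se))
  cat(sprintf("  <R_G^2> = %.4g, <n_PS> = %.3g, acceptance %.3f, desorbed %.4f\n",
              x$mean_rg_sq, x$mean_n_ps, x$acceptance_rate,
              x$desorbed_fraction))
  invisible(x)
}

.write_point <- function(pt, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- pt[setdiff(names(pt), c("msd", "acf", "protocol"))]
  summ$protocol <- unclass(pt$protocol)
  jsonlite::write_json(summ, file.path(out_dir, paste0(pt$key, ".json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(pt$msd, file.path(out_dir, paste0(pt$key, "_msd.csv")),
            row.names = FALSE)
  write.csv(pt$acf, file.path(out_dir, paste0(pt$key, "_acf.csv")),
            row.names = FALSE)
  invisible(pt)
}

.point_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  key <- x$key
  for (part in c("msd", "acf")) {
    f <- file.path(base, paste0(key, "_", part, ".csv"))
    if (file.exists(f)) x[[part]] <- utils::read.csv(f)
  }
  x$d_xy_se <- if (is.null(x$d_xy_se)) NA_real_ else x$d_xy_se
  x$tau_r <- if (is.null(x$tau_r)) NA_real_ else x$tau_r
  class(x) <- "polylat_point"
  x
}

#' Sweep configuration
#'
#' Describes a grid of chain lengths and attraction strengths to simulate in
#' one boundary mode, with per-point replica counts and run-protocol
#' overrides.  \code{e_ps_values} is ignored (forced to 0) outside slab
#' mode, where the surface term does not act.
#'
#' @param n_values chain lengths.
#' @param mode boundary mode.
#' @param e_pp_values,e_ps_values attraction strengths (kT).
#' @param replicas replicas per grid point: a scalar, or a function of n
#'   (long chains carry more time origins per trajectory, so fewer replicas
#'   are needed for comparable statistics).
#' @param seed base seed; points use widely spaced derived seeds.
#' @param out_dir optional output directory (enables resumable sweeps and
#'   CSV/JSON result files).
#' @param production_mcs,sample_interval,equilibration_mcs optional protocol
#'   overrides applied at every point (scalars, or functions of n).
#' @param boot bootstrap resamples per point.
#' @return A list of class \code{sweep_config}.
#' @export
sweep_config <- function(n_values, mode = c("bulk3d", "slab", "plane2d"),
                         e_pp_values = 0, e_ps_values = 0, replicas = 8,
                         seed = 1, out_dir = NULL, production_mcs = NULL,
                         sample_interval = NULL, equilibration_mcs = NULL,
                         boot = 100) {
  mode <- match.arg(mode)
  if (mode != "slab") e_ps_values <- 0
  structure(list(n_values = as.integer(n_values), mode = mode,
                 e_pp_values = e_pp_values, e_ps_values = e_ps_values,
                 replicas = replicas, seed = seed, out_dir = out_dir,
                 production_mcs = production_mcs,
                 sample_interval = sample_interval,
                 equilibration_mcs = equilibration_mcs, boot = boot),
            class = "sweep_config")
}

.protocol_for <- function(config, n, e_ps = 0) {
  ov <- function(v) {
    if (is.null(v)) NULL else if (is.function(v)) v(n) else v
  }
  run_protocol(n, config$mode, e_ps = e_ps,
               equilibration_mcs = ov(config$equilibration_mcs),
               production_mcs = ov(config$production_mcs),
               sample_interval = ov(config$sample_interval))
}

#' Run a parameter sweep and fit scaling exponents
#'
#' Simulates every (n, e_pp, e_ps) grid point of the configuration, then for
#' each (e_pp, e_ps) pair fits the chain-length scaling exponents
#' \code{alpha} (from \code{D_xy ~ N^-alpha}) and \code{beta} (from
#' \code{tau_R ~ N^beta}) by log-log least squares.  Points whose tau_R
#' estimate failed are dropped from the beta fit and recorded in the
#' manifest.  Identical configuration and seed give identical outputs.
#'
#' @param config a \code{\link{sweep_config}}.
#' @param n_min_fit only chain lengths >= this enter the exponent fits
#'   (default: all supplied lengths; analyses with many lengths may restrict
#'   to the long-chain regime, e.g. N >= 32).
#' @return A list of class \code{polylat_sweep} with elements
#'   \code{points} (list of \code{polylat_point}), \code{exponents}
#'   (data.frame: mode, e_pp, e_ps, alpha, alpha_se, beta, beta_se,
#'   n_used), and \code{manifest} (per-point status).
#' @export
run_sweep <- function(config, n_min_fit = NULL) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- expand.grid(n = config$n_values, e_pp = config$e_pp_values,
                      e_ps = config$e_ps_values, KEEP.OUT.ATTRS = FALSE)
  points <- list()
  manifest <- data.frame(key = character(), seed = numeric(),
                         status = character(), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    n <- grid$n[r]; e_pp <- grid$e_pp[r]; e_ps <- grid$e_ps[r]
    pt_seed <- config$seed + (r - 1) * 100000
    key <- .point_key(n, config$mode, e_pp, e_ps)
    pt <- tryCatch(
      run_point(n, config$mode, e_pp = e_pp, e_ps = e_ps,
                replicas = if (is.function(config$replicas))
                  config$replicas(n) else config$replicas,
                seed = pt_seed,
                protocol = .protocol_for(config, n, e_ps), boot = config$boot,
                out_dir = config$out_dir),
      error = function(e) e)
    if (inherits(pt, "error")) {
      manifest <- rbind(manifest, data.frame(
        key = key, seed = pt_seed, status = paste("failed:",
                                                  conditionMessage(pt))))
      next
    }
    status <- if (is.na(pt$tau_r)) "ok (tau_R unavailable)" else "ok"
    manifest <- rbind(manifest, data.frame(key = key, seed = pt_seed,
                                           status = status))
    points[[key]] <- pt
  }

  exponents <- .fit_sweep_exponents(points, config$mode, n_min_fit)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(exponents, file.path(config$out_dir, "exponents.csv"),
              row.names = FALSE)
    jsonlite::write_json(exponents, file.path(config$out_dir,
                                              "exponents.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  structure(list(points = points, exponents = exponents, manifest = manifest,
                 config = config),
            class = "polylat_sweep")
}

.fit_sweep_exponents <- function(points, mode, n_min_fit = NULL) {
  empty <- data.frame(mode = character(), e_pp = numeric(), e_ps = numeric(),
                      alpha = numeric(), alpha_se = numeric(),
                      beta = numeric(), beta_se = numeric(),
                      n_used = character(), stringsAsFactors = FALSE)
  if (length(points) == 0) return(empty)
  tab <- do.call(rbind, lapply(points, function(p)
    data.frame(n = p$n, e_pp = p$e_pp, e_ps = p$e_ps, d_xy = p$d_xy,
               tau_r = p$tau_r)))
  if (!is.null(n_min_fit)) tab <- tab[tab$n >= n_min_fit, , drop = FALSE]
  out <- empty
  for (ep in unique(tab$e_pp)) for (es in unique(tab$e_ps)) {
    sub <- tab[tab$e_pp == ep & tab$e_ps == es, , drop = FALSE]
    if (nrow(sub) < 3) next
    a <- tryCatch(fit_scaling_exponent(sub$n, sub$d_xy, decreasing = TRUE),
                  error = function(e) NULL)
    subt <- sub[is.finite(sub$tau_r), , drop = FALSE]
    b <- tryCatch(fit_scaling_exponent(subt$n, subt$tau_r),
                  error = function(e) NULL)
    out <- rbind(out, data.frame(
      mode = mode, e_pp = ep, e_ps = es,
      alpha = if (is.null(a)) NA_real_ else a$exponent,
      alpha_se = if (is.null(a)) NA_real_ else a$se,
      beta = if (is.null(b)) NA_real_ else b$exponent,
      beta_se = if (is.null(b)) NA_real_ else b$se,
      n_used = paste(sub$n, collapse = ","), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.polylat_sweep <- function(x, ...) {
  cat(sprintf("polylat_sweep: %d points, mode %s\n", length(x$points),
              x$config$mode))
  print(x$exponents)
  invisible(x)
}

#' Write a trajectory in XYZ format
#'
#' One frame per recorded sample; every monomer is written with element tag
#' "C".  The run must have been produced with \code{record_positions = TRUE}.
#'
#' @param run a \code{\link{run_polymer}} result with recorded positions.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_xyz <- function(run, file) {
  if (is.null(run$positions))
    stop("run has no recorded positions; use record_positions = TRUE")
  pos <- run$positions
  n <- dim(pos)[2]
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(dim(pos)[1])) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t = %g MCS", run$times[f]), con)
    writeLines(sprintf("C %d %d %d", pos[f, , 1], pos[f, , 2], pos[f, , 3]),
               con)
  }
  invisible(file)
}
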