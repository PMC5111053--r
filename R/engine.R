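#' Rough relaxation-time scale used to size default run lengths
#'
#' Internal guide for the rotational relaxation time of the athermal chain,
#' calibrated once against pilot measurements with this engine: tau_R is
#' within about +/-40% of the guide over n = 8..64 in every mode.  In slab
#' geometry the relaxation slows with the surface attraction, hence the
#' e_ps-dependent prefactor.  Used only to size default equilibration and
#' production lengths and sampling intervals.
#' @noRd
.tau_guide <- function(n, mode, e_ps = 0) {
  switch(.mode_name(mode),
         bulk3d  = 1.0 * n^2.35,
         slab    = (0.35 + 0.30 * max(e_ps, 1)) * n^2.6,
         plane2d = 2.1 * n^2.7)
}

#' Run protocol: equilibration, adsorption and production schedule
#'
#' Defaults follow the model's own time scales.  Equilibration covers the
#' larger of \code{ceiling(n^(1 + 2 nu))} MCS (nu = 0.6 in 3D, 0.75
#' in-plane) and about two rotational relaxation times, so that production
#' always starts from a decorrelated equilibrium conformation; the settle
#' stage after first surface contact in slab mode uses the same scales; and
#' production covers roughly a dozen relaxation times so the end-to-end
#' autocorrelation decays well below its fit window.
#'
#' @param n chain length.
#' @param mode boundary mode.
#' @param e_ps surface attraction (kT); in slab mode stronger adsorption
#'   slows relaxation, so default run lengths grow with it.
#' @param equilibration_mcs MCS of pre-production equilibration (slab mode:
#'   between the virtual repulsive wall at z = L_z/4 and the top).
#' @param settle_mcs MCS run after the chain first touches the adsorbing
#'   surface, before production (slab mode only).
#' @param production_mcs MCS of recorded production.
#' @param sample_interval MCS between recorded frames.
#' @param adsorb_cap_mcs give up if the chain has not touched the surface
#'   within this many MCS after the virtual wall is removed.
#' @return An object of class \code{run_protocol}.
#' @examples
#' run_protocol(32, "slab", e_ps = 1)
#' @export
run_protocol <- function(n, mode = c("bulk3d", "slab", "plane2d"), e_ps = 0,
                         equilibration_mcs = NULL, settle_mcs = NULL,
                         production_mcs = NULL, sample_interval = NULL,
                         adsorb_cap_mcs = NULL) {
  mode <- match.arg(mode)
  nu <- if (mode == "plane2d") 0.75 else 0.6
  tau <- .tau_guide(n, mode, e_ps)
  if (is.null(equilibration_mcs))
    equilibration_mcs <- max(ceiling(n^(1 + 2 * nu)), ceiling(2 * tau))
  if (is.null(settle_mcs))
    settle_mcs <- max(ceiling(n^(1 + 2 * nu)), ceiling(tau))
  if (is.null(production_mcs)) production_mcs <- max(3000, ceiling(12 * tau))
  if (is.null(sample_interval))
    sample_interval <- max(1L, as.integer(floor(production_mcs / 2048)))
  if (is.null(adsorb_cap_mcs)) adsorb_cap_mcs <- 500 * equilibration_mcs + 1e5
  stopifnot(equilibration_mcs >= 0, settle_mcs >= 0, production_mcs >= 1,
            sample_interval >= 1, adsorb_cap_mcs >= 1)
  structure(list(equilibration_mcs = equilibration_mcs,
                 settle_mcs = settle_mcs,
                 production_mcs = production_mcs,
                 sample_interval = as.integer(sample_interval),
                 adsorb_cap_mcs = adsorb_cap_mcs),
            class = "run_protocol")
}

#' @export
print.run_protocol <- function(x, ...) {
  cat(sprintf(paste0("run_protocol: equil %g MCS, settle %g MCS, ",
                     "production %g MCS (sampled every %d MCS)\n"),
              x$equilibration_mcs, x$settle_mcs, x$production_mcs,
              x$sample_interval))
  invisible(x)
}

#' Simulate one polymer chain
#'
#' Runs the Metropolis single-monomer dynamics for one chain and records a
#' production trajectory.  In slab mode (unless \code{adsorb = FALSE}) the
#' run follows the equilibrate-then-adsorb protocol: the chain is first
#' equilibrated between a virtual repulsive wall at z = L_z/4 and the top of
#' the box, the wall is then removed and the chain diffuses until it first
#' touches the adsorbing surface, and it settles for \code{settle_mcs}
#' before production starts.
#'
#' One Monte Carlo step (MCS) consists of \code{n} attempted moves; rejected
#' attempts consume time.  Identical \code{seed} and configuration give a
#' bit-identical trajectory.
#'
#' @param n chain length (number of monomers).
#' @param mode boundary mode: \code{"bulk3d"}, \code{"slab"} or
#'   \code{"plane2d"}.
#' @param e_pp,e_ps attraction strengths in kT (see
#'   \code{\link{energy_params}}); \code{e_ps} only acts in slab mode.
#' @param box a \code{\link{box_spec}}; defaults to the mode's default box.
#' @param protocol a \code{\link{run_protocol}}; defaults to
#'   \code{run_protocol(n, mode)}.
#' @param seed integer seed of the run's private RNG stream.
#' @param adsorb use the adsorption protocol (slab mode only).
#' @param record_positions also record all monomer positions each frame
#'   (needed for \code{\link{write_xyz}}; memory-heavy for long runs).
#' @param check_every if > 0, re-verify all chain invariants (self-avoidance,
#'   bond lengths, non-crossing, contact bookkeeping) every
#'   \code{check_every} MCS and abort on any violation.
#' @param init_positions optional n x 3 integer matrix of starting positions
#'   (skips the internal initial configuration and, in slab mode, the
#'   adsorption protocol).
#' @return An object of class \code{polylat_run}: a list with the trajectory
#'   (\code{times}, \code{com}, \code{end_to_end}, \code{rg_sq}, \code{n_pp},
#'   \code{n_ps}, \code{energy}), run diagnostics (acceptance rate, desorbed
#'   fraction, adsorption waiting time) and the final configuration.
#' @examples
#' run <- run_polymer(8, "bulk3d", seed = 1,
#'                    protocol = run_protocol(8, "bulk3d",
#'                                            production_mcs = 500,
#'                                            sample_interval = 5))
#' mean(run$rg_sq)
#' @export
run_polymer <- function(n, mode = c("bulk3d", "slab", "plane2d"),
                        e_pp = 0, e_ps = 0, box = NULL, protocol = NULL,
                        seed = 1, adsorb = NULL, record_positions = FALSE,
                        check_every = 0, init_positions = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, e_pp >= 0, e_ps >= 0)
  if (is.null(box)) box <- box_spec(mode, n = n)
  stopifnot(box$mode == mode)
  if (is.null(protocol)) protocol <- run_protocol(n, mode, e_ps = e_ps)
  if (is.null(adsorb)) adsorb <- (mode == "slab")
  if (adsorb && mode != "slab") stop("the adsorption protocol requires slab mode")
  ip <- if (is.null(init_positions)) NULL else
    matrix(as.integer(as.matrix(init_positions)), ncol = 3)
  res <- run_chain_cpp(as.integer(n), .mode_code(mode), e_pp, e_ps,
                       c(box$l_x, box$l_y, box$l_z),
                       protocol$equilibration_mcs, protocol$settle_mcs,
                       protocol$production_mcs, protocol$sample_interval,
                       protocol$adsorb_cap_mcs, isTRUE(adsorb),
                       as.numeric(seed), as.integer(check_every),
                       isTRUE(record_positions), ip)
  if (record_positions && !is.null(res$positions)) {
    res$positions <- aperm(array(res$positions,
                                 dim = c(3, n, length(res$times))),
                           c(3, 2, 1))  # frame x monomer x coordinate
  }
  res$config <- list(n = n, mode = mode, e_pp = e_pp, e_ps = e_ps,
                     box = box, protocol = protocol, seed = seed,
                     adsorb = adsorb)
  class(res) <- "polylat_run"
  res
}

#' @export
print.polylat_run <- function(x, ...) {
  cf <- x$config
  cat(sprintf("polylat_run: n = %d, %s, e_pp = %g, e_ps = %g, seed = %s\n",
              cf$n, cf$mode, cf$e_pp, cf$e_ps, format(cf$seed)))
  cat(sprintf("  %d frames over %g MCS; acceptance %.3f",
              length(x$times), max(x$times), x$acceptance_rate))
  if (cf$mode == "slab")
    cat(sprintf("; desorbed fraction %.4f", x$desorbed_fraction))
  cat("\n")
  invisible(x)
}

#' Continue dynamics from a given configuration
#'
#' Runs \code{n_mcs} Monte Carlo steps starting from explicit positions,
#' recording every \code{sample_interval} MCS.  A thin wrapper around
#' \code{\link{run_polymer}} used mainly for validation (e.g. comparing the
#' engine's incremental contact bookkeeping against from-scratch recounts
#' along arbitrary trajectories).
#'
#' @param positions n x 3 integer matrix of starting positions.
#' @inheritParams run_polymer
#' @param n_mcs number of MCS to run.
#' @param sample_interval MCS between recorded frames.
#' @return A \code{polylat_run}.
#' @export
run_mcs <- function(positions, n_mcs, mode = c("bulk3d", "slab", "plane2d"),
                    e_pp = 0, e_ps = 0, box = NULL, seed = 1,
                    sample_interval = 1, record_positions = FALSE,
                    check_every = 0) {
  mode <- match.arg(mode)
  n <- nrow(as.matrix(positions))
  proto <- run_protocol(n, mode, equilibration_mcs = 0, settle_mcs = 0,
                        production_mcs = n_mcs,
                        sample_interval = sample_interval)
  run_polymer(n, mode, e_pp = e_pp, e_ps = e_ps, box = box, protocol = proto,
              seed = seed, adsorb = FALSE, record_positions = record_positions,
              check_every = check_every, init_positions = positions)
}

#' Is a proposed single-monomer move geometrically allowed?
#'
#' Applies the model's move constraints to an explicit configuration: the
#' target site must be empty (minimum image in periodic directions), both
#' affected bonds must stay in the allowed length set, neither displaced
#' bond may intersect any non-adjacent bond, and in slab mode the target
#' must respect the walls (z >= z_min, z <= L_z - 1).  This is the same
#' rule set the simulation engine applies internally; energetics play no
#' part here.
#'
#' @param positions n x 3 integer matrix (unwrapped).
#' @param monomer index (1-based) of the monomer to move.
#' @param direction integer axis unit vector of length 3.
#' @param mode boundary mode.
#' @param box a \code{\link{box_spec}}; defaults to the mode's default box.
#' @param z_min lower wall for the move (slab mode; 1 normally, L_z/4
#'   during virtual-wall equilibration).
#' @return Logical scalar.
#' @examples
#' pos <- rbind(c(0, 0, 1), c(1, 0, 1))
#' move_is_allowed(pos, 1, c(0, 0, -1), mode = "slab")  # into the wall
#' @export
move_is_allowed <- function(positions, monomer, direction,
                            mode = c("bulk3d", "slab", "plane2d"),
                            box = NULL, z_min = 1) {
  mode <- match.arg(mode)
  p <- as.matrix(positions)
  n <- nrow(p)
  stopifnot(monomer >= 1, monomer <= n, length(direction) == 3,
            sum(abs(direction)) == 1)
  if (is.null(box)) box <- box_spec(mode, n = n)
  l <- c(box$l_x, box$l_y, box$l_z)
  new_pos <- p[monomer, ] + direction
  if (mode == "slab" && (new_pos[3] < z_min || new_pos[3] > box$l_z - 1))
    return(FALSE)
  if (mode == "plane2d" && direction[3] != 0) return(FALSE)
  # occupancy with minimum image in the periodic directions
  mi <- function(d, i) {
    if (mode != "bulk3d" && i == 3) return(d)
    ((d + l[i] %/% 2) %% l[i]) - l[i] %/% 2
  }
  for (j in seq_len(n)[-monomer]) {
    d <- new_pos - p[j, ]
    if (all(vapply(1:3, function(i) mi(d[i], i), numeric(1)) == 0))
      return(FALSE)
  }
  nbrs <- c(monomer - 1, monomer + 1)
  nbrs <- nbrs[nbrs >= 1 & nbrs <= n]
  for (j in nbrs) {
    if (!bond_is_valid(new_pos - p[j, ], mode = mode)) return(FALSE)
  }
  if (n > 2) {
    for (j in nbrs) {
      for (k in seq_len(n - 1)) {           # bond k joins monomers k, k+1
        if (k %in% c(j - 1, j, monomer - 1, monomer)) next
        if (segments_intersect(p[j, ], new_pos, p[k, ], p[k + 1, ]))
          return(FALSE)
      }
    }
  }
  TRUE
}

#' Metropolis acceptance decision
#'
#' Accepts a proposed move with probability \code{min(1, exp(-d_e))} at
#' kT = 1.  Vectorised; uses R's RNG.
#'
#' @param d_e numeric vector of energy changes (kT).
#' @return Logical vector of accept decisions.
#' @examples
#' set.seed(1)
#' mean(metropolis_accept(rep(1, 1e4)))  # ~ exp(-1)
#' @export
metropolis_accept <- function(d_e) {
  runif(length(d_e)) < exp(-pmax(d_e, 0))
}

#' Sample move proposals
#'
#' Draws \code{n_prop} (monomer, direction) proposals exactly as the engine
#' does: the monomer index uniform on 1..n and the direction uniform on the
#' mode's axis unit vectors (six in 3D, four in-plane), so forward and
#' reverse moves are equally likely.
#'
#' @param n_prop number of proposals to draw.
#' @param n chain length.
#' @param mode boundary mode.
#' @param seed RNG stream seed.
#' @return A data.frame with columns \code{monomer}, \code{dx}, \code{dy},
#'   \code{dz}.
#' @export
propose_moves <- function(n_prop, n, mode = c("bulk3d", "slab", "plane2d"),
                          seed = 1) {
  mode <- match.arg(mode)
  m <- propose_moves_cpp(as.integer(n_prop), as.integer(n),
                         .mode_code(mode), as.numeric(seed))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  data.frame(monomer = m[, 1], dx = dirs[m[, 2], 1],
             dy = dirs[m[, 2], 2], dz = dirs[m[, 2], 3])
}
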