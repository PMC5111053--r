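#' Energy parameters of the lattice polymer
#'
#' The polymer energy is \code{E = -n_pp * e_pp - n_ps * e_ps}, where
#' \code{n_pp} counts non-bonded monomer pairs on nearest-neighbour sites and
#' \code{n_ps} counts monomers in the lattice layer adjacent to the wall
#' (z = 1, slab mode only).  Temperature is fixed by the convention kT = 1,
#' so both strengths are dimensionless.
#'
#' @param e_pp non-negative intra-polymer nearest-neighbour attraction (kT).
#' @param e_ps non-negative polymer-surface attraction (kT).
#' @return An object of class \code{energy_params}.
#' @examples
#' energy_params(e_pp = 0.5, e_ps = 1)
#' @export
energy_params <- function(e_pp = 0, e_ps = 0) {
  stopifnot(is.numeric(e_pp), length(e_pp) == 1, e_pp >= 0,
            is.numeric(e_ps), length(e_ps) == 1, e_ps >= 0)
  structure(list(e_pp = as.numeric(e_pp), e_ps = as.numeric(e_ps)),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf("energy_params: e_pp = %g kT, e_ps = %g kT (kT = 1)\n",
              x$e_pp, x$e_ps))
  invisible(x)
}

#' Simulation box specification
#'
#' In \code{bulk3d} mode the box is periodic in x, y and z.  In \code{slab}
#' mode it is periodic in x and y, an impenetrable adsorbing wall occupies
#' z = 0 (monomer sites start at z = 1) and a reflecting top closes the box
#' at z = L_z.  In \code{plane2d} mode the chain lives on a single z-plane
#' that is periodic in x and y.  The default edge length
#' \code{max(64, ceiling(4 * n^0.75))} keeps the chain from interacting with
#' its own periodic images.
#'
#' The slab default height is \code{max(6, ceiling(1.5 * n^0.588))}: several
#' times the vertical extent of a desorbed coil (whose per-axis radius of
#' gyration is only ~0.4 n^0.588), so the pre-adsorption equilibration is
#' unconfined in practice, while keeping the diffusive search for the
#' surface short and the chain firmly in the adsorbed regime during
#' production.
#'
#' @param mode one of \code{"bulk3d"}, \code{"slab"}, \code{"plane2d"}.
#' @param n chain length used to size the default box.
#' @param l_x,l_y,l_z explicit box dimensions (lattice units); \code{l_z} is
#'   forced to 1 in \code{plane2d} mode.
#' @return An object of class \code{box_spec}.
#' @examples
#' box_spec("slab", n = 64)
#' @export
box_spec <- function(mode = c("bulk3d", "slab", "plane2d"), n = 64,
                     l_x = NULL, l_y = NULL, l_z = NULL) {
  mode <- match.arg(mode)
  l_default <- max(64L, as.integer(ceiling(4 * n^0.75)))
  l_x <- if (is.null(l_x)) l_default else as.integer(l_x)
  l_y <- if (is.null(l_y)) l_x else as.integer(l_y)
  l_z <- if (mode == "plane2d") 1L else if (!is.null(l_z)) as.integer(l_z)
    else if (mode == "slab") max(6L, as.integer(ceiling(1.5 * n^0.588)))
    else l_x
  stopifnot(l_x >= 2, l_y >= 2, l_z >= 1)
  structure(list(mode = mode, l_x = l_x, l_y = l_y, l_z = l_z),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("box_spec: %s, %d x %d x %d\n", x$mode, x$l_x, x$l_y, x$l_z))
  invisible(x)
}

#' Is a bond vector allowed?
#'
#' A bond between consecutive monomers must have squared length 1, 2 or 3
#' (i.e. length 1, sqrt(2) or sqrt(3)); a chain confined to a plane only
#' admits squared lengths 1 and 2.
#'
#' @param displacement integer vector of length 3 (or an m x 3 matrix) giving
#'   the lattice vector between two consecutive monomers.
#' @param mode boundary mode; only \code{"plane2d"} changes the allowed set.
#' @return Logical (vectorised over matrix rows).
#' @examples
#' bond_is_valid(c(1, 1, 1))                    # sqrt(3): allowed in 3D
#' bond_is_valid(c(1, 1, 1), mode = "plane2d")  # has a z-component: not in-plane
#' @export
bond_is_valid <- function(displacement, mode = c("bulk3d", "slab", "plane2d")) {
  mode <- match.arg(mode)
  m <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  stopifnot(ncol(m) == 3, all(m == round(m)))
  sq <- rowSums(m^2)
  if (mode == "plane2d") sq %in% c(1, 2) & m[, 3] == 0 else sq %in% c(1, 2, 3)
}

#' Do two bonds geometrically intersect?
#'
#' Exact test (integer/rational arithmetic) of whether the closed line
#' segments a1--a2 and b1--b2 share at least one point.  This is the
#' non-crossing constraint of the model: during a move, neither displaced
#' bond may intersect any other bond; consecutive bonds sharing a monomer
#' are exempt from the test.
#'
#' @param a1,a2,b1,b2 integer vectors of length 3 (lattice sites).
#' @return Logical scalar.
#' @examples
#' # two face diagonals crossing at (0.5, 0.5, 0)
#' segments_intersect(c(0,0,0), c(1,1,0), c(1,0,0), c(0,1,0))
#' @export
segments_intersect <- function(a1, a2, b1, b2) {
  stopifnot(length(a1) == 3, length(a2) == 3, length(b1) == 3, length(b2) == 3)
  segments_intersect_cpp(as.integer(a1), as.integer(a2),
                         as.integer(b1), as.integer(b2))
}

#' Count energy-carrying contacts of a chain
#'
#' Recounts, from scratch, \code{n_pp} (unordered monomer pairs (i, j) with
#' |i - j| >= 2 at unit lattice distance, using the minimum-image convention
#' in periodic directions) and \code{n_ps} (monomers at z = 1; slab mode
#' only, otherwise 0).
#'
#' @param positions n x 3 integer matrix of monomer positions.
#' @param mode boundary mode.
#' @param box a \code{\link{box_spec}} (defaults to the default box for
#'   \code{nrow(positions)}).
#' @return Named integer vector \code{c(n_pp, n_ps)}.
#' @examples
#' pos <- rbind(c(0, 0, 5), c(1, 1, 5), c(1, 0, 5))
#' count_contacts(pos, "bulk3d")  # pair 1-3 is a non-bonded NN contact
#' @export
count_contacts <- function(positions, mode = c("bulk3d", "slab", "plane2d"),
                           box = NULL) {
  mode <- match.arg(mode)
  m <- as.matrix(positions)
  stopifnot(ncol(m) == 3)
  if (is.null(box)) box <- box_spec(mode, n = nrow(m))
  out <- count_contacts_cpp(matrix(as.integer(m), ncol = 3), .mode_code(mode),
                            c(box$l_x, box$l_y, box$l_z))
  c(n_pp = out[1], n_ps = out[2])
}

#' Total energy of a chain configuration
#'
#' Evaluates \code{E = -n_pp * e_pp - n_ps * e_ps} (in kT) after recounting
#' contacts from the given positions.
#'
#' @inheritParams count_contacts
#' @param params an \code{\link{energy_params}} object.
#' @return Energy in kT.
#' @examples
#' pos <- rbind(c(0, 0, 1), c(1, 0, 1))
#' total_energy(pos, energy_params(e_ps = 1.5), mode = "slab")  # -3
#' @export
total_energy <- function(positions, params,
                         mode = c("bulk3d", "slab", "plane2d"), box = NULL) {
  stopifnot(inherits(params, "energy_params"))
  cc <- count_contacts(positions, mode, box)
  -cc[["n_pp"]] * params$e_pp - cc[["n_ps"]] * params$e_ps
}

#' Squared radius of gyration of a configuration
#'
#' Mean squared distance of the monomers from their centroid, computed from
#' unwrapped positions.
#'
#' @param positions n x 3 numeric matrix of (unwrapped) monomer positions.
#' @return Non-negative scalar (lattice units squared).
#' @examples
#' radius_of_gyration_sq(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.25
#' @export
radius_of_gyration_sq <- function(positions) {
  m <- as.matrix(positions)
  stopifnot(ncol(m) == 3)
  ctr <- colMeans(m)
  mean(rowSums((m - rep(ctr, each = nrow(m)))^2))
}
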