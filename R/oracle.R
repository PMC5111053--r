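# Exact enumeration of tiny-chain ensembles.  Everything here is pure R and
# independent of the C++ engine, so that equilibrium averages and geometric
# rules can be validated against an implementation that shares no code with
# the sampler.

# all allowed bond vectors: squared length in {1,2,3} (3D) or {1,2} in-plane
.bond_vectors <- function(mode) {
  g <- expand.grid(x = -1:1, y = -1:1, z = if (mode == "plane2d") 0 else -1:1)
  g <- as.matrix(g)
  sq <- rowSums(g^2)
  allowed <- if (mode == "plane2d") sq %in% c(1, 2) else sq %in% c(1, 2, 3)
  g[allowed, , drop = FALSE]
}

# reference segment-intersection test, exact in integer arithmetic
.seg_intersect_ref <- function(a, b, cc, d) {
  cross3 <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                             p[3] * q[1] - p[1] * q[3],
                             p[1] * q[2] - p[2] * q[1])
  u <- b - a; v <- d - cc; w <- cc - a
  nv <- cross3(u, v)
  if (any(nv != 0)) {
    if (sum(nv * w) != 0) return(FALSE)          # skew
    den <- sum(nv * nv)
    s <- sum(cross3(w, v) * nv)
    t <- sum(cross3(w, u) * nv)
    return(s >= 0 && s <= den && t >= 0 && t <= den)
  }
  if (any(cross3(w, u) != 0)) return(FALSE)      # parallel, not collinear
  uu <- sum(u * u)
  t0 <- sum(w * u); t1 <- sum((d - a) * u)
  !(max(t0, t1) < 0 || min(t0, t1) > uu)
}

# does appending `new_pos` to `pos` (rows 1..k) keep the chain valid?
.growth_ok <- function(pos, k, new_pos) {
  for (i in seq_len(k))                            # self-avoidance
    if (all(pos[i, ] == new_pos)) return(FALSE)
  if (k >= 2) {                                    # new bond vs earlier bonds
    a <- pos[k, ]
    for (i in seq_len(k - 2))                      # bond (k-1,k) exempt
      if (.seg_intersect_ref(a, new_pos, pos[i, ], pos[i + 1, ]))
        return(FALSE)
  }
  TRUE
}

#' Exhaustively enumerate the configurations of a tiny chain
#'
#' Depth-first growth over all allowed bond vectors with self-avoidance and
#' non-crossing checks, in open space (no periodic wrapping; valid as long
#' as the comparison box is large enough that a short chain cannot touch its
#' own image).  Translations are modded out: the first monomer sits at the
#' origin in bulk and in-plane modes; in slab mode its x, y are fixed but
#' its absolute height runs over z = 1..z_max, and every monomer must stay
#' within 1 <= z <= z_max (a reflecting top at z_max, so the oracle ensemble
#' matches an engine box with L_z = z_max + 1).
#'
#' @param n chain length, at most 4 (exhaustive-search guard).
#' @param mode boundary mode.
#' @param params an \code{\link{energy_params}}; Boltzmann weights are
#'   \code{exp(e_pp * n_pp + e_ps * n_ps)} at kT = 1.
#' @param z_max slab mode: maximum monomer height.
#' @return An object of class \code{polylat_ensemble}: a data.frame with one
#'   row per configuration (columns \code{n_pp}, \code{n_ps}, \code{r_sq},
#'   \code{rg_sq}, \code{energy}, \code{weight}), the partition sum
#'   \code{Z}, and the list of position matrices in
#'   \code{attr(, "configs")}.
#' @examples
#' ens <- enumerate_chains(2, "bulk3d")
#' nrow(ens)                      # 26 relative two-monomer configurations
#' exact_average(ens, "r_sq")     # 27/13
#' @export
enumerate_chains <- function(n, mode = c("bulk3d", "slab", "plane2d"),
                             params = energy_params(), z_max = 6) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "energy_params"))
  if (n > 4) stop("enumeration is guarded to n <= 4")
  bonds <- .bond_vectors(mode)
  z0s <- if (mode == "slab") seq_len(z_max) else
    if (mode == "plane2d") 0L else 0L
  configs <- list()
  grow <- function(pos, k) {
    if (k == n) {
      configs[[length(configs) + 1L]] <<- pos
      return(invisible())
    }
    for (b in seq_len(nrow(bonds))) {
      np <- pos[k, ] + bonds[b, ]
      if (mode == "slab" && (np[3] < 1 || np[3] > z_max)) next
      if (!.growth_ok(pos, k, np)) next
      pos2 <- pos
      pos2[k + 1, ] <- np
      grow(pos2, k + 1)
    }
  }
  for (z0 in z0s) {
    pos <- matrix(0L, nrow = n, ncol = 3)
    pos[1, 3] <- z0
    grow(pos, 1)
  }
  tab <- do.call(rbind, lapply(configs, function(p) {
    npp <- 0L
    if (n >= 3) {
      for (i in 1:(n - 2)) for (j in (i + 2):n)
        if (sum((p[i, ] - p[j, ])^2) == 1) npp <- npp + 1L
    }
    nps <- if (mode == "slab") sum(p[, 3] == 1) else 0L
    data.frame(n_pp = npp, n_ps = nps,
               r_sq = sum((p[n, ] - p[1, ])^2),
               rg_sq = radius_of_gyration_sq(p),
               energy = -npp * params$e_pp - nps * params$e_ps)
  }))
  if (is.null(tab)) tab <- data.frame(n_pp = 0L, n_ps = 0L, r_sq = 0,
                                      rg_sq = 0, energy = 0)[0, ]
  tab$weight <- exp(-tab$energy)
  structure(tab, configs = configs, Z = sum(tab$weight),
            params = params, mode = mode, n = n,
            class = c("polylat_ensemble", "data.frame"))
}

#' Exact Boltzmann average over an enumerated ensemble
#'
#' @param ensemble an \code{\link{enumerate_chains}} result.
#' @param observable the name of a per-configuration column (one of
#'   \code{"r_sq"}, \code{"rg_sq"}, \code{"n_pp"}, \code{"n_ps"},
#'   \code{"energy"}) or a function of a position matrix.
#' @return The weighted average \code{sum(w * obs) / Z}.
#' @export
exact_average <- function(ensemble, observable) {
  stopifnot(inherits(ensemble, "polylat_ensemble"))
  w <- ensemble$weight
  obs <- if (is.function(observable)) {
    vapply(attr(ensemble, "configs"), observable, numeric(1))
  } else {
    stopifnot(observable %in% names(ensemble))
    ensemble[[observable]]
  }
  sum(w * obs) / attr(ensemble, "Z")
}

#' Exact configuration probabilities of an enumerated ensemble
#'
#' Convenience accessor for goodness-of-fit checks of the sampler: returns
#' the configurations keyed by a canonical string of their relative
#' coordinates together with their Boltzmann probabilities.
#'
#' @param ensemble an \code{\link{enumerate_chains}} result.
#' @return A data.frame with columns \code{key} and \code{prob}.
#' @export
ensemble_probabilities <- function(ensemble) {
  stopifnot(inherits(ensemble, "polylat_ensemble"))
  keys <- vapply(attr(ensemble, "configs"), config_key, character(1),
                 mode = attr(ensemble, "mode"))
  data.frame(key = keys, prob = ensemble$weight / attr(ensemble, "Z"),
             stringsAsFactors = FALSE)
}

#' Canonical key of a chain configuration (translations modded out in x, y
#' and, for non-slab modes, z)
#'
#' @param positions n x 3 integer matrix.
#' @param mode boundary mode (slab keeps absolute z).
#' @return A string key.
#' @export
config_key <- function(positions, mode = NULL) {
  p <- as.matrix(positions)
  if (is.null(mode)) mode <- "bulk3d"
  rel <- sweep(p, 2, c(p[1, 1], p[1, 2], if (mode == "slab") 0 else p[1, 3]))
  paste(t(rel), collapse = ",")
}
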