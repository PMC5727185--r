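#' Mechanical relaxation of the particle packing
#'
#' Restores approximate mechanical equilibrium after growth, division and
#' death by iterative pairwise shoving: every overlapping pair of spheres
#' is displaced symmetrically along its centre line by half the overlap,
#' with the lateral minimum-image convention and a hard floor at the enamel
#' plane (centres never drop below one radius). Sweeps repeat until the
#' largest overlap falls below \code{overlap_tol} times the mean radius or
#' \code{max_relax_iters} is reached, in which case a warning reports the
#' residual and the simulation proceeds. Positions are the only state
#' touched: masses, types and adaptation state are never modified.
#'
#' @param pop Population.
#' @param params Parameters.
#' @param quiet Suppress the non-convergence warning.
#' @return Population with updated positions; attributes
#'   \code{relax_iters}, \code{relax_residual} (largest remaining overlap,
#'   um) and \code{relax_sq_overlap} (total squared overlap per sweep).
#' @export
relax_packing <- function(pop, params, quiet = FALSE) {
  if (nrow(pop) == 0L) return(pop)
  r <- particle_radius(pop$mass + pop$eps, params$biomass_density)
  tol_abs <- params$overlap_tol * mean(r)
  res <- relax_cpp(pop$x, pop$y, pop$z, r, params$box_x, params$box_y,
                   tol_abs, as.integer(params$max_relax_iters))
  pop$x <- res$x; pop$y <- res$y; pop$z <- res$z
  if (res$max_overlap > tol_abs && !quiet) {
    warning(sprintf(
      "shoving did not converge in %d sweeps (residual overlap %.3g um)",
      res$iters, res$max_overlap), call. = FALSE)
  }
  attr(pop, "relax_iters") <- res$iters
  attr(pop, "relax_residual") <- res$max_overlap
  attr(pop, "relax_sq_overlap") <- res$sq_overlap
  pop
}

#' Particle radii of a population
#' @param pop Population.
#' @param params Parameters.
#' @return Radii, um (from total cell + EPS mass at the biomass density).
#' @export
particle_radii <- function(pop, params) {
  particle_radius(pop$mass + pop$eps, params$biomass_density)
}
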