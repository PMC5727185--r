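#' Initialise the particle population
#'
#' Particles (cell aggregates) are placed on a regular lattice filling the
#' box up to \code{h_plaque}, with lattice spacing equal to the particle
#' diameter at the division mass. Each particle is independently of type A
#' with probability \code{init_fraction_A} (uniform spatial mixing), starts
#' at half the division mass with no EPS, and carries its type's initial
#' acidity optimum.
#'
#' Uses the current R random stream; call \code{set.seed()} first for a
#' reproducible population.
#'
#' @param params A [plaque_params()] object.
#' @return A \code{data.frame} of class \code{plaque_population} with
#'   columns \code{id}, \code{type} ("A"/"NA"), \code{x}, \code{y},
#'   \code{z} (um), \code{mass}, \code{eps} (g), \code{K_acid} (mol/L).
#' @export
init_population <- function(params) {
  s <- 2 * particle_radius(params$m_max, params$biomass_density)
  nx <- floor(params$box_x / s + 1e-6)
  ny <- floor(params$box_y / s + 1e-6)
  nz <- floor(params$h_plaque / s + 1e-6)
  if (nx < 1 || ny < 1 || nz < 1) {
    stop("lattice spacing exceeds the domain: particle diameter too large",
         call. = FALSE)
  }
  gx <- (seq_len(nx) - 0.5) * s
  gy <- (seq_len(ny) - 0.5) * s
  gz <- (seq_len(nz) - 0.5) * s
  pos <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pos)
  is_A <- stats::runif(n) < params$init_fraction_A
  pop <- data.frame(
    id = seq_len(n),
    type = ifelse(is_A, "A", "NA"),
    x = pos$x, y = pos$y, z = pos$z,
    mass = rep(params$m_max / 2, n),
    eps = rep(0, n),
    K_acid = ifelse(is_A, params$K_acid_A0, params$K_acid_NA0),
    stringsAsFactors = FALSE
  )
  attr(pop, "next_id") <- n + 1L
  class(pop) <- c("plaque_population", "data.frame")
  pop
}

#' Population counters
#' @param pop A population.
#' @return List with \code{N_A}, \code{N_NA}, \code{N_total}.
#' @export
pop_counts <- function(pop) {
  N_A <- sum(pop$type == "A")
  list(N_A = N_A, N_NA = nrow(pop) - N_A, N_total = nrow(pop))
}

# per-particle lookup of a type-dependent parameter pair (A value, NA value)
.by_type <- function(type, a_val, na_val) ifelse(type == "A", a_val, na_val)

#' pH inhibition factor of glycolysis
#'
#' \code{4 H K / (H + K)^2}: a bell-shaped factor on the log[H+] axis with
#' maximum value 1 attained exactly at \code{H == K}, suppressing
#' metabolism on either side of the particle's optimal acidity.
#'
#' @param H Environmental H+ concentration(s), mol/L (> 0).
#' @param K Optimal H+ concentration(s), mol/L (> 0).
#' @return Factor(s) in (0, 1].
#' @export
acid_inhibition <- function(H, K) {
  if (any(H <= 0) || any(K <= 0)) {
    stop("H and K must be positive", call. = FALSE)
  }
  4 * H * K / (H + K)^2
}

#' Glycolysis rate on a single carbon source
#'
#' Mass-specific Monod kinetics with pH inhibition:
#' \deqn{r_i = m_i \mu_{max} \frac{[Gl]}{[Gl]+K^{Gl}}
#'   \frac{4 [H^+] K^{acid}}{([H^+]+K^{acid})^2}.}
#' Uses each particle's current (possibly adapted) acidity optimum.
#'
#' @param pop Population.
#' @param Gl Substrate concentration(s), g/L (scalar or per particle).
#' @param H H+ concentration(s), mol/L (scalar or per particle).
#' @param params Parameters.
#' @return Per-particle rate, g substrate / h.
#' @export
glycolysis_rate <- function(pop, Gl, H, params) {
  if (any(Gl < 0)) stop("Gl must be non-negative", call. = FALSE)
  K_Gl <- .by_type(pop$type, params$K_Gl_A, params$K_Gl_NA)
  pop$mass * params$mu_max * Gl / (Gl + K_Gl) *
    acid_inhibition(H, pop$K_acid)
}

#' Combined substrate and acid-production rates
#'
#' Glycolysis is evaluated separately on dietary glucose and on the
#' polyglucose background and the rates added. Acid production converts
#' consumed substrate (g/h) to lactate (mol/h) with a fixed stoichiometry
#' (default 2 mol lactate per mol glucose). Polyglucose consumption does
#' not deplete the polyglucose pool.
#'
#' @param pop Population.
#' @param intakeGl Dietary glucose at each particle, g/L.
#' @param polyGl Polyglucose level, g/L (scalar or per particle).
#' @param H H+ at each particle, mol/L.
#' @param params Parameters.
#' @return List of per-particle vectors: \code{glucose_uptake} (g/h),
#'   \code{polyGl_uptake} (g/h), \code{acid_production} (mol lactate/h),
#'   \code{glycolysis} (g/h total, drives growth).
#' @export
total_rates <- function(pop, intakeGl, polyGl, H, params) {
  r_gl <- glycolysis_rate(pop, intakeGl, H, params)
  r_poly <- glycolysis_rate(pop, polyGl, H, params)
  total <- r_gl + r_poly
  list(glucose_uptake = r_gl,
       polyGl_uptake = r_poly,
       acid_production = params$lactate_per_glucose * total / params$glucose_mw,
       glycolysis = total)
}

#' Grow particles
#'
#' Mass increases at \code{yield_growth} times the glycolysis rate and EPS
#' at \code{yield_EPS} times it; the particle radius follows from the total
#' (cell + EPS) mass at the biomass density, assuming spheres.
#'
#' @param pop Population.
#' @param rate Per-particle glycolysis rate, g/h.
#' @param dt Step, h.
#' @param params Parameters.
#' @return Updated population.
#' @export
grow <- function(pop, rate, dt, params) {
  stopifnot(dt > 0)
  pop$mass <- pop$mass + params$yield_growth * rate * dt
  pop$eps <- pop$eps + params$yield_EPS * rate * dt
  pop
}

#' Division sweep
#'
#' Every particle at or above the division mass \code{m_max} is replaced by
#' two daughters, each with half the mother's mass and half her EPS, placed
#' tangentially along a uniformly random direction (centres one daughter
#' radius either side of the mother's centre; z clipped so daughters do not
#' penetrate the enamel). Both daughters' acidity optima revert to the
#' type's initial value: adaptation is not inherited. Total mass and EPS
#' are conserved exactly.
#'
#' Uses the current R random stream.
#'
#' @param pop Population.
#' @param params Parameters.
#' @return Updated population.
#' @export
divide_sweep <- function(pop, params) {
  div <- which(pop$mass >= params$m_max)
  if (length(pop$mass) == 0L || length(div) == 0L) return(pop)
  mothers <- pop[div, , drop = FALSE]
  half_m <- mothers$mass / 2
  half_e <- mothers$eps / 2
  r_d <- particle_radius(half_m + half_e, params$biomass_density)
  # uniform random direction on the sphere
  u <- matrix(stats::rnorm(3 * nrow(mothers)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  K0 <- .by_type(mothers$type, params$K_acid_A0, params$K_acid_NA0)
  next_id <- attr(pop, "next_id")
  mk_daughter <- function(sgn, ids) {
    data.frame(id = ids, type = mothers$type,
               x = mothers$x + sgn * u[, 1] * r_d,
               y = mothers$y + sgn * u[, 2] * r_d,
               z = pmax(mothers$z + sgn * u[, 3] * r_d, r_d),
               mass = half_m, eps = half_e, K_acid = K0,
               stringsAsFactors = FALSE)
  }
  d1 <- mk_daughter(+1, mothers$id)
  d2 <- mk_daughter(-1, seq.int(next_id, length.out = nrow(mothers)))
  out <- rbind(pop[-div, , drop = FALSE], d1, d2)
  attr(out, "next_id") <- next_id + nrow(mothers)
  class(out) <- c("plaque_population", "data.frame")
  rownames(out) <- NULL
  out
}

#' Acid-dependent death hazard
#'
#' \deqn{r^{death}_i = r^{death}_{type} \, [H^+] / 10^{-7}:} the death rate
#' equals the type's tabulated rate at neutral pH and rises linearly with
#' environmental H+.
#'
#' @param pop Population.
#' @param H H+ concentration(s), mol/L (> 0).
#' @param params Parameters.
#' @return Per-particle hazard, 1/h.
#' @export
death_hazard <- function(pop, H, params) {
  if (any(H <= 0)) stop("H must be positive", call. = FALSE)
  .by_type(pop$type, params$death_rate_A, params$death_rate_NA) * H / 1e-7
}

#' Stochastic death sweep
#'
#' Each particle dies within the step with probability
#' \code{1 - exp(-hazard * dt)} (exponential waiting time at its current
#' hazard); dead particles are removed entirely, with no utilisation of
#' residual biomass. Uses the current R random stream.
#'
#' @param pop Population.
#' @param H Per-particle H+, mol/L.
#' @param dt Step, h.
#' @param params Parameters.
#' @return Updated population.
#' @export
apply_death <- function(pop, H, dt, params) {
  if (nrow(pop) == 0L) return(pop)
  p_die <- 1 - exp(-death_hazard(pop, H, params) * dt)
  keep <- stats::runif(nrow(pop)) >= p_die
  out <- pop[keep, , drop = FALSE]
  attr(out, "next_id") <- attr(pop, "next_id")
  class(out) <- c("plaque_population", "data.frame")
  rownames(out) <- NULL
  out
}

#' Phenotypic adaptation of the acidity optimum
#'
#' Each particle's optimum moves towards the current environmental acidity
#' at its type's rate M: \code{dK/dt = M (H - K)}, integrated exactly over
#' the step with H frozen:
#' \code{K <- H + (K - H) * exp(-M dt)}. With \code{M = 0} the optimum
#' never changes.
#'
#' @param pop Population.
#' @param H Per-particle H+, mol/L.
#' @param dt Step, h.
#' @param params Parameters.
#' @return Updated population.
#' @export
adapt <- function(pop, H, dt, params) {
  stopifnot(dt > 0)
  M <- .by_type(pop$type, params$M_A, params$M_NA)
  pop$K_acid <- H + (pop$K_acid - H) * exp(-M * dt)
  pop
}

#' Remove particles above the pruning height
#'
#' Every particle whose centre exceeds \code{h_plaque} is removed,
#' modelling loss of biomass beyond the biofilm's fixed thickness.
#'
#' @param pop Population.
#' @param h_plaque Pruning height, um.
#' @return Updated population.
#' @export
prune_above <- function(pop, h_plaque) {
  out <- pop[pop$z <= h_plaque, , drop = FALSE]
  attr(out, "next_id") <- attr(pop, "next_id")
  class(out) <- c("plaque_population", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a particle snapshot as CSV
#'
#' Columns: id, type, x, y, z (um), mass, eps (g), K_acid (mol/L).
#'
#' @param pop Population.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_particles_csv <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}
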