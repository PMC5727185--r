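#' Model parameters for the plaque biofilm simulator
#'
#' Constructs and validates the full parameter set: geometry, per-type
#' kinetics, yields, death and adaptation rates, solute diffusivities, the
#' buffered pH chemistry, and solver constants. Defaults reproduce the
#' standard parameterisation of the model (250 um biofilm under a 250 um
#' saliva layer on a 500 x 500 um patch of enamel, two cell types A =
#' aciduric and NA = non-aciduric).
#'
#' Units are micrometres for lengths, hours for times, g/L for sugar
#' concentrations, mol/L for H+ and lactate, and grams for particle mass.
#'
#' @param h_plaque Biofilm thickness / pruning height, um.
#' @param h_saliva Saliva layer thickness, um. The saliva-air interface sits
#'   at \code{h_plaque + h_saliva}.
#' @param box_x,box_y Lateral domain size, um (periodic directions).
#' @param K_Gl_A,K_Gl_NA Glucose half-saturation constants, g/L.
#' @param K_acid_A0,K_acid_NA0 Initial optimal H+ concentration for
#'   glycolysis, mol/L. A's optimum (1e-5, pH 5) is more acidic than NA's
#'   (1e-7, pH 7).
#' @param mu_max Glycolysis base rate, 1/h (both types).
#' @param polyGl_fraction Stored polyglucose as a fraction of the total
#'   daily intake (dimensionless).
#' @param yield_growth Growth yield: mass increase per unit glycolysis.
#' @param yield_EPS EPS production yield per unit glycolysis.
#' @param death_rate_A,death_rate_NA Death rates at neutral pH, 1/h. Must
#'   satisfy \code{death_rate_A < death_rate_NA} (A is more acid tolerant).
#' @param M_A,M_NA Adaptation rates, 1/h; 0 disables adaptation.
#' @param init_fraction_A Initial aciduric fraction of the population.
#' @param D_glucose,D_lactate Diffusivities, m^2/s, uniform over biofilm and
#'   saliva.
#' @param biomass_density Particle biomass density, g/L (mass to radius
#'   conversion assuming spherical aggregates). The default, a dry-biomass
#'   scale value, is calibrated so that the standard-depth film's enamel pH
#'   spans the high-4s to high-5s across physiological intakes with a
#'   famine plateau near 6 (see the vignette).
#' @param m_max Division threshold mass, g. The default gives a 10 um
#'   diameter aggregate at division at the default density.
#' @param grid_spacing Solute grid spacing, um; must divide \code{box_x},
#'   \code{box_y} and \code{h_plaque + h_saliva} evenly.
#' @param baseline_pH Resting pH of saliva with no lactate present.
#' @param buffer_conc,buffer_pKa Salivary buffer total concentration
#'   (mol/L) and pKa.
#' @param lactic_pKa pKa of lactic acid.
#' @param lactate_per_glucose Stoichiometry, mol lactate per mol glucose
#'   (2 = homolactic fermentation).
#' @param glucose_mw Molar mass of glucose, g/mol.
#' @param sample_mode,deposit_mode Field/particle coupling: \code{"nearest"}
#'   (containing cell) or \code{"trilinear"}.
#' @param overlap_tol Mechanical relaxation tolerance, as a fraction of the
#'   mean particle radius.
#' @param max_relax_iters Maximum shoving sweeps per biology step.
#' @param dt_field Solute substep, h.
#' @param dt_bio_fine,dt_bio_coarse Biology macro-steps, h, used inside /
#'   outside the refined window around each glucose pulse.
#' @param fine_margin Half-width of the refined stepping window around each
#'   pulse, h.
#' @return An object of class \code{plaque_params} (a validated named list).
#' @seealso [intake_schedule()], [plaque_sim()], [preset_params()]
#' @export
plaque_params <- function(h_plaque = 250,
                          h_saliva = 250,
                          box_x = 500,
                          box_y = 500,
                          K_Gl_A = 0.4,
                          K_Gl_NA = 0.1,
                          K_acid_A0 = 1e-5,
                          K_acid_NA0 = 1e-7,
                          mu_max = 5,
                          polyGl_fraction = 0.01,
                          yield_growth = 0.1,
                          yield_EPS = 0.04,
                          death_rate_A = 3e-3,
                          death_rate_NA = 6e-3,
                          M_A = 0,
                          M_NA = 0,
                          init_fraction_A = 0.05,
                          D_glucose = 6.7e-10,
                          D_lactate = 1.0e-9,
                          biomass_density = 40,
                          m_max = 40 * (4 / 3) * pi * 5^3 / 1e15,
                          grid_spacing = 10,
                          baseline_pH = 7,
                          buffer_conc = 0.030,
                          buffer_pKa = 6.8,
                          lactic_pKa = 3.86,
                          lactate_per_glucose = 2,
                          glucose_mw = 180.16,
                          sample_mode = c("nearest", "trilinear"),
                          deposit_mode = c("nearest", "trilinear"),
                          overlap_tol = 0.01,
                          max_relax_iters = 100,
                          dt_field = 1 / 60,
                          dt_bio_fine = 1 / 60,
                          dt_bio_coarse = 1 / 6,
                          fine_margin = 0.5) {
  p <- list(
    h_plaque = h_plaque, h_saliva = h_saliva,
    box_x = box_x, box_y = box_y,
    K_Gl_A = K_Gl_A, K_Gl_NA = K_Gl_NA,
    K_acid_A0 = K_acid_A0, K_acid_NA0 = K_acid_NA0,
    mu_max = mu_max, polyGl_fraction = polyGl_fraction,
    yield_growth = yield_growth, yield_EPS = yield_EPS,
    death_rate_A = death_rate_A, death_rate_NA = death_rate_NA,
    M_A = M_A, M_NA = M_NA,
    init_fraction_A = init_fraction_A,
    D_glucose = D_glucose, D_lactate = D_lactate,
    biomass_density = biomass_density, m_max = m_max,
    grid_spacing = grid_spacing,
    baseline_pH = baseline_pH, buffer_conc = buffer_conc,
    buffer_pKa = buffer_pKa, lactic_pKa = lactic_pKa,
    lactate_per_glucose = lactate_per_glucose, glucose_mw = glucose_mw,
    sample_mode = match.arg(sample_mode),
    deposit_mode = match.arg(deposit_mode),
    overlap_tol = overlap_tol, max_relax_iters = max_relax_iters,
    dt_field = dt_field, dt_bio_fine = dt_bio_fine,
    dt_bio_coarse = dt_bio_coarse, fine_margin = fine_margin
  )
  class(p) <- "plaque_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity, fraction ranges, the required ordering of the two
#' types' death rates and acidity optima, and that the grid spacing tiles
#' the domain exactly.
#'
#' @param p A \code{plaque_params} object.
#' @return \code{p}, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "plaque_params"))
  pos <- c("h_plaque", "h_saliva", "box_x", "box_y", "K_Gl_A", "K_Gl_NA",
           "K_acid_A0", "K_acid_NA0", "mu_max", "yield_growth",
           "death_rate_A", "death_rate_NA", "D_glucose", "D_lactate",
           "biomass_density", "m_max", "grid_spacing", "buffer_conc",
           "lactate_per_glucose", "glucose_mw", "overlap_tol", "dt_field",
           "dt_bio_fine", "dt_bio_coarse")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single positive number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("polyGl_fraction", "init_fraction_A")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("parameter '%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  for (nm in c("M_A", "M_NA", "yield_EPS")) {
    if (p[[nm]] < 0) stop(sprintf("parameter '%s' must be >= 0", nm),
                          call. = FALSE)
  }
  if (!(p$death_rate_A < p$death_rate_NA)) {
    stop("death_rate_A must be < death_rate_NA (A is the acid-tolerant type)",
         call. = FALSE)
  }
  if (!(-log10(p$K_acid_A0) < -log10(p$K_acid_NA0))) {
    stop("K_acid_A0 must exceed K_acid_NA0 (A's pH optimum is more acidic)",
         call. = FALSE)
  }
  h_total <- p$h_plaque + p$h_saliva
  for (ext in c(x = p$box_x, y = p$box_y, z = h_total)) {
    n <- ext / p$grid_spacing
    if (abs(n - round(n)) > 1e-9) {
      stop("grid_spacing must divide box_x, box_y and h_plaque + h_saliva ",
           "evenly", call. = FALSE)
    }
  }
  invisible(p)
}

#' Preset parameterisations
#'
#' \code{"full"} is the full-scale standard parameterisation (500 um box,
#' 250 + 250 um plaque and saliva, 10 um grid; around 6e4 particles).
#' \code{"patch"} keeps the full 250 + 250 um depth — and with it the
#' mass-transfer limitation that the cariogenicity map depends on — on a
#' reduced 100 x 100 um lateral patch (2500 initial particles).
#' \code{"desk"} further shrinks the film to 100 um under 50 um of saliva
#' (1000 initial particles): the cheapest preset, for interactive work and
#' engine-level testing; its thin film is far less acidic than full depth.
#'
#' @param preset \code{"full"}, \code{"patch"} or \code{"desk"}.
#' @param ... Overrides passed on to [plaque_params()].
#' @return A \code{plaque_params} object.
#' @export
preset_params <- function(preset = c("full", "patch", "desk"), ...) {
  preset <- match.arg(preset)
  switch(preset,
    paper = plaque_params(...),
    patch = plaque_params(box_x = 100, box_y = 100, ...),
    desk = plaque_params(h_plaque = 100, h_saliva = 50, box_x = 100,
                         box_y = 100, grid_spacing = 10, ...)
  )
}

#' @export
print.plaque_params <- function(x, ...) {
  cat("Plaque model parameters\n")
  cat(sprintf("  domain: %g x %g um, plaque %g um + saliva %g um, grid %g um\n",
              x$box_x, x$box_y, x$h_plaque, x$h_saliva, x$grid_spacing))
  cat(sprintf("  kinetics: mu_max %g/h; K_Gl A %g, NA %g g/L; pH optima A %g, NA %g\n",
              x$mu_max, x$K_Gl_A, x$K_Gl_NA,
              -log10(x$K_acid_A0), -log10(x$K_acid_NA0)))
  cat(sprintf("  yields: growth %g, EPS %g; death at pH 7: A %g, NA %g /h\n",
              x$yield_growth, x$yield_EPS, x$death_rate_A, x$death_rate_NA))
  cat(sprintf("  adaptation: M_A %g, M_NA %g /h; initial aciduric fraction %g\n",
              x$M_A, x$M_NA, x$init_fraction_A))
  invisible(x)
}

# radius (um) of a sphere of total mass m (g) at the biomass density (g/L);
# 1 L = 1e15 um^3
particle_radius <- function(mass, density) {
  vol_um3 <- mass / density * 1e15
  (3 * vol_um3 / (4 * pi))^(1 / 3)
}
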