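#' Length of the next biology macro-step
#'
#' Biology advances with a fine step inside a refinement window extending
#' \code{fine_margin} hours either side of each glucose pulse and a coarse
#' step elsewhere; steps are truncated so that pulse and window boundaries
#' are always landed on exactly (the boundary condition is then constant
#' within any one step).
#'
#' @param schedule Intake schedule.
#' @param t Current time, h.
#' @param params Parameters.
#' @return Step length, h.
#' @export
next_macro_dt <- function(schedule, t, params) {
  period <- 24 / schedule$frequency
  dur <- schedule$pulse_minutes / 60
  margin <- params$fine_margin
  p <- (t - schedule$first_pulse_time) %% period
  # circular distance from the pulse interval [0, dur]
  d <- if (p <= dur) 0 else min(p - dur, period - p)
  dt0 <- if (d < margin - 1e-12) params$dt_bio_fine else params$dt_bio_coarse
  bounds <- unique(c(0, dur, (dur + margin) %% period,
                     (-margin) %% period))
  ahead <- (bounds - p) %% period
  ahead <- ahead[ahead > 1e-9]
  if (length(ahead)) dt0 <- min(dt0, min(ahead))
  dt0
}

#' Run the plaque biofilm simulation
#'
#' The main entry point. Starting from a lattice of particles filling the
#' biofilm region (5\% aciduric by default) and empty solute fields, the
#' simulation advances in operator-split macro-steps. Each step:
#' \enumerate{
#'   \item samples glucose, polyglucose and H+ at every particle and
#'     evaluates the Monod/pH-inhibition glycolysis rates on both carbon
#'     sources;
#'   \item deposits the resulting glucose sink and lactate source on the
#'     grid and advances both solute fields semi-implicitly with the
#'     current pulsed boundary condition;
#'   \item grows particles (and their EPS) in proportion to glycolysis and
#'     relaxes each particle's acidity optimum towards the local acidity;
#'   \item applies stochastic acid-dependent death;
#'   \item divides particles that reached the division mass;
#'   \item relaxes the sphere packing by shoving;
#'   \item prunes particles above the biofilm thickness and records
#'     observables.
#' }
#' A (schedule, params, seed) triple fully determines the trajectory.
#'
#' @param schedule An [intake_schedule()].
#' @param params A [plaque_params()]; see [preset_params()].
#' @param days Simulated duration, days (may be fractional; 0 returns the
#'   initial state only).
#' @param seed Integer seed for the single global random stream.
#' @param snapshot_every Interval between stored particle + field
#'   snapshots, h (\code{Inf} stores only the final state).
#' @param callback Optional \code{function(state)} invoked after every
#'   macro-step; returned values are collected.
#' @param resume A state from [restore_sim()] to continue instead of
#'   initialising (seed is then taken from the saved stream).
#' @return An object of class \code{plaque_sim}: list with
#'   \code{trajectory} (one row per macro-step: \code{t}, \code{pulse},
#'   \code{N_A}, \code{N_total}, \code{enamel_pH}, \code{mean_pH},
#'   \code{total_glucose}, \code{total_lactate}, \code{clipped_glucose}),
#'   \code{snapshots}, \code{final} state, \code{params}, \code{schedule},
#'   \code{seed}, \code{status} ("completed" or "extinct").
#' @examples
#' sim <- plaque_sim(intake_schedule(15, 4), preset_params("desk"),
#'                   days = 0, seed = 1)
#' summary(sim)
#' @export
plaque_sim <- function(schedule, params = plaque_params(), days,
                       seed = 1L, snapshot_every = Inf, callback = NULL,
                       resume = NULL) {
  stopifnot(inherits(schedule, "intake_schedule"),
            inherits(params, "plaque_params"), days >= 0)
  validate_params(params)
  grid <- make_grid(params)
  lookup <- build_ph_lookup(params)

  if (is.null(resume)) {
    set.seed(seed)
    st <- list(time = 0,
               pop = init_population(params),
               fields = make_fields(grid, params, schedule),
               obs = list(), snapshots = list(),
               next_snapshot = snapshot_every,
               clipped_glucose = 0, clipped_lactate = 0,
               params = params, schedule = schedule, seed = seed)
  } else {
    st <- resume
    assign(".Random.seed", st$rng, envir = globalenv())
    params <- st$params; schedule <- st$schedule; seed <- st$seed
    grid <- make_grid(params)
    lookup <- build_ph_lookup(params)
  }

  bottom <- seq_len(grid$nx * grid$ny)
  record <- function(st, pulse_on, gamma = NA_real_) {
    la <- as.vector(st$fields$lactate)
    ph_bottom <- mean(ph_lookup_eval(lookup, la[bottom]))
    cnt <- pop_counts(st$pop)
    st$obs[[length(st$obs) + 1L]] <- c(
      t = st$time, pulse = as.numeric(pulse_on),
      N_A = cnt$N_A, N_total = cnt$N_total,
      enamel_pH = ph_bottom,
      mean_pH = mean(ph_lookup_eval(lookup, la)),
      total_glucose = sum(st$fields$glucose) * grid$cell_volume,
      total_lactate = sum(la) * grid$cell_volume,
      clipped_glucose = st$clipped_glucose,
      growth_rate = gamma)
    st
  }
  if (is.null(resume)) st <- record(st, pulse_active(schedule, 0))

  solvers <- new.env(parent = emptyenv())
  status <- "completed"
  cb_out <- list()
  t_end <- days * 24

  while (st$time < t_end - 1e-9) {
    dt <- min(next_macro_dt(schedule, st$time, params), t_end - st$time)
    bc <- boundary_glucose(schedule, st$time + dt / 2)

    env <- sample_at_particles(st$fields, st$pop, grid, params, lookup)
    rates <- total_rates(st$pop, env$glucose, env$polyGl, env$H_plus, params)
    gamma <- mean(params$yield_growth * rates$glycolysis / st$pop$mass)
    uptake <- deposit_rates(st$pop, rates$glucose_uptake, grid, params)
    acid <- deposit_rates(st$pop, rates$acid_production, grid, params)
    sf <- step_fields(st$fields, uptake, acid, dt, bc, grid, params, solvers)
    st$fields <- sf$fields
    st$clipped_glucose <- st$clipped_glucose + sf$clipped_glucose
    st$clipped_lactate <- st$clipped_lactate + sf$clipped_lactate

    st$pop <- grow(st$pop, rates$glycolysis, dt, params)
    st$pop <- adapt(st$pop, env$H_plus, dt, params)
    st$pop <- apply_death(st$pop, env$H_plus, dt, params)
    st$pop <- divide_sweep(st$pop, params)
    st$pop <- relax_packing(st$pop, params, quiet = TRUE)
    st$pop <- prune_above(st$pop, params$h_plaque)
    st$time <- st$time + dt

    if (any(!is.finite(st$fields$glucose)) ||
        any(!is.finite(st$fields$lactate)) ||
        (nrow(st$pop) && any(!is.finite(st$pop$mass) | st$pop$mass <= 0))) {
      dump <- file.path(tempdir(), sprintf("plaquesim-abort-%d.rds",
                                           as.integer(seed)))
      st$rng <- get(".Random.seed", envir = globalenv())
      saveRDS(st, dump)
      stop("non-finite or non-positive state at t = ", st$time,
           " h; state dumped to ", dump, call. = FALSE)
    }

    st <- record(st, bc > 0, gamma)
    if (st$time >= st$next_snapshot - 1e-9) {
      st$snapshots[[length(st$snapshots) + 1L]] <-
        list(t = st$time, pop = st$pop, fields = st$fields)
      st$next_snapshot <- st$next_snapshot + snapshot_every
    }
    if (!is.null(callback)) cb_out[[length(cb_out) + 1L]] <- callback(st)
    if (nrow(st$pop) == 0L) { status <- "extinct"; break }
  }

  st$rng <- get(".Random.seed", envir = globalenv())
  traj <- as.data.frame(do.call(rbind, st$obs))
  out <- list(trajectory = traj,
              snapshots = st$snapshots,
              final = st,
              params = params, schedule = schedule,
              grid = grid, days = days, seed = seed,
              status = status, callback_results = cb_out)
  class(out) <- "plaque_sim"
  out
}

.CHECKPOINT_VERSION <- "plaquesim-checkpoint-1"

#' Checkpoint a simulation state
#'
#' Serialises a complete simulation state, including the random stream, so
#' that a resumed run reproduces the uninterrupted trajectory bit for bit.
#'
#' @param sim A \code{plaque_sim} object (its final state is saved) or a
#'   raw state list.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
checkpoint_sim <- function(sim, path) {
  st <- if (inherits(sim, "plaque_sim")) sim$final else sim
  if (is.null(st$rng)) st$rng <- get(".Random.seed", envir = globalenv())
  saveRDS(list(version = .CHECKPOINT_VERSION, state = st), path)
  invisible(path)
}

#' Restore a checkpointed simulation state
#'
#' @param path File written by [checkpoint_sim()].
#' @return The saved state, suitable for \code{plaque_sim(resume = )}.
#' @export
restore_sim <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$version, .CHECKPOINT_VERSION)) {
    stop("checkpoint version mismatch or corrupt file: ", path,
         call. = FALSE)
  }
  obj$state
}
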