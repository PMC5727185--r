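#' Minimum enamel-surface pH over a measurement window
#'
#' The cariogenicity metric: the minimum, over a time window containing at
#' least one glucose pulse, of the pH averaged over the bottom layer of
#' grid cells (adjacent to the enamel). Values below the critical pH 5.5
#' indicate expected net enamel demineralisation.
#'
#' @param sim A \code{plaque_sim} object or its trajectory data frame.
#' @param window Numeric \code{c(t0, t1)}, hours; defaults to the whole
#'   trajectory.
#' @return Minimum enamel pH; attribute \code{cariogenic} is \code{TRUE}
#'   when it falls below 5.5.
#' @export
min_enamel_ph <- function(sim, window = NULL) {
  traj <- if (inherits(sim, "plaque_sim")) sim$trajectory else sim
  if (is.null(window)) window <- range(traj$t)
  rows <- traj$t >= window[1] - 1e-9 & traj$t <= window[2] + 1e-9
  if (!any(rows)) stop("window contains no trajectory samples", call. = FALSE)
  if (!any(traj$pulse[rows] > 0)) {
    stop("measurement window must contain at least one glucose pulse",
         call. = FALSE)
  }
  v <- min(traj$enamel_pH[rows])
  attr(v, "cariogenic") <- v < 5.5
  v
}

#' Aciduric fraction of the community
#'
#' \code{N_A / N_total} at the trajectory sample nearest to time \code{t}.
#'
#' @param sim A \code{plaque_sim} object or trajectory data frame.
#' @param t Time, h; defaults to the final sample.
#' @return Fraction in [0, 1]; \code{NA} with a warning if the population
#'   is extinct at that sample.
#' @export
composition <- function(sim, t = NULL) {
  traj <- if (inherits(sim, "plaque_sim")) sim$trajectory else sim
  i <- if (is.null(t)) nrow(traj) else which.min(abs(traj$t - t))
  if (traj$N_total[i] == 0) {
    warning("population extinct: composition undefined", call. = FALSE)
    return(NA_real_)
  }
  traj$N_A[i] / traj$N_total[i]
}

#' Depth profiles of glucose, pH and community composition
#'
#' Laterally averaged profiles as a function of distance z from the enamel,
#' from a simulation's final state or a stored snapshot. Field values are
#' averaged over the grid cells whose centres fall in each bin; the
#' aciduric fraction comes from particle centres. Bins containing no
#' particles report \code{NA}, not zero. Intended to be taken during a
#' glucose pulse.
#'
#' @param sim A \code{plaque_sim} object, or a state list with \code{pop}
#'   and \code{fields}.
#' @param params,n_bins Parameters and number of z bins (default 25).
#' @return Data frame with \code{z} (bin centres, um), \code{glucose}
#'   (g/L), \code{pH}, \code{fraction_A}, \code{n_particles}.
#' @export
depth_profiles <- function(sim, params = NULL, n_bins = 25) {
  if (inherits(sim, "plaque_sim")) {
    state <- sim$final; params <- sim$params
  } else {
    state <- sim
    if (is.null(params)) stop("params required for a raw state", call. = FALSE)
  }
  grid <- make_grid(params)
  zmax <- grid$nz * grid$spacing
  edges <- seq(0, zmax, length.out = n_bins + 1)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  cell_z <- rep((seq_len(grid$nz) - 0.5) * grid$spacing,
                each = grid$nx * grid$ny)
  bin_cell <- pmin(pmax(findInterval(cell_z, edges, rightmost.closed = TRUE),
                        1L), n_bins)
  gl <- tapply(as.vector(state$fields$glucose), bin_cell, mean)
  la <- tapply(as.vector(state$fields$lactate), bin_cell, mean)
  out <- data.frame(z = centres, glucose = NA_real_, pH = NA_real_,
                    fraction_A = NA_real_, n_particles = 0L)
  out$glucose[as.integer(names(gl))] <- as.numeric(gl)
  out$pH[as.integer(names(la))] <- ph_from_lactate(pmax(as.numeric(la), 0),
                                                   params)
  pop <- state$pop
  if (nrow(pop) > 0) {
    bin_p <- pmin(pmax(findInterval(pop$z, edges, rightmost.closed = TRUE),
                       1L), n_bins)
    cnt <- tapply(rep(1L, nrow(pop)), bin_p, sum)
    fa <- tapply(pop$type == "A", bin_p, mean)
    out$n_particles[as.integer(names(cnt))] <- as.integer(cnt)
    out$fraction_A[as.integer(names(fa))] <- as.numeric(fa)
  }
  out
}

#' Frequency-by-amount sweep with replicates
#'
#' Runs the simulator over a grid of (total daily amount, pulse frequency)
#' combinations with \code{replicates} seeds per point (replicate r uses
#' seed \code{base_seed + r - 1}), and measures for each run the minimum
#' enamel pH over the final measurement window (the last inter-pulse
#' period, which contains exactly one pulse) and the terminal aciduric
#' fraction. A replicate that aborts is flagged (NA) and the others kept.
#'
#' @param totals Total daily amounts, g/L/d.
#' @param frequencies Pulses per day.
#' @param days Simulated duration per run, days.
#' @param replicates Replicates per grid point (standard errors need >= 2).
#' @param base_seed Base seed.
#' @param params Parameters (see [preset_params()]).
#' @param pulse_minutes Pulse duration, minutes.
#' @return Object of class \code{plaque_sweep}: list with \code{replicates}
#'   (long data frame: total, frequency, replicate, seed, min_pH,
#'   fraction_A) and \code{summary} (per grid point: means, standard errors
#'   \code{sd/sqrt(n)}, n).
#' @export
run_sweep <- function(totals, frequencies, days, replicates = 5,
                      base_seed = 1, params = plaque_params(),
                      pulse_minutes = 15) {
  rows <- list()
  for (total in totals) {
    for (freq in frequencies) {
      sched <- intake_schedule(total, freq, pulse_minutes)
      period <- 24 / freq
      for (r in seq_len(replicates)) {
        seed <- base_seed + r - 1
        res <- tryCatch({
          sim <- plaque_sim(sched, params, days = days, seed = seed)
          t_end <- max(sim$trajectory$t)
          win <- c(max(0, t_end - period), t_end)
          c(min_pH = as.numeric(min_enamel_ph(sim, win)),
            fraction_A = composition(sim))
        }, error = function(e) c(min_pH = NA_real_, fraction_A = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          total = total, frequency = freq, replicate = r, seed = seed,
          min_pH = res[["min_pH"]], fraction_A = res[["fraction_A"]])
      }
    }
  }
  reps <- do.call(rbind, rows)
  out <- list(replicates = reps, summary = summarise_sweep(reps))
  class(out) <- "plaque_sweep"
  out
}

summarise_sweep <- function(reps) {
  key <- interaction(reps$total, reps$frequency, drop = TRUE)
  agg <- lapply(split(reps, key), function(d) {
    ok <- is.finite(d$min_pH)
    n <- sum(ok)
    se <- function(v) if (n >= 2) stats::sd(v[ok]) / sqrt(n) else NA_real_
    data.frame(total = d$total[1], frequency = d$frequency[1], n = n,
               min_pH = mean(d$min_pH[ok]), min_pH_se = se(d$min_pH),
               fraction_A = mean(d$fraction_A[ok]),
               fraction_A_se = se(d$fraction_A))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$total, out$frequency), ]
  rownames(out) <- NULL
  out
}

#' Write / read a sweep's replicate table as CSV
#'
#' Round-trips exactly: \code{read_sweep_csv(write_sweep_csv(x, p))}
#' rebuilds the same replicate table and summary.
#'
#' @param sweep A \code{plaque_sweep} object.
#' @param path CSV path.
#' @return \code{path} invisibly / the restored \code{plaque_sweep}.
#' @export
write_sweep_csv <- function(sweep, path) {
  d <- sweep$replicates
  for (nm in names(d)) {
    if (is.double(d[[nm]])) d[[nm]] <- sprintf("%.17g", d[[nm]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  reps <- utils::read.csv(path)
  out <- list(replicates = reps, summary = summarise_sweep(reps))
  class(out) <- "plaque_sweep"
  out
}

#' Critical intake frequency
#'
#' For one total daily amount, the frequency at which the minimum enamel pH
#' first crosses the critical value 5.5 (linear interpolation between the
#' two bracketing frequencies). Returns \code{"none"} when the row never
#' crosses: either never cariogenic (all pH above 5.5) or always cariogenic
#' (all below). With multiple crossings the first is returned with a
#' warning.
#'
#' @param sweep A \code{plaque_sweep}, its summary data frame, or any data
#'   frame with \code{frequency} and \code{min_pH}.
#' @param total Total amount selecting the row when a full sweep is given.
#' @param threshold Critical pH (default 5.5).
#' @return Interpolated frequency (numeric), or the string \code{"none"}.
#' @export
critical_frequency <- function(sweep, total = NULL, threshold = 5.5) {
  d <- if (inherits(sweep, "plaque_sweep")) sweep$summary else sweep
  if (!is.null(total)) d <- d[d$total == total, , drop = FALSE]
  d <- d[order(d$frequency), ]
  if (nrow(d) < 2) stop("need at least two frequencies", call. = FALSE)
  ph <- d$min_pH; f <- d$frequency
  above <- ph > threshold
  cross <- which(above[-length(ph)] & !above[-1])
  if (length(cross) == 0L) return("none")
  if (length(cross) > 1L) {
    warning("multiple crossings of the critical pH; returning the first",
            call. = FALSE)
  }
  i <- cross[1]
  f[i] + (threshold - ph[i]) * (f[i + 1] - f[i]) / (ph[i + 1] - ph[i])
}

#' Acid-adaptation calibration protocol
#'
#' The well-mixed, single-particle protocol used to calibrate the
#' adaptation rates against planktonic experiments: hold the environmental
#' pH at a controlled low value for a set duration while the particle's
#' acidity optimum relaxes towards it (death disabled), restore pH 7, and
#' report the rate of acid production immediately afterwards relative to an
#' unadapted control. Substrate saturation cancels in the ratio, which
#' reduces to the ratio of pH-inhibition factors at pH 7 between the
#' adapted and initial optima.
#'
#' @param low_pH The held pH.
#' @param duration_h Exposure duration, h.
#' @param M Adaptation rate, 1/h.
#' @param type \code{"A"} or \code{"NA"}.
#' @param params Parameters (provides the initial optima).
#' @return Ratio of post-exposure to control acid production rate.
#' @export
adaptation_calibration <- function(low_pH, duration_h, M, type = "NA",
                                   params = plaque_params()) {
  stopifnot(type %in% c("A", "NA"), duration_h >= 0, M >= 0)
  p2 <- params
  p2$M_A <- M; p2$M_NA <- M
  K0 <- if (type == "A") params$K_acid_A0 else params$K_acid_NA0
  pop <- data.frame(id = 1L, type = type, x = 0, y = 0, z = 0,
                    mass = params$m_max / 2, eps = 0, K_acid = K0,
                    stringsAsFactors = FALSE)
  class(pop) <- c("plaque_population", "data.frame")
  H_low <- 10^(-low_pH)
  if (duration_h > 0) pop <- adapt(pop, H_low, duration_h, p2)
  H7 <- 1e-7
  acid_inhibition(H7, pop$K_acid) / acid_inhibition(H7, K0)
}

#' Particle doubling time in the growing biofilm
#'
#' The time for a newly formed particle (at half the division mass) to grow
#' back to the division mass, estimated from the population-mean specific
#' growth rate recorded along the trajectory:
#' \code{ln(2) / mean(growth_rate)} over the requested window.
#'
#' @param sim A \code{plaque_sim} object or trajectory data frame.
#' @param window Optional \code{c(t0, t1)}, hours; defaults to the whole
#'   trajectory.
#' @return Estimated doubling time, h.
#' @export
doubling_time <- function(sim, window = NULL) {
  traj <- if (inherits(sim, "plaque_sim")) sim$trajectory else sim
  if (is.null(window)) window <- range(traj$t)
  rows <- traj$t >= window[1] - 1e-9 & traj$t <= window[2] + 1e-9
  g <- traj$growth_rate[rows]
  g <- g[is.finite(g)]
  if (!length(g)) stop("no growth-rate samples in window", call. = FALSE)
  log(2) / mean(g)
}

#' Recovered inter-pulse enamel pH
#'
#' The famine-phase pH plateau: for each inter-pulse interval the enamel pH
#' is read over the final quarter of the interval (after the post-pulse
#' transient has cleared), and the minimum over intervals is returned.
#'
#' @param sim A \code{plaque_sim} object.
#' @param window Optional \code{c(t0, t1)}, hours.
#' @return Minimum recovered inter-pulse enamel pH.
#' @export
interpulse_min_ph <- function(sim, window = NULL) {
  traj <- sim$trajectory
  sched <- sim$schedule
  if (is.null(window)) window <- range(traj$t)
  period <- 24 / sched$frequency
  dur <- sched$pulse_minutes / 60
  phase <- (traj$t - sched$first_pulse_time) %% period
  plateau <- phase >= dur + 0.75 * (period - dur)
  rows <- plateau & traj$t >= window[1] - 1e-9 & traj$t <= window[2] + 1e-9
  if (!any(rows)) stop("no inter-pulse plateau samples in window",
                       call. = FALSE)
  min(traj$enamel_pH[rows])
}
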