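#' Glucose intake schedule
#'
#' Defines the pulsed dietary glucose supply: a total daily amount (g/L/d)
#' delivered as equally spaced square pulses of fixed duration. The g/L/d
#' unit is operational: the pulse concentration is whatever value, held for
#' the pulse duration and repeated \code{frequency} times per day, delivers
#' the stated total of concentration x pulse-hours per day. Doubling the
#' frequency at fixed total therefore halves the concentration of each
#' pulse.
#'
#' @param total_amount Total daily glucose, g/L/d.
#' @param frequency Pulses per day; need not be an integer (the schedule is
#'   periodic with period \code{24 / frequency} hours).
#' @param pulse_minutes Duration of each pulse, minutes (default 15).
#' @param first_pulse_time Start of the first pulse, hours after t = 0.
#' @return An object of class \code{intake_schedule}.
#' @examples
#' s <- intake_schedule(15, 4)        # 15 g/L/d in four 15-minute pulses
#' pulse_concentration(s)             # 15 g/L during each pulse
#' @export
intake_schedule <- function(total_amount, frequency, pulse_minutes = 15,
                            first_pulse_time = 0) {
  if (!is.numeric(total_amount) || total_amount < 0 || !is.finite(total_amount)) {
    stop("total_amount must be a non-negative number (g/L/d)", call. = FALSE)
  }
  if (!is.numeric(frequency) || frequency <= 0 || !is.finite(frequency)) {
    stop("frequency must be a positive number of pulses per day", call. = FALSE)
  }
  if (!is.numeric(pulse_minutes) || pulse_minutes <= 0) {
    stop("pulse_minutes must be positive", call. = FALSE)
  }
  if (first_pulse_time < 0) stop("first_pulse_time must be >= 0", call. = FALSE)
  if (frequency * pulse_minutes / 60 > 24 + 1e-9) {
    stop("pulses overlap: frequency x pulse duration exceeds 24 h/day",
         call. = FALSE)
  }
  s <- list(total_amount = total_amount, frequency = frequency,
            pulse_minutes = pulse_minutes,
            first_pulse_time = first_pulse_time)
  class(s) <- "intake_schedule"
  s
}

#' Concentration imposed during each pulse
#'
#' The boundary glucose concentration during a pulse, chosen so that the
#' schedule delivers its total daily amount of concentration x pulse-hours
#' per day:
#' \deqn{c = \mathrm{total} / (\mathrm{frequency} \times
#'   \mathrm{duration_h}),}
#' which for 15-minute pulses reduces to \code{4 * total / frequency}:
#' doubling the frequency at fixed total halves each pulse.
#'
#' @param schedule An [intake_schedule()].
#' @return Pulse concentration, g/L.
#' @export
pulse_concentration <- function(schedule) {
  stopifnot(inherits(schedule, "intake_schedule"))
  dur_h <- schedule$pulse_minutes / 60
  schedule$total_amount / (schedule$frequency * dur_h)
}

#' Background polyglucose concentration
#'
#' Stored polyglucose is modelled as a constant, uniform low-level carbon
#' source equal to a fixed fraction (default 1\%) of the total daily intake.
#' It is available at all times and is never depleted.
#'
#' @param params A [plaque_params()] object.
#' @param schedule An [intake_schedule()].
#' @return Polyglucose concentration, g/L.
#' @export
polyglucose_concentration <- function(params, schedule) {
  stopifnot(inherits(params, "plaque_params"),
            inherits(schedule, "intake_schedule"))
  params$polyGl_fraction * schedule$total_amount
}

#' Glucose boundary condition at the saliva-air interface
#'
#' The Dirichlet value imposed at the top of the saliva layer: the pulse
#' concentration while a pulse is active, zero otherwise. The schedule is
#' exactly periodic with period \code{24 / frequency} hours; the first pulse
#' opens at \code{first_pulse_time}.
#'
#' @param schedule An [intake_schedule()].
#' @param t Time(s), hours; must be non-negative. Vectorised.
#' @return Boundary concentration(s), g/L.
#' @export
boundary_glucose <- function(schedule, t) {
  stopifnot(inherits(schedule, "intake_schedule"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  period <- 24 / schedule$frequency
  dur_h <- schedule$pulse_minutes / 60
  phase <- (t - schedule$first_pulse_time) %% period
  on <- (t >= schedule$first_pulse_time) & (phase < dur_h - 1e-12)
  ifelse(on, pulse_concentration(schedule), 0)
}

#' Is a pulse active at time t?
#' @inheritParams boundary_glucose
#' @return Logical vector.
#' @export
pulse_active <- function(schedule, t) boundary_glucose(schedule, t) > 0

#' Equivalent peak for exponentially-decaying intake models
#'
#' Square-pulse concentrations should be multiplied by 3.0 when compared to
#' the peak values of models that feed an exponentially decaying
#' concentration delivering the same net amount. Reporting convenience only;
#' has no effect on the dynamics.
#'
#' @param c_pulse Square-pulse concentration(s), g/L (non-negative).
#' @return Equivalent exponential-model peak concentration(s), g/L.
#' @export
exp_decay_equivalent <- function(c_pulse) {
  if (any(c_pulse < 0)) stop("c_pulse must be non-negative", call. = FALSE)
  3.0 * c_pulse
}

#' @export
print.intake_schedule <- function(x, ...) {
  cat(sprintf(
    "Intake schedule: %g g/L/d in %g x %g-min pulses/day (%g g/L per pulse)\n",
    x$total_amount, x$frequency, x$pulse_minutes, pulse_concentration(x)))
  invisible(x)
}
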