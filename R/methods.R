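#' @export
print.plaque_sim <- function(x, ...) {
  cat("Plaque biofilm simulation\n")
  print(x$schedule)
  cat(sprintf("  %g simulated days, seed %d, status: %s\n",
              x$days, as.integer(x$seed), x$status))
  n <- nrow(x$trajectory)
  last <- x$trajectory[n, ]
  cat(sprintf("  final: t = %.2f h, N_total = %d, aciduric fraction %.3f\n",
              last$t, as.integer(last$N_total),
              if (last$N_total > 0) last$N_A / last$N_total else NA))
  cat(sprintf("  enamel pH at last sample: %.3f\n", last$enamel_pH))
  invisible(x)
}

#' Summarise a plaque simulation
#'
#' Reports the terminal composition, the minimum enamel pH over the final
#' measurement window (one inter-pulse period), and whether the biofilm
#' classifies as cariogenic (minimum enamel pH below 5.5).
#'
#' @param object A \code{plaque_sim}.
#' @param ... Unused.
#' @return A list of class \code{summary.plaque_sim}.
#' @export
summary.plaque_sim <- function(object, ...) {
  traj <- object$trajectory
  t_end <- max(traj$t)
  period <- 24 / object$schedule$frequency
  min_ph <- if (t_end > 0 && any(traj$pulse > 0)) {
    win_lo <- max(0, t_end - period)
    tryCatch(as.numeric(min_enamel_ph(object, c(win_lo, t_end))),
             error = function(e) NA_real_)
  } else NA_real_
  out <- list(schedule = object$schedule, days = object$days,
              seed = object$seed, status = object$status,
              N_total = traj$N_total[nrow(traj)],
              fraction_A = composition(object),
              min_enamel_pH = min_ph,
              cariogenic = !is.na(min_ph) && min_ph < 5.5)
  class(out) <- "summary.plaque_sim"
  out
}

#' @export
print.summary.plaque_sim <- function(x, ...) {
  print(x$schedule)
  cat(sprintf("  %g days, seed %d, %s\n", x$days, as.integer(x$seed),
              x$status))
  cat(sprintf("  N_total = %d, aciduric fraction = %.3f\n",
              as.integer(x$N_total), x$fraction_A))
  if (!is.na(x$min_enamel_pH)) {
    cat(sprintf("  min enamel pH (final window) = %.3f -> %s\n",
                x$min_enamel_pH,
                if (x$cariogenic) "cariogenic (pH < 5.5)" else
                  "not cariogenic"))
  }
  invisible(x)
}

#' @export
as.data.frame.plaque_sim <- function(x, ...) x$trajectory

#' Plot a plaque simulation trajectory
#'
#' Two stacked panels: the aciduric fraction \code{N_A / N_total} and the
#' enamel-surface pH against time, with pulse windows shaded and the
#' critical pH 5.5 marked.
#'
#' @param x A \code{plaque_sim}.
#' @param ... Passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.plaque_sim <- function(x, ...) {
  traj <- x$trajectory
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  frac <- ifelse(traj$N_total > 0, traj$N_A / traj$N_total, NA)
  graphics::plot(traj$t, frac, type = "l", xlab = "time (h)",
                 ylab = expression(N[A] / N[total]), ...)
  shade_pulses(x$schedule, range(traj$t))
  graphics::lines(traj$t, frac)
  graphics::plot(traj$t, traj$enamel_pH, type = "l", xlab = "time (h)",
                 ylab = "enamel pH", ...)
  shade_pulses(x$schedule, range(traj$t))
  graphics::lines(traj$t, traj$enamel_pH)
  graphics::abline(h = 5.5, lty = 2, col = "red")
  invisible(x)
}

shade_pulses <- function(schedule, tr) {
  period <- 24 / schedule$frequency
  dur <- schedule$pulse_minutes / 60
  starts <- seq(schedule$first_pulse_time, tr[2], by = period)
  usr <- graphics::par("usr")
  for (s in starts) {
    graphics::rect(s, usr[3], min(s + dur, tr[2]), usr[4],
                   col = grDevices::adjustcolor("grey", 0.4), border = NA)
  }
}

#' @export
print.plaque_sweep <- function(x, ...) {
  cat("Frequency x amount sweep (minimum enamel pH, aciduric fraction)\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Plot a sweep: minimum pH versus intake frequency
#'
#' One line per total daily amount, the critical pH 5.5 dashed.
#'
#' @param x A \code{plaque_sweep}.
#' @param ... Passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.plaque_sweep <- function(x, ...) {
  s <- x$summary
  totals <- sort(unique(s$total))
  freqs <- sort(unique(s$frequency))
  m <- sapply(totals, function(tt) {
    d <- s[s$total == tt, ]
    d$min_pH[match(freqs, d$frequency)]
  })
  graphics::matplot(freqs, m, type = "b", pch = seq_along(totals),
                    xlab = "pulses per day", ylab = "minimum enamel pH",
                    ...)
  graphics::abline(h = 5.5, lty = 2, col = "red")
  graphics::legend("bottomleft", legend = paste(totals, "g/L/d"),
                   pch = seq_along(totals), col = seq_along(totals),
                   bty = "n")
  invisible(x)
}
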