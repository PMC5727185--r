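#' pH of the medium for a given total lactate concentration
#'
#' Solves the proton condition for a medium that rests at
#' \code{baseline_pH} when no lactate is present and contains a monoprotic
#' buffer (total \code{buffer_conc}, pKa \code{buffer_pKa}) plus lactic acid
#' (pKa \code{lactic_pKa}) at the given total concentration. The background
#' cation excess is fixed by requiring pH = baseline at zero lactate;
#' charge balance is then
#' \deqn{[H^+] + C_0 = [OH^-] + [B^-] + [Lac^-],}
#' with the buffer and lactate anions given by their dissociation
#' equilibria. The root in \eqn{[H^+]} is bracketed on \eqn{[10^{-14}, 1]}.
#' pH is strictly decreasing in lactate and equals the baseline at zero.
#'
#' @param lactate Total lactate concentration(s), mol/L (vectorised).
#' @param params A [plaque_params()] carrying the chemistry constants, or a
#'   list with fields \code{baseline_pH}, \code{buffer_conc},
#'   \code{buffer_pKa}, \code{lactic_pKa}.
#' @param tol Root-finding tolerance on \eqn{[H^+]} (relative).
#' @return pH value(s).
#' @export
ph_from_lactate <- function(lactate, params, tol = 1e-12) {
  if (any(lactate < 0)) stop("lactate must be non-negative", call. = FALSE)
  Kw <- 1e-14
  Kb <- 10^(-params$buffer_pKa)
  Kl <- 10^(-params$lactic_pKa)
  B <- params$buffer_conc
  H0 <- 10^(-params$baseline_pH)
  # background cation excess making the lactate-free medium sit at baseline
  C0 <- Kw / H0 + B * Kb / (Kb + H0) - H0
  residual <- function(H, L) {
    H + C0 - Kw / H - B * Kb / (Kb + H) - L * Kl / (Kl + H)
  }
  vapply(lactate, function(L) {
    if (L == 0) return(params$baseline_pH)
    lo <- 1e-14; hi <- 1
    if (residual(lo, L) * residual(hi, L) > 0) {
      stop("chemistry parameters do not bracket a root on [1e-14, 1]",
           call. = FALSE)
    }
    r <- stats::uniroot(residual, c(lo, hi), L = L, tol = tol * H0,
                        maxiter = 200)
    -log10(r$root)
  }, numeric(1))
}

# Monotone interpolation table lactate -> pH, built once per run from the
# exact solver; used on the hot path (per-cell / per-particle conversion).
# Linear in log10(lactate) between knots; exact at 0.
build_ph_lookup <- function(params, l_max = 2, n = 600) {
  l_lo <- 1e-9
  knots <- 10^seq(log10(l_lo), log10(l_max), length.out = n)
  ph <- ph_from_lactate(knots, params)
  list(log_knots = log10(knots), ph = ph, l_lo = l_lo, l_max = l_max,
       baseline = params$baseline_pH)
}

ph_lookup_eval <- function(lookup, lactate) {
  ph <- rep(lookup$baseline, length(lactate))
  idx <- lactate > lookup$l_lo
  if (any(idx)) {
    x <- pmin(lactate[idx], lookup$l_max)
    ph[idx] <- stats::approx(lookup$log_knots, lookup$ph, xout = log10(x),
                             rule = 2)$y
  }
  ph
}
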