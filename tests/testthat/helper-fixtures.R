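# Shared fixtures: small parameter sets and hand-rolled oracles.

desk_params <- function(...) preset_params("desk", ...)

# single 1 x 1 x 3 column of 10 um cells: hand-checkable diffusion
column_params <- function(...) {
  plaque_params(box_x = 10, box_y = 10, h_plaque = 20, h_saliva = 10,
                grid_spacing = 10, ...)
}

# explicit forward-Euler step of the same discrete operator used by the
# solver: Dirichlet ghost at the top face, no-flux enamel, periodic x/y
explicit_step <- function(conc, grid, D_m2s, dt, source, bc) {
  a <- dt * D_m2s * 3.6e15 / grid$spacing^2
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  arr <- array(conc, c(nx, ny, nz))
  lap <- array(0, c(nx, ny, nz))
  sh <- function(a3, d, dim) {
    # periodic shift along x/y
    idx <- list(seq_len(nx), seq_len(ny), seq_len(nz))
    idx[[dim]] <- ((idx[[dim]] - 1 + d) %% c(nx, ny, nz)[dim]) + 1
    a3[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  lap <- sh(arr, 1, 1) + sh(arr, -1, 1) + sh(arr, 1, 2) + sh(arr, -1, 2) -
    4 * arr
  for (k in seq_len(nz)) {
    up <- if (k < nz) arr[, , k + 1] else 2 * bc - arr[, , nz]
    dn <- if (k > 1) arr[, , k - 1] else arr[, , 1]  # no-flux mirror
    lap[, , k] <- lap[, , k] + up + dn - 2 * arr[, , k]
  }
  arr + a * lap + dt * array(source, c(nx, ny, nz))
}

# independent bisection on the charge-balance residual (re-derived here)
ph_bisect_oracle <- function(lactate, params, iters = 60) {
  Kw <- 1e-14
  Kb <- 10^(-params$buffer_pKa)
  Kl <- 10^(-params$lactic_pKa)
  B <- params$buffer_conc
  H0 <- 10^(-params$baseline_pH)
  C0 <- Kw / H0 + B * Kb / (Kb + H0) - H0
  f <- function(H) H + C0 - Kw / H - B * Kb / (Kb + H) -
    lactate * Kl / (Kl + H)
  lo <- 1e-14; hi <- 1
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)  # bisect in log space
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  -log10(sqrt(lo * hi))
}

# short cached desk run shared by several acceptance checks
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# single-particle population of a given type
init_pop_of <- function(type, params) {
  K0 <- if (type == "A") params$K_acid_A0 else params$K_acid_NA0
  pop <- data.frame(id = 1L, type = type, x = 20, y = 20, z = 20,
                    mass = params$m_max / 2, eps = 0, K_acid = K0,
                    stringsAsFactors = FALSE)
  attr(pop, "next_id") <- 2L
  class(pop) <- c("plaque_population", "data.frame")
  pop
}
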