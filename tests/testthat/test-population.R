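mk_pop <- function(type = "A", mass = 1, K_acid = NULL, n = 1,
                   params = plaque_params()) {
  K0 <- if (is.null(K_acid)) {
    ifelse(type == "A", params$K_acid_A0, params$K_acid_NA0)
  } else K_acid
  pop <- data.frame(id = seq_len(n), type = rep(type, length.out = n),
                    x = rep(10, n), y = rep(10, n), z = rep(10, n),
                    mass = rep(mass, length.out = n), eps = rep(0, n),
                    K_acid = rep(K0, length.out = n),
                    stringsAsFactors = FALSE)
  attr(pop, "next_id") <- n + 1L
  class(pop) <- c("plaque_population", "data.frame")
  pop
}

test_that("glycolysis rate reproduces the Monod x pH-inhibition kinetics", {
  p <- plaque_params()
  a <- mk_pop("A", mass = 1)
  # saturating identity: Gl = K_Gl and H = K_acid gives mu_max/2
  expect_equal(glycolysis_rate(a, Gl = p$K_Gl_A, H = p$K_acid_A0, p), 2.5)
  expect_equal(glycolysis_rate(a, Gl = 0, H = 1e-6, p), 0)
  # acid factor is exactly 1 at H == K, for any K
  for (K in c(1e-7, 1e-5, 3.2e-6)) {
    expect_equal(acid_inhibition(K, K), 1)
  }
  expect_error(acid_inhibition(0, 1e-5), "positive")
})

test_that("acid factor is bounded by 1 and the rate is monotone in glucose", {
  set.seed(11)
  p <- plaque_params()
  H <- 10^runif(200, -9, -2)
  K <- 10^runif(200, -9, -2)
  f <- acid_inhibition(H, K)
  expect_true(all(f <= 1 + 1e-12))
  expect_true(all(f[abs(log10(H) - log10(K)) > 1e-6] < 1))
  a <- mk_pop("NA", mass = 1)
  gl <- sort(runif(50, 0, 30))
  r <- glycolysis_rate(a[rep(1, 50), ], Gl = gl, H = 1e-7, p)
  expect_true(all(diff(r) > 0))
})

test_that("dual-substrate rates add and respect stoichiometry", {
  p <- plaque_params()
  a <- mk_pop("A", mass = 1)
  z <- total_rates(a, intakeGl = 0, polyGl = 0, H = 1e-5, p)
  expect_equal(unlist(z), c(glucose_uptake = 0, polyGl_uptake = 0,
                            acid_production = 0, glycolysis = 0))
  # polyglucose alone drives acid production between pulses
  z2 <- total_rates(a, intakeGl = 0, polyGl = 0.2, H = 1e-5, p)
  expect_gt(z2$acid_production, 0)
  # equal substrate levels: total is exactly twice the single-source rate
  z3 <- total_rates(a, intakeGl = p$K_Gl_A, polyGl = p$K_Gl_A, H = 1e-5, p)
  expect_equal(z3$glycolysis, 2 * z3$glucose_uptake)
  expect_equal(z3$acid_production,
               p$lactate_per_glucose * z3$glycolysis / p$glucose_mw)
})

test_that("growth applies the yields and the EPS/growth ratio", {
  p <- plaque_params()
  a <- mk_pop("A", mass = 1)
  g <- grow(a, rate = 2.5, dt = 1, p)
  expect_equal(g$mass, 1 + 0.25)
  expect_equal(g$eps / (g$mass - 1), p$yield_EPS / p$yield_growth)
  expect_equal(p$yield_EPS / p$yield_growth, 0.4)
  expect_equal(grow(a, rate = 0, dt = 1, p)$mass, a$mass)
})

test_that("saturated growth doubles at the closed-form rate", {
  p <- plaque_params()
  a <- mk_pop("A", mass = 1)
  dt <- 1e-3
  t <- 0
  while (a$mass < 2) {
    r <- glycolysis_rate(a, Gl = 1e6, H = p$K_acid_A0, p)
    a <- grow(a, r, dt, p)
    t <- t + dt
  }
  expect_equal(t, log(2) / (p$yield_growth * p$mu_max), tolerance = 5e-3)
})

test_that("division conserves mass, resets adaptation, touches nothing else", {
  p <- plaque_params()
  below <- mk_pop("A", mass = p$m_max * 0.99)
  expect_identical(divide_sweep(below, p)$mass, below$mass)
  set.seed(3)
  mother <- mk_pop("NA", mass = p$m_max, K_acid = 5e-6)  # adapted
  mother$eps <- 2e-11
  kids <- divide_sweep(mother, p)
  expect_equal(nrow(kids), 2L)
  expect_equal(sum(kids$mass), p$m_max)
  expect_equal(sum(kids$eps), 2e-11)
  expect_equal(kids$K_acid, rep(p$K_acid_NA0, 2))  # reversion on division
  expect_true(all(kids$mass < p$m_max))
  # daughters are tangent: centre separation equals the daughter diameter
  r_d <- particle_radius(kids$mass[1] + kids$eps[1], p$biomass_density)
  sep <- sqrt(sum((kids[1, c("x", "y", "z")] - kids[2, c("x", "y", "z")])^2))
  expect_equal(as.numeric(sep), 2 * r_d, tolerance = 1e-8)
  # no daughter below the enamel plane
  expect_true(all(kids$z >= r_d - 1e-12))
  expect_identical(divide_sweep(mk_pop(n = 0), p), mk_pop(n = 0))
})

test_that("death hazard follows the tabulated neutral-pH rates", {
  p <- plaque_params()
  expect_equal(death_hazard(mk_pop("A"), H = 1e-7, p), 3e-3)
  expect_equal(death_hazard(mk_pop("NA"), H = 1e-7, p), 6e-3)
  expect_equal(death_hazard(mk_pop("NA"), H = 1e-6, p), 6e-2)
  expect_equal(death_hazard(mk_pop("A"), H = 1e-12, p), 3e-8)
  # stochastic sweep kills at the expected rate
  set.seed(9)
  big <- mk_pop("NA", n = 4000)
  out <- apply_death(big, H = 1e-4, dt = 0.5, p)  # hazard 6/h for 30 min
  p_surv <- exp(-3)
  expect_equal(nrow(out) / 4000, p_surv, tolerance = 0.2)
})

test_that("adaptation relaxes exactly and is reversible at M = 0", {
  p <- plaque_params(M_A = 1e-2, M_NA = 1e-2)
  a <- mk_pop("A", K_acid = 1e-7)
  out <- adapt(a, H = 1e-5, dt = 1, p)
  expect_equal(out$K_acid, 1e-5 + (1e-7 - 1e-5) * exp(-0.01))
  # brute-force RK4 integration of dK/dt = M (H - K)
  K <- 1e-7; M <- 1e-2; H <- 1e-5; dt <- 1e-3
  for (i in seq_len(1000)) {
    f <- function(k) M * (H - k)
    k1 <- f(K); k2 <- f(K + dt * k1 / 2); k3 <- f(K + dt * k2 / 2)
    k4 <- f(K + dt * k3)
    K <- K + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  expect_lt(abs(out$K_acid - K), 1e-10)
  # fixed point and disabled adaptation
  expect_equal(adapt(a, H = 1e-7, dt = 5, p)$K_acid, 1e-7)
  p0 <- plaque_params(M_A = 0, M_NA = 0)
  expect_equal(adapt(a, H = 1e-3, dt = 100, p0)$K_acid, 1e-7)
})

test_that("pruning removes exactly the particles above the biofilm height", {
  p <- plaque_params()
  pop <- mk_pop("A", n = 5)
  pop$z <- c(10, 249.9, 250, 250.0001, 400)
  out <- prune_above(pop, p$h_plaque)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$z <= 250))
  expect_equal(nrow(prune_above(mk_pop(n = 0), 250)), 0L)
  expect_identical(prune_above(pop[pop$z < 100, ], 250)$z, 10)
})

test_that("initial population is a lattice with the right composition", {
  p <- desk_params()
  set.seed(5)
  pop <- init_population(p)
  expect_equal(nrow(pop), 1000L)  # 10 x 10 x 10 lattice of 10 um aggregates
  expect_true(all(pop$z <= p$h_plaque))
  expect_equal(unique(pop$mass), p$m_max / 2)
  frac <- mean(pop$type == "A")
  expect_equal(frac, 0.05, tolerance = 0.5)  # binomial n = 1000
  expect_true(all(pop$K_acid[pop$type == "A"] == p$K_acid_A0))
  expect_true(all(pop$K_acid[pop$type == "NA"] == p$K_acid_NA0))
  # determinism under a fixed seed
  set.seed(5)
  expect_identical(init_population(p), pop)
  # edge compositions
  set.seed(1)
  expect_equal(pop_counts(init_population(desk_params(init_fraction_A = 0)))$N_A, 0L)
  cnt <- pop_counts(pop)
  expect_equal(cnt$N_total, cnt$N_A + cnt$N_NA)
})
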