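synthetic_traj <- function() {
  data.frame(
    t = seq(0, 10, by = 0.5),
    pulse = rep(c(1, rep(0, 7)), length.out = 21),
    N_A = c(rep(5, 10), 8, rep(10, 10)),
    N_total = rep(100, 21),
    enamel_pH = c(rep(7, 8), 5.2, rep(6.8, 12)),
    mean_pH = 6.9, total_glucose = 0, total_lactate = 0,
    clipped_glucose = 0, growth_rate = 0.07
  )
}

test_that("minimum enamel pH is the window minimum and flags cariogenicity", {
  tr <- synthetic_traj()
  v <- min_enamel_ph(tr, c(0, 10))
  expect_equal(as.numeric(v), 5.2)
  expect_true(attr(v, "cariogenic"))
  flat <- transform(tr, enamel_pH = 7)
  expect_equal(as.numeric(min_enamel_ph(flat, c(0, 10))), 7)
  expect_false(attr(min_enamel_ph(flat, c(0, 10)), "cariogenic"))
  # a window with no pulse is a contract violation
  expect_error(min_enamel_ph(tr, c(0.6, 3.4)), "pulse")
})

test_that("composition counts aciduric particles", {
  tr <- synthetic_traj()
  expect_equal(composition(tr, t = 0), 0.05)
  expect_equal(composition(tr, t = 10), 0.10)
  all_na <- transform(tr, N_A = 0)
  expect_equal(composition(all_na, t = 3), 0)
  all_a <- transform(tr, N_A = tr$N_total)
  expect_equal(composition(all_a, t = 3), 1)
  dead <- transform(tr, N_total = 0)
  expect_warning(v <- composition(dead, t = 1), "extinct")
  expect_true(is.na(v))
})

test_that("depth profiles average laterally and flag empty bins", {
  p <- desk_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  f$glucose[] <- 4.2
  pop <- data.frame(id = 1:4, type = c("A", "NA", "NA", "NA"),
                    x = c(10, 20, 30, 40), y = 10, z = c(5, 5, 15, 95),
                    mass = 1e-10, eps = 0, K_acid = 1e-7)
  prof <- depth_profiles(list(pop = pop, fields = f), p, n_bins = 15)
  expect_equal(nrow(prof), 15L)
  expect_equal(prof$glucose, rep(4.2, 15))        # flat field, flat profile
  expect_equal(prof$pH, rep(7, 15))
  expect_equal(prof$fraction_A[1], 0.5)           # 1 A of 2 in [0, 10)
  expect_equal(prof$fraction_A[2], 0)
  expect_true(is.na(prof$fraction_A[5]))          # empty bin flagged NA
  expect_equal(prof$n_particles[10], 1L)
})

test_that("critical frequency interpolates the first crossing of pH 5.5", {
  row <- data.frame(frequency = c(6, 7), min_pH = c(5.6, 5.4))
  expect_equal(critical_frequency(row), 6.5)
  never <- data.frame(frequency = 2:8, min_pH = seq(6.5, 5.9, by = -0.1))
  expect_identical(critical_frequency(never), "none")
  always <- data.frame(frequency = 2:8, min_pH = seq(5.4, 4.8, by = -0.1))
  expect_identical(critical_frequency(always), "none")
  wobble <- data.frame(frequency = 1:4, min_pH = c(5.8, 5.4, 5.7, 5.2))
  expect_warning(v <- critical_frequency(wobble), "multiple")
  expect_equal(v, 1 + (5.5 - 5.8) / (5.4 - 5.8))
  expect_error(critical_frequency(row[1, ]), "two frequencies")
})

test_that("sweep aggregation, standard errors and CSV round trip", {
  # deterministic miniature sweep: 1 grid point, 2 replicates
  p <- desk_params()
  sw <- run_sweep(totals = 15, frequencies = 12, days = 0.05,
                  replicates = 2, base_seed = 1, params = p)
  expect_equal(nrow(sw$replicates), 2L)
  expect_equal(sw$summary$n, 2L)
  expect_true(is.finite(sw$summary$min_pH))
  expect_equal(sw$summary$min_pH_se,
               stats::sd(sw$replicates$min_pH) / sqrt(2))
  sw2 <- run_sweep(totals = 15, frequencies = 12, days = 0.05,
                   replicates = 2, base_seed = 1, params = p)
  expect_identical(sw$replicates, sw2$replicates)
  path <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  back <- read_sweep_csv(path)
  expect_equal(back$replicates, sw$replicates)
  expect_equal(back$summary, sw$summary)
})

test_that("sweep standard error matches a bootstrap estimate", {
  set.seed(14)
  reps <- data.frame(total = 15, frequency = 6, replicate = 1:40,
                     seed = 1:40, min_pH = rnorm(40, 5.6, 0.2),
                     fraction_A = runif(40))
  s <- plaquesim:::summarise_sweep(reps)
  boot <- replicate(4000, mean(sample(reps$min_pH, replace = TRUE)))
  expect_equal(s$min_pH_se, stats::sd(boot), tolerance = 0.1)
})

test_that("adaptation calibration ratio follows the closed form", {
  p <- plaque_params()
  expect_equal(adaptation_calibration(5.5, 2, M = 0, "NA", p), 1)
  # independent closed form: K(t) = H + (K0 - H) exp(-M t), ratio of
  # inhibition factors at pH 7
  M <- 3e-2; dur <- 2; H_low <- 10^-5.5; K0 <- p$K_acid_NA0; H7 <- 1e-7
  K_t <- H_low + (K0 - H_low) * exp(-M * dur)
  fac <- function(H, K) 4 * H * K / (H + K)^2
  expect_equal(adaptation_calibration(5.5, dur, M, "NA", p),
               fac(H7, K_t) / fac(H7, K0))
  # monotone in exposure duration (NA: adapting away from pH 7 slows it)
  durs <- c(0.5, 1, 2, 4, 8)
  ratios <- sapply(durs, function(d) adaptation_calibration(5.5, d, M, "NA", p))
  expect_true(all(diff(ratios) < 0))
  # aciduric particles adapt towards pH 5.5, increasing their rate at pH 7
  ratios_A <- sapply(durs, function(d) adaptation_calibration(5.5, d, M, "A", p))
  expect_true(all(ratios_A > 1))
})

test_that("doubling time reads the recorded specific growth rate", {
  tr <- synthetic_traj()
  expect_equal(doubling_time(tr), log(2) / 0.07)
  tr$growth_rate[1] <- NA
  expect_equal(doubling_time(tr), log(2) / 0.07)
})
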