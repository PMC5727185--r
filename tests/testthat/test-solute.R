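test_that("uniform Dirichlet feeding with no uptake equilibrates the field", {
  p <- column_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  zero <- array(0, c(g$nx, g$ny, g$nz))
  for (i in 1:40) {
    f <- step_fields(f, zero, zero, dt = 0.01, bc_glucose = 7, g, p)$fields
  }
  expect_equal(as.vector(f$glucose), rep(7, 3), tolerance = 1e-6)
})

test_that("implicit step matches an explicit-Euler oracle to O(dt^2)", {
  p <- column_params(dt_field = 1)  # one substep
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  f$glucose <- array(c(1, 3, 2), c(1, 1, 3))
  sink <- array(c(0.5, 0, 0.2), c(1, 1, 3))
  err <- sapply(c(2e-7, 5e-8), function(dt) {
    implicit <- step_fields(f, sink, array(0, dim(sink)), dt = dt,
                            bc_glucose = 4, g, p)$fields$glucose
    oracle <- explicit_step(f$glucose, g, p$D_glucose, dt, -sink, bc = 4)
    max(abs(implicit - oracle))
  })
  expect_lt(err[1], 1e-3 * max(f$glucose))
  # quartering dt shrinks the implicit/explicit gap ~16x (both O(dt) schemes
  # sharing the O(dt) term; the difference is O(dt^2))
  expect_gt(err[1] / err[2], 8)
})

test_that("steady profile under a biofilm sink decreases toward the enamel", {
  p <- plaque_params(box_x = 20, box_y = 20, h_plaque = 100, h_saliva = 100,
                     grid_spacing = 10)
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  sink <- array(0, c(g$nx, g$ny, g$nz))
  sink[, , 1:10] <- 200  # uniform uptake in the biofilm layer, g/L/h
  for (i in 1:60) {
    f <- step_fields(f, sink, array(0, dim(sink)), dt = 0.02,
                     bc_glucose = 10, g, p)$fields
  }
  prof <- apply(f$glucose, 3, mean)
  expect_true(all(diff(prof) > -1e-9))     # non-increasing toward enamel
  expect_gt(prof[1], 0)                    # finite value at the surface
  expect_equal(prof[g$nz], 10, tolerance = 0.1)
})

test_that("glucose mass accounting closes each step", {
  p <- desk_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  set.seed(42)
  f$glucose <- array(runif(g$nx * g$ny * g$nz, 0, 5), c(g$nx, g$ny, g$nz))
  sink <- array(runif(g$nx * g$ny * g$nz, 0, 40), c(g$nx, g$ny, g$nz))
  res <- step_fields(f, sink, array(0, dim(sink)), dt = 1 / 60,
                     bc_glucose = 15, g, p)
  d_total <- (sum(res$fields$glucose) - sum(f$glucose)) * g$cell_volume
  expect_equal(d_total,
               res$influx_glucose - res$uptake_applied + res$clipped_glucose,
               tolerance = 1e-8)
})

test_that("an initial lactate pulse clears monotonically through the top", {
  p <- column_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  f$lactate <- array(c(0.02, 0.01, 0.005), c(1, 1, 3))
  zero <- array(0, c(1, 1, 3))
  totals <- numeric(30)
  for (i in seq_along(totals)) {
    f <- step_fields(f, zero, zero, dt = 0.002, bc_glucose = 0, g, p)$fields
    totals[i] <- sum(f$lactate)
  }
  expect_true(all(diff(totals) < 0))
  expect_lt(totals[30], 1e-6)
})

test_that("fast diffusion homogenises the domain to the boundary value", {
  p <- desk_params(D_glucose = 6.7e-10 * 1e6, D_lactate = 1e-9 * 1e6)
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  sink <- array(5, c(g$nx, g$ny, g$nz))
  for (i in 1:10) {
    f <- step_fields(f, sink, array(0, dim(sink)), dt = 0.01,
                     bc_glucose = 12, g, p)$fields
  }
  gl <- as.vector(f$glucose)
  expect_lt(max(gl) - min(gl), 0.01 * mean(gl))   # spatially uniform
  expect_equal(mean(gl), 12, tolerance = 0.01)    # pinned to the boundary
})

test_that("lactate-to-pH map is exact, monotone, and anchored at baseline", {
  p <- plaque_params()
  expect_equal(ph_from_lactate(0, p), 7)
  lac <- 10^seq(-6, -0.5, length.out = 10)
  ph <- ph_from_lactate(lac, p)
  expect_true(all(diff(ph) < 0))
  oracle <- vapply(lac, ph_bisect_oracle, numeric(1), params = p)
  expect_equal(ph, oracle, tolerance = 1e-6)
  expect_error(ph_from_lactate(-1, p), "non-negative")
  # internal lookup table agrees with the exact solver
  lk <- plaquesim:::build_ph_lookup(p)
  expect_equal(plaquesim:::ph_lookup_eval(lk, lac), ph, tolerance = 1e-4)
})

test_that("field sampling at particles is exact for the cases it must be", {
  p <- desk_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  f$glucose[] <- 3.3
  pop <- data.frame(id = 1:3, type = c("A", "NA", "A"),
                    x = c(5, 55, 99), y = c(5, 15, 42), z = c(5, 75, 149),
                    mass = 1e-10, eps = 0, K_acid = 1e-5)
  sm <- sample_at_particles(f, pop, g, p)
  expect_equal(sm$glucose, rep(3.3, 3))           # constant field
  expect_equal(sm$polyGl, rep(f$polyGl, 3))
  # cell-centre exactness for a varying field
  f$glucose <- array(seq_len(g$nx * g$ny * g$nz), c(g$nx, g$ny, g$nz))
  pc <- data.frame(id = 1, type = "A", x = 15, y = 25, z = 35,
                   mass = 1e-10, eps = 0, K_acid = 1e-5)
  expect_equal(sample_at_particles(f, pc, g, p)$glucose, f$glucose[2, 3, 4])
  # trilinear: midway between two cells along z in a z-linear field
  pt <- desk_params(sample_mode = "trilinear")
  f$glucose <- array(rep(2 * (seq_len(g$nz) - 0.5), each = g$nx * g$ny),
                     c(g$nx, g$ny, g$nz))
  pm <- data.frame(id = 1, type = "A", x = 15, y = 25, z = 40,
                   mass = 1e-10, eps = 0, K_acid = 1e-5)
  expect_equal(sample_at_particles(f, pm, g, pt)$glucose,
               (f$glucose[1, 1, 4] + f$glucose[1, 1, 5]) / 2)
  bad <- transform(pc, z = 1e4)
  expect_error(sample_at_particles(f, bad, g, p), "outside")
})

test_that("rate deposition conserves the total deposited amount", {
  p <- desk_params()
  g <- make_grid(p)
  one <- data.frame(id = 1, type = "A", x = 15, y = 25, z = 35,
                    mass = 1e-10, eps = 0, K_acid = 1e-5)
  arr <- deposit_rates(one, 4e-10, g, p)
  expect_equal(arr[2, 3, 4], 4e-10 / g$cell_volume)
  expect_equal(sum(arr != 0), 1L)
  # two co-located particles add
  two <- rbind(one, one)
  arr2 <- deposit_rates(two, c(4e-10, 6e-10), g, p)
  expect_equal(arr2[2, 3, 4], 1e-9 / g$cell_volume)
  # random set: exact global conservation, both deposition modes
  set.seed(7)
  n <- 300
  popr <- data.frame(id = 1:n, type = "NA",
                     x = runif(n, 0, p$box_x), y = runif(n, 0, p$box_y),
                     z = runif(n, 0, p$h_plaque + p$h_saliva),
                     mass = 1e-10, eps = 0, K_acid = 1e-7)
  rates <- runif(n, 0, 1e-9)
  for (mode in c("nearest", "trilinear")) {
    pm <- desk_params(deposit_mode = mode)
    total <- sum(deposit_rates(popr, rates, g, pm)) * g$cell_volume
    expect_equal(total, sum(rates), tolerance = 1e-12)
  }
  expect_error(deposit_rates(one, -1, g, p), "non-negative")
})

test_that("VTK snapshot writer emits a well-formed structured-points file", {
  p <- column_params()
  g <- make_grid(p)
  f <- make_fields(g, p, intake_schedule(15, 4))
  f$glucose[] <- c(1, 2, 3)
  path <- tempfile(fileext = ".vtk")
  write_vtk_fields(f, g, p, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("DIMENSIONS 1 1 3", lines)))
  i <- which(lines == "SCALARS glucose double 1")
  expect_equal(as.numeric(lines[(i + 2):(i + 4)]), c(1, 2, 3))
})
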