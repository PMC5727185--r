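#' Solute grid for the plaque domain
#'
#' A regular Cartesian grid over the full domain (enamel at z = 0, saliva-air
#' interface at \code{h_plaque + h_saliva}), periodic in x and y, bounded in
#' z. Cell centres sit at \code{(i - 1/2) * spacing}.
#'
#' @param params A [plaque_params()] object.
#' @return A list of class \code{plaque_grid} with \code{nx, ny, nz},
#'   \code{spacing} (um) and \code{cell_volume} (litres).
#' @export
make_grid <- function(params) {
  h <- params$grid_spacing
  g <- list(
    nx = as.integer(round(params$box_x / h)),
    ny = as.integer(round(params$box_y / h)),
    nz = as.integer(round((params$h_plaque + params$h_saliva) / h)),
    spacing = h,
    cell_volume = (h * 1e-6)^3 * 1e3  # m^3 -> L
  )
  class(g) <- "plaque_grid"
  g
}

#' Initialise solute fields
#'
#' Glucose starts at zero everywhere (first pulse fills it), lactate at
#' zero, and the polyglucose background at its constant level.
#'
#' @param grid A [make_grid()] grid.
#' @param params A [plaque_params()] object.
#' @param schedule An [intake_schedule()]; sets the polyglucose level.
#' @return A list of class \code{solute_fields} with 3-D arrays
#'   \code{glucose} (g/L) and \code{lactate} (mol/L) and scalar
#'   \code{polyGl} (g/L).
#' @export
make_fields <- function(grid, params, schedule) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  f <- list(glucose = array(0, dims), lactate = array(0, dims),
            polyGl = polyglucose_concentration(params, schedule))
  class(f) <- "solute_fields"
  f
}

# diffusivity m^2/s -> um^2/h
.D_um2_per_h <- function(D_m2s) D_m2s * 3.6e15

# Backward-Euler operator (I - dt*D*Lap) for a field with Dirichlet top
# face (ghost cell at the saliva-air interface), no-flux enamel, periodic
# laterally. Returns the Cholesky factor plus the boundary coupling needed
# to move the Dirichlet value to the right-hand side.
make_field_solver <- function(grid, D_m2s, dt) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  a <- dt * .D_um2_per_h(D_m2s) / grid$spacing^2
  lin <- function(ix, iy, iz) ix + nx * ((iy - 1L) + ny * (iz - 1L))

  ix <- rep.int(seq_len(nx), ny * nz)
  iy <- rep.int(rep(seq_len(ny), each = nx), nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  here <- seq_len(n)

  ii <- here; jj <- here
  deg <- numeric(n)
  add_neighbour <- function(jx, jy, jz) {
    j <- lin(jx, jy, jz)
    ii <<- c(ii, here); jj <<- c(jj, j)
    deg <<- deg + 1
  }
  wrap <- function(i, nmax) ((i - 1L) %% nmax) + 1L
  add_neighbour(wrap(ix + 1L, nx), iy, iz)
  add_neighbour(wrap(ix - 1L, nx), iy, iz)
  add_neighbour(ix, wrap(iy + 1L, ny), iz)
  add_neighbour(ix, wrap(iy - 1L, ny), iz)
  # z- : no-flux at enamel (omit for iz == 1)
  has_dn <- iz > 1L
  j <- lin(ix[has_dn], iy[has_dn], iz[has_dn] - 1L)
  ii <- c(ii, here[has_dn]); jj <- c(jj, j)
  deg[has_dn] <- deg[has_dn] + 1
  # z+ : interior neighbour, or ghost Dirichlet face at the top
  has_up <- iz < nz
  j <- lin(ix[has_up], iy[has_up], iz[has_up] + 1L)
  ii <- c(ii, here[has_up]); jj <- c(jj, j)
  deg[has_up] <- deg[has_up] + 1
  top <- which(iz == nz)
  deg[top] <- deg[top] + 2  # ghost cell at bc, half-spacing face

  vals <- c(1 + a * deg, rep(-a, length(ii) - n))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(n, n))
  M <- Matrix::forceSymmetric(M)
  ch <- Matrix::Cholesky(M, LDL = FALSE)
  list(factor = ch, a = a, dt = dt, top = top, n = n)
}

# One backward-Euler diffusion step with constant explicit source.
# Returns new field plus the discrete flux through the top (Dirichlet)
# face, in concentration * cell-volume units per substep.
.implicit_substep <- function(conc, solver, source, dt, bc) {
  rhs <- as.vector(conc) + dt * as.vector(source)
  rhs[solver$top] <- rhs[solver$top] + 2 * solver$a * bc
  out <- as.numeric(Matrix::solve(solver$factor, rhs, system = "A"))
  influx_conc <- sum(2 * solver$a * (bc - out[solver$top]))
  list(conc = out, influx_conc = influx_conc)
}

#' Advance the solute fields by one biology step
#'
#' Semi-implicit operator splitting: reactions (per-cell glucose sink and
#' lactate source, held constant over the step) are explicit, diffusion is
#' backward Euler on the 7-point Laplacian. Glucose has a Dirichlet value
#' \code{bc_glucose} at the saliva-air interface and no-flux at the enamel;
#' lactate has Dirichlet 0 at the interface (salivary clearance sink) and
#' no-flux at the enamel; both are laterally periodic. The step is divided
#' into substeps of at most \code{params$dt_field}; any substep changing a
#' cell by more than 50\% (relative) is recursively halved. Negative
#' concentrations produced by a sink exceeding local supply are clipped to
#' zero and the clipped mass is reported.
#'
#' @param fields A [make_fields()] object.
#' @param uptake 3-D array, per-cell glucose sink, g/L/h (non-negative).
#' @param acid_source 3-D array, per-cell lactate source, mol/L/h.
#' @param dt Step length, h.
#' @param bc_glucose Boundary glucose during this step, g/L.
#' @param grid,params Grid and parameters.
#' @param solvers Optional cache for the factorised diffusion operators: an
#'   environment (reused and filled across calls, keyed by substep length)
#'   or a pre-built pair from \code{make_field_solver}; built on the fly
#'   when \code{NULL}.
#' @return List with the updated \code{fields} and the step's bookkeeping:
#'   \code{influx_glucose} (g, through the top face), \code{uptake_applied}
#'   (g), \code{outflux_lactate} (mol), \code{produced_lactate} (mol),
#'   \code{clipped_glucose} (g), \code{clipped_lactate} (mol).
#' @export
step_fields <- function(fields, uptake, acid_source, dt, bc_glucose,
                        grid, params, solvers = NULL) {
  stopifnot(dt > 0)
  n_sub <- max(1L, ceiling(dt / params$dt_field - 1e-9))
  dt_s <- dt / n_sub
  cache <- if (is.environment(solvers)) solvers else
    new.env(parent = emptyenv())
  if (!is.environment(solvers) && !is.null(solvers) &&
      abs(solvers$glucose$dt - dt_s) < 1e-12 * dt_s) {
    cache[[sprintf("g%.9e", dt_s)]] <- solvers$glucose
    cache[[sprintf("l%.9e", dt_s)]] <- solvers$lactate
  }
  get_solver <- function(which, dt_here) {
    key <- sprintf("%s%.9e", which, dt_here)
    if (is.null(cache[[key]])) {
      D <- if (which == "g") params$D_glucose else params$D_lactate
      cache[[key]] <- make_field_solver(grid, D, dt_here)
    }
    cache[[key]]
  }
  solvers <- list(glucose = get_solver("g", dt_s),
                  lactate = get_solver("l", dt_s))
  vol <- grid$cell_volume
  gl <- as.vector(fields$glucose)
  la <- as.vector(fields$lactate)
  upt <- as.vector(uptake)
  src <- as.vector(acid_source)
  influx_gl <- 0; outflux_la <- 0
  clip_gl <- 0; clip_la <- 0

  advance <- function(conc, which, source, dt_here, bc, depth = 0L) {
    res <- .implicit_substep(conc, get_solver(which, dt_here), source,
                             dt_here, bc)
    # relative per-cell change; cells far below the field scale are ignored
    # so that filling an empty field does not trigger endless halving
    scale <- max(abs(conc))
    big <- if (scale > 0) {
      max(abs(res$conc - conc) / pmax(abs(conc), 0.05 * scale))
    } else 0
    if (big > 0.5 && depth < 6L) {
      r1 <- advance(conc, which, source, dt_here / 2, bc, depth + 1L)
      r2 <- advance(r1$conc, which, source, dt_here / 2, bc, depth + 1L)
      return(list(conc = r2$conc, influx_conc = r1$influx_conc + r2$influx_conc))
    }
    res
  }

  for (k in seq_len(n_sub)) {
    rg <- advance(gl, "g", -upt, dt_s, bc_glucose)
    gl <- rg$conc
    influx_gl <- influx_gl + rg$influx_conc * vol
    neg <- gl < 0
    if (any(neg)) { clip_gl <- clip_gl - sum(gl[neg]) * vol; gl[neg] <- 0 }

    rl <- advance(la, "l", src, dt_s, 0)
    la <- rl$conc
    outflux_la <- outflux_la - rl$influx_conc * vol
    neg <- la < 0
    if (any(neg)) { clip_la <- clip_la - sum(la[neg]) * vol; la[neg] <- 0 }
  }
  dims <- c(grid$nx, grid$ny, grid$nz)
  fields$glucose <- array(gl, dims)
  fields$lactate <- array(la, dims)
  list(fields = fields,
       influx_glucose = influx_gl,
       uptake_applied = sum(upt) * dt * vol,
       outflux_lactate = outflux_la,
       produced_lactate = sum(src) * dt * vol,
       clipped_glucose = clip_gl,
       clipped_lactate = clip_la,
       solvers = solvers)
}

#' Sample solute fields at particle positions
#'
#' Evaluates glucose, the constant polyglucose, and the H+ concentration at
#' each particle centre, either from the containing cell
#' (\code{sample_mode = "nearest"}) or by trilinear interpolation between
#' cell centres (periodic laterally, clamped at the z boundaries).
#'
#' @param fields,grid,params Fields, grid, parameters.
#' @param pop A population (see [init_population()]); positions in um.
#' @param lookup Optional pH lookup table (internal speed-up); when
#'   \code{NULL} the exact charge-balance solver is used.
#' @return List of numeric vectors \code{glucose} (g/L), \code{polyGl}
#'   (g/L), \code{H_plus} (mol/L), \code{pH}.
#' @export
sample_at_particles <- function(fields, pop, grid, params, lookup = NULL) {
  if (nrow(pop) == 0L) {
    return(list(glucose = numeric(0), polyGl = numeric(0),
                H_plus = numeric(0), pH = numeric(0)))
  }
  h <- grid$spacing
  zmax <- grid$nz * h
  if (any(pop$z < 0 | pop$z > zmax)) {
    stop("particle outside the domain in z", call. = FALSE)
  }
  if (params$sample_mode == "nearest") {
    ix <- (floor(pop$x / h) %% grid$nx) + 1L
    iy <- (floor(pop$y / h) %% grid$ny) + 1L
    iz <- pmin(pmax(floor(pop$z / h) + 1L, 1L), grid$nz)
    lin <- ix + grid$nx * ((iy - 1L) + grid$ny * (iz - 1L))
    gl <- as.vector(fields$glucose)[lin]
    la <- as.vector(fields$lactate)[lin]
  } else {
    gl <- .trilinear(fields$glucose, pop$x, pop$y, pop$z, grid)
    la <- .trilinear(fields$lactate, pop$x, pop$y, pop$z, grid)
  }
  la <- pmax(la, 0)
  ph <- if (is.null(lookup)) ph_from_lactate(la, params) else
    ph_lookup_eval(lookup, la)
  list(glucose = gl, polyGl = rep(fields$polyGl, nrow(pop)),
       H_plus = 10^(-ph), pH = ph)
}

# trilinear interpolation between cell centres; x,y periodic, z clamped
.trilinear <- function(arr, x, y, z, grid) {
  h <- grid$spacing
  v <- as.vector(arr)
  gx <- x / h - 0.5; gy <- y / h - 0.5; gz <- z / h - 0.5
  i0 <- floor(gx); j0 <- floor(gy); k0 <- floor(gz)
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  k0c <- pmin(pmax(k0, 0), grid$nz - 2L)
  fz <- pmin(pmax(gz - k0c, 0), 1)
  out <- numeric(length(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- ((i0 + dx) %% grid$nx) + 1L
    jj <- ((j0 + dy) %% grid$ny) + 1L
    kk <- k0c + dz + 1L
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    lin <- ii + grid$nx * ((jj - 1L) + grid$ny * (kk - 1L))
    out <- out + w * v[lin]
  }
  out
}

#' Deposit per-particle rates onto the grid
#'
#' Converts per-particle uptake/production rates (amount per hour) into
#' per-cell volumetric densities (amount per litre per hour), either into
#' the containing cell (\code{deposit_mode = "nearest"}) or spread
#' trilinearly. Total deposited amount equals the summed particle rates to
#' machine precision.
#'
#' @param pop Population data frame (positions in um).
#' @param rates Per-particle rates, amount/h (finite, non-negative).
#' @param grid,params Grid and parameters.
#' @return 3-D array of per-cell rate densities, amount/L/h.
#' @export
deposit_rates <- function(pop, rates, grid, params) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  out <- numeric(prod(dims))
  if (nrow(pop) > 0L) {
    if (any(!is.finite(rates)) || any(rates < 0)) {
      stop("rates must be finite and non-negative", call. = FALSE)
    }
    h <- grid$spacing
    if (any(pop$z < 0 | pop$z > grid$nz * h)) {
      stop("particle outside the domain in z", call. = FALSE)
    }
    if (params$deposit_mode == "nearest") {
      ix <- (floor(pop$x / h) %% grid$nx) + 1L
      iy <- (floor(pop$y / h) %% grid$ny) + 1L
      iz <- pmin(pmax(floor(pop$z / h) + 1L, 1L), grid$nz)
      lin <- ix + grid$nx * ((iy - 1L) + grid$ny * (iz - 1L))
      acc <- rowsum(rates, group = lin)
      out[as.integer(rownames(acc))] <- acc[, 1]
    } else {
      gx <- pop$x / h - 0.5; gy <- pop$y / h - 0.5; gz <- pop$z / h - 0.5
      i0 <- floor(gx); j0 <- floor(gy); k0 <- floor(gz)
      fx <- gx - i0; fy <- gy - j0
      k0c <- pmin(pmax(k0, 0), grid$nz - 2L)
      fz <- pmin(pmax(gz - k0c, 0), 1)
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        ii <- ((i0 + dx) %% grid$nx) + 1L
        jj <- ((j0 + dy) %% grid$ny) + 1L
        kk <- k0c + dz + 1L
        w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
          (if (dz) fz else 1 - fz)
        lin <- ii + grid$nx * ((jj - 1L) + grid$ny * (kk - 1L))
        acc <- rowsum(rates * w, group = lin)
        out[as.integer(rownames(acc))] <-
          out[as.integer(rownames(acc))] + acc[, 1]
      }
    }
  }
  array(out / grid$cell_volume, dims)
}

#' Write fields as a legacy ASCII VTK structured-points file
#'
#' @param fields,grid,params Fields, grid, parameters.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_vtk_fields <- function(fields, grid, params, path) {
  ph <- array(ph_from_lactate(as.vector(fields$lactate), params),
              dim = dim(fields$lactate))
  con <- file(path, "w")
  on.exit(close(con))
  h <- grid$spacing
  writeLines(c("# vtk DataFile Version 3.0",
               "plaquesim solute fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               sprintf("ORIGIN %g %g %g", h / 2, h / 2, h / 2),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", grid$nx * grid$ny * grid$nz)), con)
  for (nm in c("glucose", "lactate")) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(as.vector(fields[[nm]]), digits = 10), con)
  }
  writeLines(c("SCALARS pH double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(ph), digits = 10), con)
  invisible(path)
}
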