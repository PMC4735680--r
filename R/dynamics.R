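# Desk-scale dynamics: velocity-Verlet, BAOAB Langevin thermostat, and a
# Berendsen-style semi-isotropic weak-coupling barostat. Enough to exercise
# the energy model; not a production MD engine.

#' Integrator settings
#'
#' @param timestep ps (default 0.01, appropriate for smooth CG potentials).
#' @param temperature Target temperature, K (default 303).
#' @param friction Langevin friction, 1/ps (default 1; 0 gives NVE).
#' @param pressure Target pressure, bar, or `NULL` for no barostat.
#' @param barostat_tau Barostat coupling time, ps (default 1).
#' @param compressibility Effective compressibility for the weak coupling,
#'   1/bar (default 4.5e-5, water-like).
#' @param seed Integer seed for the thermostat noise stream.
#' @return An `integrator_settings` object.
#' @export
integrator_settings <- function(timestep = 0.01, temperature = 303,
                                friction = 1, pressure = NULL,
                                barostat_tau = 1,
                                compressibility = 4.5e-5, seed = 1) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction < 0) stop("friction must be >= 0")
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, pressure = pressure,
                 barostat_tau = barostat_tau,
                 compressibility = compressibility,
                 seed = as.integer(seed)),
            class = "integrator_settings")
}

.masses <- function(config, params) {
  params$tables$mass[.type_index(config, params) + 1L]
}

.kinetic <- function(v, m) {
  if (is.null(v)) stop("velocities required; see initialize_velocities()")
  0.5 * colSums(v^2 * m) # per-component kinetic energy, kJ/mol
}

#' Instantaneous kinetic temperature
#'
#' @param config Configuration with velocities.
#' @param params Parameter set.
#' @return Temperature, K (3N degrees of freedom).
#' @export
kinetic_temperature <- function(config, params) {
  m <- .masses(config, params)
  2 * sum(.kinetic(config$velocities, m)) /
    (3 * nrow(config$positions) * .KB)
}

# One BAOAB step; friction = 0 reduces exactly to velocity Verlet
# (c1 = 1, noise amplitude 0). Returns config plus the new force field in
# attr "state".
.baoab_step <- function(config, params, settings, state = NULL) {
  m <- .masses(config, params)
  dt <- settings$timestep
  if (is.null(state)) state <- .energy_forces(config, params)
  if (any(!is.finite(state$forces))) {
    dump <- file.path(tempdir(), "ilbilayer_crash.gro")
    write_gro(config, dump)
    stop("non-finite force encountered; offending frame written to ", dump)
  }
  v <- config$velocities + state$forces * (dt / 2) / m
  x <- config$positions + v * (dt / 2)
  if (settings$friction > 0) {
    c1 <- exp(-settings$friction * dt)
    c2 <- sqrt(.KB * settings$temperature * (1 - c1^2) / m)
    v <- c1 * v + c2 * matrix(rnorm(length(v)), nrow(v), 3)
  }
  x <- x + v * (dt / 2)
  if (config$periodic) x <- wrap_positions(x, config$box)
  config$positions <- x
  state <- .energy_forces(config, params)
  if (any(!is.finite(state$forces))) {
    dump <- file.path(tempdir(), "ilbilayer_crash.gro")
    write_gro(config, dump)
    stop("non-finite force encountered; offending frame written to ", dump)
  }
  v <- v + state$forces * (dt / 2) / m
  config$velocities <- v
  attr(config, "state") <- state
  config
}

#' One deterministic velocity-Verlet (NVE) step
#'
#' @param config Configuration with velocities.
#' @param params Parameter set.
#' @param settings [integrator_settings()]; friction is ignored (treated as
#'   0).
#' @return Updated configuration; attribute `"state"` carries energy,
#'   forces and virial at the new positions.
#' @export
velocity_verlet_step <- function(config, params, settings) {
  s <- settings
  s$friction <- 0
  .baoab_step(config, params, s)
}

#' One BAOAB Langevin step
#'
#' Stochastic velocity-Verlet (BAOAB splitting). The noise comes from R's
#' RNG stream: call `set.seed()` (or use [run_simulation()], which seeds
#' from its settings) for reproducible trajectories; an identical seed
#' yields a bitwise-identical trajectory. With `friction = 0` the update is
#' exactly velocity Verlet.
#'
#' @inheritParams velocity_verlet_step
#' @return Updated configuration (attribute `"state"` as above).
#' @export
langevin_step <- function(config, params, settings) {
  .baoab_step(config, params, settings)
}

#' One semi-isotropic Berendsen barostat step
#'
#' Weak-coupling rescale of the box: the lateral edges Lx = Ly share one
#' factor computed from the lateral pressure, Lz gets its own from the
#' normal pressure; bead coordinates are scaled affinely. A factor outside
#' [0.9, 1.1] is clamped (with a message). The Lx/Ly ratio is preserved
#' exactly. Center-of-mass momentum is re-zeroed after rescaling.
#'
#' @param config Configuration with velocities.
#' @param params Parameter set.
#' @param settings [integrator_settings()] with non-`NULL` `pressure`.
#' @param virial Length-3 diagonal virial (kJ/mol) from the force
#'   evaluation; taken from the configuration's `"state"` attribute when
#'   missing.
#' @return Updated configuration with rescaled box and positions; attribute
#'   `"pressure"` holds the instantaneous (Pxx, Pyy, Pzz) in bar.
#' @export
semi_isotropic_barostat_step <- function(config, params, settings,
                                         virial = NULL) {
  if (is.null(settings$pressure)) stop("settings$pressure is NULL")
  if (is.null(virial)) {
    st <- attr(config, "state")
    virial <- if (!is.null(st)) st$virial
    else .energy_forces(config, params)$virial
  }
  m <- .masses(config, params)
  V <- prod(config$box)
  ke <- .kinetic(config$velocities, m)
  P <- (2 * ke + virial) / V * .PRESS_UNIT # bar, per component
  p_lat <- (P[1] + P[2]) / 2
  p_z <- P[3]
  fac <- function(p) {
    mu <- (1 - settings$compressibility * settings$timestep /
             settings$barostat_tau * (settings$pressure - p))^(1 / 3)
    if (mu < 0.9 || mu > 1.1) {
      message("barostat rescale factor ", signif(mu, 4),
              " clamped to [0.9, 1.1]")
      mu <- min(max(mu, 0.9), 1.1)
    }
    mu
  }
  mu_xy <- fac(p_lat)
  mu_z <- fac(p_z)
  config$box <- config$box * c(mu_xy, mu_xy, mu_z)
  config$positions <- sweep(config$positions, 2, c(mu_xy, mu_xy, mu_z), `*`)
  # zero net momentum after the affine rescale
  pm <- colSums(config$velocities * m)
  config$velocities <- sweep(config$velocities, 2, pm / sum(m))
  attr(config, "state") <- NULL # forces stale after rescale
  attr(config, "pressure") <- P
  config
}

#' Run a toy simulation
#'
#' Velocity-Verlet / BAOAB loop with optional semi-isotropic barostat,
#' writing GRO frames at a configured stride and returning scalar time
#' series (energies, kinetic temperature, box edges). `n_steps = 0` writes
#' the initial frame only. The RNG is seeded from `settings$seed`, so a
#' rerun (or a restart from a checkpoint, which stores the RNG state)
#' reproduces the trajectory bitwise.
#'
#' @param config Starting configuration (velocities initialized if absent).
#' @param params Parameter set.
#' @param settings [integrator_settings()].
#' @param n_steps Number of steps.
#' @param stride Frame/series output interval in steps (default 100).
#' @param trajectory Optional GRO output path.
#' @param checkpoint Optional checkpoint path (JSON), written at the end.
#' @param restart Optional checkpoint to resume from (overrides positions,
#'   velocities, box, step counter and RNG state).
#' @return List with `config` (final state) and `series` (data frame:
#'   step, time_ps, potential, kinetic, total, temperature_K, Lx, Lz).
#' @export
run_simulation <- function(config, params, settings, n_steps,
                           stride = 100, trajectory = NULL,
                           checkpoint = NULL, restart = NULL) {
  step0 <- 0L
  if (!is.null(restart)) {
    ck <- jsonlite::read_json(restart, simplifyVector = TRUE)
    config$positions <- matrix(as.numeric(ck$positions), ncol = 3)
    config$velocities <- matrix(as.numeric(ck$velocities), ncol = 3)
    config$box <- as.numeric(ck$box)
    step0 <- ck$step
    assign(".Random.seed", as.integer(ck$rng_state), envir = globalenv())
  } else {
    set.seed(settings$seed)
    if (is.null(config$velocities))
      config <- initialize_velocities(config, params,
                                      settings$temperature,
                                      seed = settings$seed)
  }
  m <- .masses(config, params)
  state <- .energy_forces(config, params)
  attr(config, "state") <- state
  rows <- list()
  record <- function(step, cfg, st) {
    ke <- sum(.kinetic(cfg$velocities, m))
    list(step = step, time_ps = step * settings$timestep,
         potential = st$energy, kinetic = ke, total = st$energy + ke,
         temperature_K = 2 * ke / (3 * nrow(cfg$positions) * .KB),
         Lx = cfg$box[1], Lz = cfg$box[3])
  }
  emit <- function(step, cfg, st) {
    rows[[length(rows) + 1L]] <<- record(step, cfg, st)
    if (!is.null(trajectory))
      write_gro(cfg, trajectory, append = step > step0,
                time = step * settings$timestep)
  }
  emit(step0, config, state)
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      step <- step0 + s
      config <- .baoab_step(config, params, settings,
                            attr(config, "state"))
      if (!is.null(settings$pressure))
        config <- semi_isotropic_barostat_step(config, params, settings)
      st <- attr(config, "state")
      if (is.null(st)) {
        st <- .energy_forces(config, params)
        attr(config, "state") <- st
      }
      if (!is.finite(st$energy)) {
        dump <- paste0(trajectory %||% file.path(tempdir(), "ilbilayer"),
                       "_crash.gro")
        write_gro(config, dump)
        stop("non-finite energy at step ", step, "; frame written to ",
             dump)
      }
      if (step %% stride == 0 || s == n_steps) emit(step, config, st)
    }
  }
  if (!is.null(checkpoint)) {
    # doubles serialized as %.17g strings: JSON numbers do not round-trip
    # bitwise, decimal shortest-17 strings do
    jsonlite::write_json(list(
      step = step0 + n_steps,
      positions = sprintf("%.17g", as.numeric(config$positions)),
      velocities = sprintf("%.17g", as.numeric(config$velocities)),
      box = sprintf("%.17g", config$box),
      rng_state = get(".Random.seed", envir = globalenv()),
      seed = settings$seed), checkpoint, auto_unbox = TRUE, digits = NA)
  }
  series <- do.call(rbind, lapply(rows, as.data.frame))
  list(config = config, series = series)
}
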