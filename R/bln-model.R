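#' BLN potential energy of a conformation
#'
#' Evaluates the coarse-grained BLN potential: harmonic bonds
#' `k_b (r - sigma)^2`, harmonic angles `(k_theta/2)(theta - theta0)^2`,
#' per-class dihedral series `A(1 + cos phi) + B(1 + cos 3phi) +
#' C(1 + sin phi)`, and Lennard-Jones nonbonded terms
#' `4 eps S1 [(sigma/r)^12 - S2 (sigma/r)^6]` over bead pairs separated by at
#' least three bonds. Coincident beads in a nonbonded pair give a non-finite
#' (`Inf`) energy, signalling singular geometry.
#'
#' @param conf N x 3 coordinate matrix (Angstrom).
#' @param seq a [bead_sequence()] of matching length.
#' @param params a [bln_parameters()] set.
#' @return Potential energy in \eqn{\epsilon}.
#' @export
bln_energy <- function(conf, seq, params = bln_parameters()) {
  conf <- as_conformation(conf, length(seq))
  .bln_energy_cpp(conf, bead_codes(seq), dihedral_codes(seq),
                  unclass(params))
}

#' Forces on each bead under the BLN potential
#'
#' Returns the force array \eqn{-\nabla V}, the negative gradient of
#' [bln_energy()]. For optimizers that expect the gradient itself, use
#' [bln_gradient_fn()].
#'
#' @inheritParams bln_energy
#' @return N x 3 matrix of forces (\eqn{\epsilon}/A); all-`NA` if the
#'   geometry is singular.
#' @export
bln_gradient <- function(conf, seq, params = bln_parameters()) {
  conf <- as_conformation(conf, length(seq))
  -.bln_gradient_cpp(conf, bead_codes(seq), dihedral_codes(seq),
                     unclass(params))
}

#' Energy/gradient closures for a BLN system
#'
#' Bind a bead sequence and parameter set into callables
#' `function(conf) -> scalar` and `function(conf) -> N x 3 gradient`
#' (the gradient \eqn{\nabla V}, not the force), the contract used by
#' [minimize_geometry()], [fsm_grow()] and [neb_optimize()].
#'
#' @inheritParams bln_energy
#' @return A function.
#' @export
bln_energy_fn <- function(seq, params = bln_parameters()) {
  bead <- bead_codes(seq); dih <- dihedral_codes(seq); p <- unclass(params)
  # hot path: trusted numeric input, no per-call validation
  function(conf) .bln_energy_cpp(
    if (is.matrix(conf)) conf else matrix(conf, ncol = 3L), bead, dih, p)
}

#' @rdname bln_energy_fn
#' @export
bln_gradient_fn <- function(seq, params = bln_parameters()) {
  bead <- bead_codes(seq); dih <- dihedral_codes(seq); p <- unclass(params)
  function(conf) .bln_gradient_cpp(
    if (is.matrix(conf)) conf else matrix(conf, ncol = 3L), bead, dih, p)
}

#' Local geometry optimization
#'
#' Quasi-Newton (L-BFGS-B) minimization of an arbitrary energy/gradient
#' contract, converged when the root-mean-square gradient falls below `tol`.
#' Non-finite energies encountered during line search are clamped to a large
#' barrier so the optimizer backs off; a non-finite energy or gradient at the
#' final point marks the run as failed (the "numerical failure" event
#' recorded by [benchmark_reconstruction()]).
#'
#' @param conf starting N x 3 conformation (or plain numeric vector).
#' @param energy_fn `function(conf) -> scalar`.
#' @param gradient_fn `function(conf) -> gradient` of the same shape as
#'   `conf`.
#' @param tol RMS-gradient convergence tolerance (\eqn{\epsilon}/A).
#' @param max_iter iteration budget.
#' @return A list with elements `conformation`, `energy`, `converged`,
#'   `failed` and `diagnostics`. The returned energy is never above the
#'   starting energy.
#' @export
minimize_geometry <- function(conf, energy_fn, gradient_fn, tol = 1e-6,
                              max_iter = 5e4) {
  is_mat <- is.matrix(conf)
  reshape <- function(x) if (is_mat) matrix(x, ncol = 3L) else x
  x0 <- as.numeric(conf)
  e0 <- energy_fn(reshape(x0))
  if (!is.finite(e0)) {
    return(list(conformation = conf, energy = e0, converged = FALSE,
                failed = TRUE, diagnostics = "non-finite starting energy"))
  }
  fn <- function(x) {
    e <- energy_fn(reshape(x))
    if (!is.finite(e)) 1e10 else e
  }
  gr <- function(x) {
    g <- as.numeric(gradient_fn(reshape(x)))
    if (!all(is.finite(g))) g[] <- 0
    g
  }
  x <- x0
  ebest <- e0
  diag_msg <- "ok"
  failed <- FALSE
  iter_left <- max_iter
  rms <- function(x) {
    g <- as.numeric(gradient_fn(reshape(x)))
    if (!all(is.finite(g))) return(NA_real_)
    sqrt(mean(g^2))
  }
  for (round in 1:8) {
    chunk <- as.integer(min(iter_left, 10000L))
    if (chunk <= 0L) break
    res <- tryCatch(
      optim(x, fn, gr, method = "L-BFGS-B",
            control = list(maxit = chunk, factr = 1e4, pgtol = tol)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- TRUE
      diag_msg <- paste("optimizer error:", conditionMessage(res))
      break
    }
    iter_left <- iter_left - res$counts[1]
    enew <- energy_fn(reshape(res$par))
    if (!is.finite(enew)) {
      failed <- TRUE
      diag_msg <- "non-finite energy at optimizer output"
      break
    }
    if (enew <= ebest) {
      x <- res$par
      ebest <- enew
    }
    r <- rms(x)
    if (is.na(r)) {
      failed <- TRUE
      diag_msg <- "non-finite gradient at optimizer output"
      break
    }
    if (r <= tol) break
    if (res$convergence == 0 && enew >= ebest) break  # no further progress
  }
  r <- rms(x)
  conv <- !failed && !is.na(r) && r <= tol
  list(conformation = reshape(x), energy = ebest, converged = conv,
       failed = failed, diagnostics = diag_msg)
}

#' Molecular-dynamics configuration
#'
#' @param dt integration time step (tu).
#' @param temperature thermostat temperature (\eqn{\epsilon}; kB = 1).
#' @param collision_rate Andersen per-bead per-step collision probability;
#'   a collision resamples all three velocity components of that bead from
#'   the Maxwell-Boltzmann distribution at `temperature`.
#' @param duration total simulated time (tu).
#' @param seed integer RNG seed; `NULL` continues the current RNG stream.
#' @param stride store a frame every `stride` steps.
#' @param energy_bound abort threshold on `|V|` (energy divergence guard).
#' @return An object of class `md_config`.
#' @export
md_config <- function(dt = 1e-3, temperature = 1, collision_rate = 1e-3,
                      duration = 10, seed = NULL, stride = 100L,
                      energy_bound = 1e10) {
  stopifnot(dt > 0, duration > 0, collision_rate >= 0, collision_rate <= 1)
  structure(list(dt = dt, temperature = temperature,
                 collision_rate = collision_rate, duration = duration,
                 seed = seed, stride = as.integer(stride),
                 energy_bound = energy_bound),
            class = "md_config")
}

#' Constant-temperature molecular dynamics
#'
#' Velocity-Verlet integration of the BLN potential with an Andersen
#' thermostat (per-step per-bead velocity resampling). Initial velocities are
#' drawn from the Maxwell-Boltzmann distribution at the target temperature
#' unless supplied. Deterministic given `md$seed`.
#'
#' @inheritParams bln_energy
#' @param md an [md_config()].
#' @param velocities optional N x 3 starting velocities.
#' @return An object of class `md_trajectory`: list with `frames` (list of
#'   N x 3 matrices), `potential` and `kinetic` energies per frame, final
#'   `coords` and `velocities`, and the configuration used.
#' @export
run_md_nvt <- function(conf, seq, params = bln_parameters(),
                       md = md_config(), velocities = NULL) {
  conf <- as_conformation(conf, length(seq))
  if (!is.null(md$seed)) set.seed(md$seed)
  n <- nrow(conf)
  if (is.null(velocities)) {
    velocities <- matrix(rnorm(3 * n, sd = sqrt(md$temperature)), n, 3)
  }
  nsteps <- max(1L, as.integer(round(md$duration / md$dt)))
  out <- .run_md_cpp(conf, velocities, bead_codes(seq), dihedral_codes(seq),
                     unclass(bln_parameters_of(params)), md$dt, nsteps,
                     md$temperature, md$collision_rate,
                     max(1L, md$stride), md$energy_bound)
  if (isTRUE(out$diverged))
    stop("MD energy diverged beyond ", md$energy_bound,
         " epsilon; reduce dt or temperature")
  structure(list(frames = out$frames[seq_len(out$n_frames)],
                 potential = out$potential[seq_len(out$n_frames)],
                 kinetic = out$kinetic[seq_len(out$n_frames)],
                 coords = out$coords, velocities = out$velocities,
                 config = md),
            class = "md_trajectory")
}

bln_parameters_of <- function(params) {
  if (inherits(params, "bln_parameters")) return(params)
  do.call(bln_parameters, params)
}

#' Simulated-annealing search for a local (or global) minimum
#'
#' Runs MD on a halving temperature ladder -- `n_halvings + 1` stages of
#' `stage_duration` tu starting at `start_T`, each at half the previous
#' temperature -- then polishes with [minimize_geometry()] under the BLN
#' potential.
#'
#' @inheritParams bln_energy
#' @param start_T initial ladder temperature (\eqn{\epsilon}).
#' @param n_halvings number of times the temperature is halved.
#' @param stage_duration MD time per ladder stage (tu).
#' @param dt,collision_rate integrator settings, see [md_config()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param tol,max_iter passed to [minimize_geometry()].
#' @return A list with `conformation`, `energy`, `converged`, `failed`.
#' @export
anneal_to_minimum <- function(conf, seq, params = bln_parameters(),
                              start_T = 10, n_halvings = 10,
                              stage_duration = 10, dt = 1e-3,
                              collision_rate = 1e-3, seed = NULL,
                              tol = 1e-6, max_iter = 5e4) {
  if (!is.null(seed)) set.seed(seed)
  conf <- as_conformation(conf, length(seq))
  temps <- start_T / 2^(0:n_halvings)
  vel <- NULL
  for (temp in temps) {
    traj <- run_md_nvt(conf, seq, params,
                       md_config(dt = dt, temperature = temp,
                                 collision_rate = collision_rate,
                                 duration = stage_duration, seed = NULL,
                                 stride = .Machine$integer.max),
                       velocities = vel)
    conf <- traj$coords
    vel <- traj$velocities
  }
  res <- minimize_geometry(conf, bln_energy_fn(seq, params),
                           bln_gradient_fn(seq, params),
                           tol = tol, max_iter = max_iter)
  res[c("conformation", "energy", "converged", "failed")]
}
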