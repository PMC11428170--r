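#' Linear synchronous transit interpolation
#'
#' Interpolates between two configurations at fraction `f` by minimizing the
#' LST deviation functional: the squared error to linearly interpolated
#' internal pairwise distances, weighted by `1/d^4` of the interpolated
#' distance, plus a small Cartesian regularization toward the straight-line
#' interpolant (which also seeds the inner minimization). For plain numeric
#' vectors (no pairwise-distance structure) the interpolation is linear.
#' If the inner minimization fails, the Cartesian interpolant is returned
#' with a warning.
#'
#' @param a,b configurations of equal shape (N x 3 matrices or numeric
#'   vectors).
#' @param f interpolation fraction in `[0, 1]`; 0 returns `a` exactly and 1
#'   returns `b` exactly.
#' @param reg Cartesian regularization weight.
#' @return The interpolated configuration.
#' @export
lst_interpolate <- function(a, b, f, reg = 1e-6) {
  stopifnot(length(a) == length(b), f >= 0, f <= 1)
  if (f == 0) return(a)
  if (f == 1) return(b)
  lin <- (1 - f) * a + f * b
  if (!is.matrix(a) || ncol(a) != 3L) return(lin)
  da <- dist(a); db <- dist(b)
  dbar <- as.numeric((1 - f) * da + f * db)
  w <- 1 / pmax(dbar, 1e-6)^4
  obj <- function(x) {
    m <- matrix(x, ncol = 3L)
    dd <- as.numeric(dist(m)) - dbar
    sum(w * dd^2) + reg * sum((x - as.numeric(lin))^2)
  }
  res <- tryCatch(
    optim(as.numeric(lin), obj, method = "L-BFGS-B",
          control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("LST inner minimization failed; using Cartesian interpolation")
    return(lin)
  }
  matrix(res$par, ncol = 3L)
}

config_rmsd <- function(a, b) sqrt(mean((as.numeric(a) - as.numeric(b))^2))

#' Freezing-string method configuration
#'
#' @param max_images_per_side growth budget from each endpoint.
#' @param advance_rmsd_cap largest RMSD of a single advance (A).
#' @param freeze_force_threshold RMS force above which a frontier freezes
#'   (\eqn{\epsilon}/A).
#' @param n_resampled number of equidistant images in the returned path.
#' @param n_relax perpendicular-relaxation iterations per advancing image.
#' @param relax_step initial relaxation step size (A).
#' @return An object of class `fsm_config`.
#' @export
fsm_config <- function(max_images_per_side = 10, advance_rmsd_cap = 2,
                       freeze_force_threshold = 100, n_resampled = 10,
                       n_relax = 3, relax_step = 0.05) {
  stopifnot(max_images_per_side >= 1, advance_rmsd_cap > 0,
            freeze_force_threshold > 0, n_resampled >= 2)
  structure(list(max_images_per_side = max_images_per_side,
                 advance_rmsd_cap = advance_rmsd_cap,
                 freeze_force_threshold = freeze_force_threshold,
                 n_resampled = n_resampled, n_relax = n_relax,
                 relax_step = relax_step),
            class = "fsm_config")
}

# a few steepest-descent steps on the component of the gradient
# perpendicular to the local path tangent; backtracks on energy increase
relax_perpendicular <- function(x, tangent, energy_fn, gradient_fn, cfg) {
  tau <- as.numeric(tangent)
  tau <- tau / max(sqrt(sum(tau^2)), 1e-12)
  step <- cfg$relax_step
  e <- energy_fn(x)
  for (it in seq_len(cfg$n_relax)) {
    g <- as.numeric(gradient_fn(x))
    if (!all(is.finite(g))) break
    gperp <- g - sum(g * tau) * tau
    nrm <- sqrt(sum(gperp^2))
    if (nrm < 1e-12) break
    for (bt in 1:6) {
      xn <- x - step * gperp / nrm * min(nrm, 1)
      en <- energy_fn(xn)
      if (is.finite(en) && en < e) { x <- xn; e <- en; break }
      step <- step / 2
    }
  }
  x
}

#' Grow an interpolated path with the freezing-string method
#'
#' Double-ended path growth: frontiers advance alternately toward each other
#' by LST steps of RMSD at most `advance_rmsd_cap`, and only the advancing
#' image is relaxed (perpendicular to the local tangent). A frontier freezes
#' when its RMS force exceeds `freeze_force_threshold`, giving better
#' resolution in high-energy regions. Growth stops when the frontiers meet
#' or the per-side image budget is exhausted; the final path is resampled to
#' `n_resampled` equidistant images by LST. If the budget is exhausted
#' before the frontiers meet, the path still bridges the endpoints through
#' resampling and a gap warning is issued.
#'
#' @param a,b endpoint configurations.
#' @param energy_fn,gradient_fn the energy contract (see [bln_energy_fn()]).
#' @param cfg an [fsm_config()].
#' @return An object of class `image_path`: list with `images` and
#'   `energies`.
#' @export
fsm_grow <- function(a, b, energy_fn, gradient_fn, cfg = fsm_config()) {
  if (config_rmsd(a, b) < 1e-12) {
    return(image_path(list(a, b), c(energy_fn(a), energy_fn(b))))
  }
  left <- list(a); right <- list(b)
  frozen_left <- FALSE; frozen_right <- FALSE
  rmsf <- function(x) {
    g <- as.numeric(gradient_fn(x))
    if (!all(is.finite(g))) Inf else sqrt(mean(g^2))
  }
  advance_from <- "left"
  repeat {
    qL <- left[[length(left)]]; qR <- right[[length(right)]]
    gap <- config_rmsd(qL, qR)
    if (gap <= cfg$advance_rmsd_cap) break
    if ((frozen_left || length(left) >= cfg$max_images_per_side) &&
        (frozen_right || length(right) >= cfg$max_images_per_side)) {
      warning("frontier gap of ", format(gap, digits = 3),
              " A RMSD remains after image budget; bridging by resampling")
      break
    }
    side <- advance_from
    if (side == "left" &&
        (frozen_left || length(left) >= cfg$max_images_per_side))
      side <- "right"
    if (side == "right" &&
        (frozen_right || length(right) >= cfg$max_images_per_side))
      side <- "left"
    f <- min(1, cfg$advance_rmsd_cap / gap)
    if (side == "left") {
      newim <- lst_interpolate(qL, qR, f)
      newim <- relax_perpendicular(newim, as.numeric(qR) - as.numeric(qL),
                                   energy_fn, gradient_fn, cfg)
      left[[length(left) + 1L]] <- newim
      if (rmsf(newim) > cfg$freeze_force_threshold) frozen_left <- TRUE
      advance_from <- "right"
    } else {
      newim <- lst_interpolate(qR, qL, f)
      newim <- relax_perpendicular(newim, as.numeric(qL) - as.numeric(qR),
                                   energy_fn, gradient_fn, cfg)
      right[[length(right) + 1L]] <- newim
      if (rmsf(newim) > cfg$freeze_force_threshold) frozen_right <- TRUE
      advance_from <- "left"
    }
  }
  images <- c(left, rev(right))
  resampled <- resample_path_lst(images, cfg$n_resampled)
  energies <- vapply(resampled, energy_fn, numeric(1))
  if (!all(is.finite(energies)))
    warning("non-finite energy on resampled path image")
  image_path(resampled, energies)
}

# resample an image list to m equidistant (arc length by RMSD) images,
# interpolating within segments by LST
resample_path_lst <- function(images, m) {
  k <- length(images)
  if (k < 2L) return(images)
  seg <- vapply(seq_len(k - 1L), function(i)
    config_rmsd(images[[i]], images[[i + 1L]]), numeric(1))
  arc <- c(0, cumsum(seg))
  total <- arc[k]
  targets <- seq(0, total, length.out = m)
  out <- vector("list", m)
  out[[1]] <- images[[1]]
  out[[m]] <- images[[k]]
  for (q in 2:(m - 1L)) {
    s <- targets[q]
    i <- max(which(arc <= s + 1e-12))
    i <- min(i, k - 1L)
    f <- if (seg[i] > 0) (s - arc[i]) / seg[i] else 0
    out[[q]] <- lst_interpolate(images[[i]], images[[i + 1L]],
                                min(max(f, 0), 1))
  }
  out
}

#' Image path container
#'
#' @param images ordered list of configurations (at least two).
#' @param energies parallel numeric vector.
#' @param converged optional convergence flag.
#' @return An object of class `image_path`.
#' @export
image_path <- function(images, energies = NULL, converged = NA) {
  stopifnot(length(images) >= 2L)
  if (!is.null(energies)) stopifnot(length(energies) == length(images))
  structure(list(images = images, energies = energies,
                 converged = converged),
            class = "image_path")
}

#' @export
print.image_path <- function(x, ...) {
  cat("image path:", length(x$images), "images; converged:",
      x$converged, "\n")
  if (!is.null(x$energies))
    cat("  energies:", paste(format(x$energies, digits = 4),
                             collapse = " "), "\n")
  invisible(x)
}

#' Nudged-elastic-band configuration
#'
#' @param max_iter QuickMin iteration budget.
#' @param rms_force_tol per-image RMS NEB-force tolerance
#'   (\eqn{\epsilon}/A).
#' @param max_force_tol per-image maximum NEB-force tolerance.
#' @param spring_constant image spring constant (\eqn{\epsilon} A^-2).
#' @param dt QuickMin time step.
#' @return An object of class `neb_config`.
#' @export
neb_config <- function(max_iter = 1e4, rms_force_tol = 1e-4,
                       max_force_tol = 1e-2, spring_constant = 1,
                       dt = 0.01) {
  stopifnot(rms_force_tol > 0, max_force_tol > 0, spring_constant > 0,
            dt > 0)
  structure(list(max_iter = as.integer(max_iter),
                 rms_force_tol = rms_force_tol,
                 max_force_tol = max_force_tol,
                 spring_constant = spring_constant, dt = dt),
            class = "neb_config")
}

#' Nudged-elastic-band path optimization with QuickMin
#'
#' Standard NEB: at each interior image the true force perpendicular to the
#' path tangent is combined with a spring force along the tangent; the
#' energy-weighted upwind tangent is used. Images are advanced with the
#' QuickMin projected-velocity integrator. Endpoints are never moved. The
#' path converges when every interior image satisfies both the RMS and the
#' maximum force tolerance; if the iteration budget is exhausted first the
#' path is returned with `converged = FALSE`.
#'
#' @param path an [image_path()] with at least 3 images.
#' @param energy_fn,gradient_fn the energy contract.
#' @param cfg a [neb_config()].
#' @return An [image_path()] with updated images, energies and `converged`.
#' @export
neb_optimize <- function(path, energy_fn, gradient_fn, cfg = neb_config()) {
  imgs <- path$images
  n_img <- length(imgs)
  stopifnot(n_img >= 3L)
  shape <- imgs[[1]]
  X <- lapply(imgs, as.numeric)
  V <- lapply(X, function(x) numeric(length(x)))
  E <- vapply(imgs, energy_fn, numeric(1))
  ksp <- cfg$spring_constant
  reshape <- function(x) if (is.matrix(shape)) matrix(x, ncol = 3L) else x

  neb_forces <- function(X, E) {
    Fs <- vector("list", n_img)
    for (i in 2:(n_img - 1L)) {
      dplus <- X[[i + 1L]] - X[[i]]
      dminus <- X[[i]] - X[[i - 1L]]
      # energy-weighted upwind tangent
      if (E[i + 1L] > E[i] && E[i] > E[i - 1L]) {
        tau <- dplus
      } else if (E[i + 1L] < E[i] && E[i] < E[i - 1L]) {
        tau <- dminus
      } else {
        dEmax <- max(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
        dEmin <- min(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
        tau <- if (E[i + 1L] > E[i - 1L])
          dplus * dEmax + dminus * dEmin
        else
          dplus * dEmin + dminus * dEmax
      }
      tau <- tau / max(sqrt(sum(tau^2)), 1e-12)
      g <- as.numeric(gradient_fn(reshape(X[[i]])))
      f_true <- -g
      f_perp <- f_true - sum(f_true * tau) * tau
      f_spring <- ksp * (sqrt(sum(dplus^2)) - sqrt(sum(dminus^2))) * tau
      Fs[[i]] <- f_perp + f_spring
    }
    Fs
  }

  converged <- FALSE
  for (iter in seq_len(cfg$max_iter)) {
    Fs <- neb_forces(X, E)
    rms_ok <- TRUE; max_ok <- TRUE
    for (i in 2:(n_img - 1L)) {
      f <- Fs[[i]]
      if (sqrt(mean(f^2)) > cfg$rms_force_tol) rms_ok <- FALSE
      if (max(abs(f)) > cfg$max_force_tol) max_ok <- FALSE
    }
    if (rms_ok && max_ok) { converged <- TRUE; break }
    for (i in 2:(n_img - 1L)) {
      f <- Fs[[i]]
      v <- V[[i]]
      vf <- sum(v * f)
      fn2 <- sum(f * f)
      v <- if (vf > 0 && fn2 > 0) (vf / fn2) * f else numeric(length(f))
      v <- v + f * cfg$dt
      V[[i]] <- v
      X[[i]] <- X[[i]] + v * cfg$dt
      E[i] <- energy_fn(reshape(X[[i]]))
      if (!is.finite(E[i])) {
        return(image_path(lapply(X, reshape), E, converged = FALSE))
      }
    }
  }
  image_path(lapply(X, reshape), E, converged = converged)
}

#' Floored energy of a path profile
#'
#' Sum of all uphill energy increments along an ordered energy profile:
#' \eqn{\Delta E^+ = \sum_k \max(0, E_{k+1} - E_k)}. Non-negative, zero for
#' monotone decreasing profiles, and invariant to adding a constant.
#'
#' @param path_energies ordered numeric vector of at least two finite
#'   energies (concatenated over all path segments).
#' @return \eqn{\Delta E^+} in \eqn{\epsilon}.
#' @export
floored_energy <- function(path_energies) {
  stopifnot(length(path_energies) >= 2L)
  if (!all(is.finite(path_energies)))
    stop("non-finite energies in path profile")
  sum(pmax(0, diff(path_energies)))
}

#' Refine a folding path with FSM + NEB
#'
#' For each consecutive pair of reconstructed intermediates, grows an
#' initial interpolation with [fsm_grow()] and refines it with
#' [neb_optimize()]; segment profiles are concatenated (dropping duplicated
#' junction images) into a single energy profile whose floored energy ranks
#' the path.
#'
#' @param conformations ordered list of conformations along the path.
#' @param seq,params the BLN system.
#' @param fsm an [fsm_config()].
#' @param neb a [neb_config()].
#' @return An object of class `folding_path`: list with `segments` (list of
#'   [image_path()]), `energies` (concatenated profile), `floored_energy`,
#'   `converged`.
#' @export
refine_path <- function(conformations, seq, params = bln_parameters(),
                        fsm = fsm_config(), neb = neb_config()) {
  stopifnot(length(conformations) >= 2L)
  efn <- bln_energy_fn(seq, params)
  gfn <- bln_gradient_fn(seq, params)
  segs <- vector("list", length(conformations) - 1L)
  profile <- numeric(0)
  images <- list()
  conv <- TRUE
  for (i in seq_along(segs)) {
    p0 <- fsm_grow(conformations[[i]], conformations[[i + 1L]], efn, gfn,
                   fsm)
    p1 <- neb_optimize(p0, efn, gfn, neb)
    conv <- conv && isTRUE(p1$converged)
    segs[[i]] <- p1
    drop_first <- if (i == 1L) 0L else 1L
    idx <- (1L + drop_first):length(p1$images)
    profile <- c(profile, p1$energies[idx])
    images <- c(images, p1$images[idx])
  }
  structure(list(segments = segs, images = images, energies = profile,
                 floored_energy = floored_energy(profile),
                 converged = conv),
            class = "folding_path")
}

#' @export
print.folding_path <- function(x, ...) {
  cat("folding path:", length(x$images), "images over",
      length(x$segments), "segments; floored energy =",
      format(x$floored_energy, digits = 5), "\n")
  invisible(x)
}
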