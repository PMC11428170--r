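test_that("LST interpolation honours endpoints and rigid translations", {
  set.seed(80)
  a <- extended_chain(8) + matrix(rnorm(24, sd = 0.3), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.8), 8, 3)
  expect_identical(lst_interpolate(a, b, 0), a)
  expect_identical(lst_interpolate(a, b, 1), b)
  # pure translation: all internal distances constant, so the interpolant
  # is the translated copy at fraction f
  shift <- matrix(rep(c(2, -1, 3), each = 8), 8, 3)
  for (f in c(0.25, 0.5, 0.8)) {
    m <- lst_interpolate(a, a + shift, f)
    expect_lt(max(abs(m - (a + f * shift))), 1e-3)
  }
  # plain vectors interpolate linearly
  expect_equal(lst_interpolate(c(0, 0), c(2, 4), 0.5), c(1, 2))
})

test_that("FSM grows a bridging path with bounded advances", {
  # 1D quadratic valley: V(x) = sum(x^2) on 2-vectors
  V <- function(x) sum(x^2)
  dV <- function(x) 2 * x
  p <- fsm_grow(c(-1, 0), c(1, 0), V, dV,
                fsm_config(advance_rmsd_cap = 0.25, n_resampled = 8))
  expect_equal(p$images[[1]], c(-1, 0))
  expect_equal(p$images[[8]], c(1, 0))
  xs <- vapply(p$images, `[`, numeric(1), 1)
  expect_true(all(diff(xs) > 0))  # monotone along the transit
  expect_equal(p$energies, rev(p$energies), tolerance = 0.2)
  # degenerate endpoints give the trivial two-image path
  p0 <- fsm_grow(c(1, 2), c(1, 2), V, dV)
  expect_length(p0$images, 2)
  # endpoints much farther than the advance budget still bridge, warning
  expect_warning(
    pfar <- fsm_grow(0, 100, function(x) 0 * x[1], function(x) 0 * x[1],
                     fsm_config(max_images_per_side = 3,
                                advance_rmsd_cap = 1, n_resampled = 5)),
    "gap")
  expect_equal(pfar$images[[1]], 0)
  expect_equal(pfar$images[[5]], 100)
})

test_that("NEB recovers the analytic double-well barrier", {
  V <- function(x) (x^2 - 1)^2
  dV <- function(x) 4 * x * (x^2 - 1)
  for (n_img in c(5, 9, 13)) {
    p0 <- image_path(as.list(seq(-1, 1, length.out = n_img)))
    p0$energies <- vapply(p0$images, V, numeric(1))
    pn <- neb_optimize(p0, V, dV, neb_config(dt = 0.02))
    expect_true(pn$converged)
    expect_equal(max(pn$energies), 1.0, tolerance = 1e-3)
    # endpoints bitwise untouched
    expect_identical(pn$images[[1]], -1)
    expect_identical(pn$images[[n_img]], 1)
  }
})

test_that("NEB leaves a straight-line path in a quadratic valley in place", {
  # V = x^2 + 10 y^2; the MEP between (-1, 0) and (1, 0) is the x axis
  V <- function(p) p[1]^2 + 10 * p[2]^2
  dV <- function(p) c(2 * p[1], 20 * p[2])
  imgs <- lapply(seq(-1, 1, length.out = 7), function(x) c(x, 0))
  p0 <- image_path(imgs, vapply(imgs, V, numeric(1)))
  pn <- neb_optimize(p0, V, dV, neb_config(dt = 0.02, max_iter = 2000))
  ys <- vapply(pn$images, `[`, numeric(1), 2)
  expect_lt(max(abs(ys)), 1e-6)
})

test_that("floored energy sums uphill segments and is shift invariant", {
  expect_equal(floored_energy(c(0, 2, 1, 3)), 4)
  expect_equal(floored_energy(c(5, 4, 3, 1)), 0)
  set.seed(81)
  for (rep in 1:20) {
    prof <- rnorm(sample(2:12, 1))
    expect_equal(floored_energy(prof + 17.3), floored_energy(prof),
                 tolerance = 1e-12)
    # time-reversal duality: uphill of the reversed profile equals the
    # downhill total of the forward profile
    expect_equal(floored_energy(rev(prof)),
                 sum(pmax(0, -diff(prof))), tolerance = 1e-12)
    expect_gte(floored_energy(prof), 0)
  }
  expect_error(floored_energy(c(1, NA)), "finite")
  expect_error(floored_energy(3), "length")
})

test_that("FSM + NEB refine a bead-protein transition end to end", {
  fx <- fix_small10()
  set.seed(82)
  # second minimum from a perturbed start
  other <- anneal_to_minimum(fx$min$conformation +
                               matrix(rnorm(30, sd = 1.2), 10, 3),
                             fx$seq, start_T = 1, n_halvings = 4,
                             stage_duration = 1, seed = 83)
  fp <- refine_path(list(fx$min$conformation, other$conformation), fx$seq,
                    fsm = fsm_config(n_resampled = 6),
                    neb = neb_config(max_iter = 300, dt = 0.005))
  expect_s3_class(fp, "folding_path")
  expect_gte(fp$floored_energy, 0)
  expect_length(fp$energies, 6)
  # endpoint energies are the minima energies
  expect_equal(fp$energies[1], fx$min$energy, tolerance = 1e-6)
  expect_equal(fp$energies[6], other$energy, tolerance = 1e-6)
})
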