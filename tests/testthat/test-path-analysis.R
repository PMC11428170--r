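test_that("chi order parameter counts native-like pair distances", {
  set.seed(90)
  folded <- extended_chain(12) + matrix(rnorm(36, sd = 1), 12, 3)
  pairs <- mutable_pairs(12)[1:8, ]
  expect_equal(chi_order_parameter(folded, folded, pairs), 1)
  # displace every pair beyond tolerance
  blown <- folded * 3
  expect_equal(chi_order_parameter(blown, folded, pairs), 0)
  # exactly half the pairs preserved: translate half the chain far away
  # while keeping pairs within the first half intact
  p_half <- rbind(cbind(1L, 4:7), cbind(6L, 9:12))
  conf <- folded
  conf[8:12, ] <- conf[8:12, ] + 100
  # pairs (1,4..7) intact, pairs (6,9..12) broken
  expect_equal(chi_order_parameter(conf, folded, p_half), 0.5)
  expect_error(chi_order_parameter(folded, folded,
                                   matrix(numeric(0), 0, 2)), "empty")
})

test_that("chi is monotone non-increasing under inflating deviations", {
  set.seed(91)
  folded <- extended_chain(10) + matrix(rnorm(30, sd = 0.5), 10, 3)
  pairs <- mutable_pairs(10)
  noise <- matrix(rnorm(30, sd = 1), 10, 3)
  chis <- vapply(c(0, 0.3, 0.8, 1.5, 3),
                 function(a) chi_order_parameter(folded + a * noise,
                                                 folded, pairs),
                 numeric(1))
  expect_true(all(diff(chis) <= 1e-12))
  expect_equal(chis[1], 1)
})

test_that("discrete Frechet matches brute-force coupling enumeration", {
  expect_equal(discrete_frechet(cbind(1, 2), cbind(4, 6)), 5)
  set.seed(92)
  tr <- matrix(runif(6), 3, 2)
  expect_equal(discrete_frechet(tr, tr), 0)
  for (rep in 1:30) {
    A <- matrix(runif(6), 3, 2)
    B <- matrix(runif(sample(c(4, 6, 8), 1)), ncol = 2)
    expect_equal(discrete_frechet(A, B), oracle_frechet(A, B),
                 tolerance = 1e-12)
    expect_equal(discrete_frechet(A, B), discrete_frechet(B, A),
                 tolerance = 1e-12)
  }
  # triangle inequality on random track triples
  for (rep in 1:40) {
    A <- matrix(runif(10), 5, 2); B <- matrix(runif(8), 4, 2)
    C <- matrix(runif(12), 6, 2)
    expect_lte(discrete_frechet(A, C),
               discrete_frechet(A, B) + discrete_frechet(B, C) + 1e-12)
  }
  expect_error(discrete_frechet(matrix(0, 0, 2), cbind(1, 1)), "empty")
})

test_that("low-energy path selection matches a sort-then-slice oracle", {
  set.seed(93)
  fe <- runif(20)
  paths <- lapply(seq_along(fe), function(i)
    list(id = i, floored_energy = fe[i]))
  sel <- select_low_energy_paths(paths, 7)
  expect_identical(vapply(sel, `[[`, integer(1), "id"), order(fe)[1:7])
  expect_length(select_low_energy_paths(paths, 0), 0)
  # ties break by position
  ties <- lapply(1:6, function(i) list(id = i, floored_energy = 1))
  expect_identical(vapply(select_low_energy_paths(ties, 3), `[[`,
                          integer(1), "id"), 1:3)
  expect_warning(sel_all <- select_low_energy_paths(paths, 50), "available")
  expect_length(sel_all, 20)
})

test_that("clustering recovers planted bundles and handles degenerate input", {
  set.seed(94)
  mk_track <- function(first) {
    # L-shaped tracks: one chi rises before the other, with jitter
    base <- if (first == 1)
      rbind(c(0, 0), c(0.5, 0.05), c(1, 0.1), c(1, 0.6), c(1, 1))
    else
      rbind(c(0, 0), c(0.05, 0.5), c(0.1, 1), c(0.6, 1), c(1, 1))
    pmin(pmax(base + matrix(rnorm(10, sd = 0.04), 5, 2), 0), 1)
  }
  tracks <- c(lapply(1:12, function(i) mk_track(1)),
              lapply(1:12, function(i) mk_track(2)),
              lapply(1:4, function(i) matrix(runif(10), 5, 2)))
  D <- frechet_matrix(tracks)
  lab <- cluster_paths(D, min_cluster_size = 5)
  expect_gte(length(setdiff(unique(lab), -1L)), 2)
  # the two planted bundles land in different clusters
  expect_true(length(unique(lab[1:12][lab[1:12] > 0])) == 1)
  expect_true(length(unique(lab[13:24][lab[13:24] > 0])) == 1)
  expect_false(identical(unique(lab[1:12][lab[1:12] > 0]),
                         unique(lab[13:24][lab[13:24] > 0])))
  # identical tracks: one homogeneous cluster
  same <- lapply(1:8, function(i) rbind(c(0, 0), c(1, 1)))
  expect_true(all(cluster_paths(frechet_matrix(same), 5) == 1L))
  # fewer paths than the minimum cluster size: all noise
  expect_identical(cluster_paths(matrix(0, 1, 1), 5), -1L)
  expect_identical(cluster_paths(frechet_matrix(same[1:3]), 5),
                   rep(-1L, 3))
})

test_that("transition-segment pruning anchors at the last unfolded exit", {
  mono <- cbind(seq(0, 1, length.out = 11), seq(0, 1, length.out = 11))
  seg <- prune_transition_segment(mono)
  expect_equal(seg[1, ], c(0.3, 0.3), ignore_attr = TRUE)
  expect_equal(seg[nrow(seg), ], c(0.9, 0.9), ignore_attr = TRUE)
  # a reversal back into the unfolded regime re-anchors the segment
  rev_track <- rbind(c(0, 0), c(0.6, 0.2), c(0.2, 0.1), c(0.5, 0.5),
                     c(0.9, 0.9))
  seg2 <- prune_transition_segment(rev_track)
  expect_equal(seg2[1, ], c(0.2, 0.1), ignore_attr = TRUE)
  expect_equal(nrow(seg2), 3)
  # entirely folded track: empty with a warning
  folded <- rbind(c(0.9, 0.95), c(1, 1))
  expect_warning(seg3 <- prune_transition_segment(folded), "unfolded")
  expect_equal(nrow(seg3), 0)
  expect_warning(prune_transition_segment(rbind(c(0, 0), c(0.5, 0.5))),
                 "folded")
})

test_that("occupancy grids count track points on the chi plane", {
  tracks <- list(rbind(c(0.1, 0.1), c(0.9, 0.9)), rbind(c(0.1, 0.12)))
  g <- chi_occupancy_grid(tracks, breaks = 10)
  expect_equal(sum(g$count), 3)
  expect_equal(nrow(g), 100)
})

test_that("TM-score is exact for rigid motions and its d0 arithmetic", {
  set.seed(95)
  conf <- extended_chain(56) + matrix(rnorm(168, sd = 0.5), 56, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- sweep(conf %*% R, 2, c(5, -3, 2), "+")
  expect_equal(tm_score(conf, moved), 1.0, tolerance = 1e-6)
  # d0 at L = 56
  expect_equal(1.24 * 41^(1/3) - 1.8, 2.47559, tolerance = 1e-4)
  # deformed copies score below 1 but above the random-similarity floor
  defo <- conf + matrix(rnorm(168, sd = 1.5), 56, 3)
  tm <- tm_score(conf, defo)
  expect_lt(tm, 1)
  expect_gt(tm, 0.17)
  expect_warning(tm_score(extended_chain(10), extended_chain(10)), "d0")
})
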