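test_that("order parameters reproduce brute-force pair evaluations", {
  expect_equal(order_S(rep(1.3, 50)), 1)
  expect_equal(order_R(rep(1.3, 50)), 1)
  # brute force over the 6 pairs of the quarter phases
  phi <- c(0, pi / 2, pi, 3 * pi / 2)
  pairs <- combn(4, 2)
  brute <- mean(cos((phi[pairs[1, ]] - phi[pairs[2, ]]) / 2)^2)
  expect_equal(order_S(phi), brute)
  expect_equal(order_S(phi), 1 / 3)
  # a single antipodal pair sits below the 0.5 large-N floor
  expect_equal(order_S(c(0, pi)), 0)
  expect_equal(order_R(c(0, pi)), 0)
  # roots of unity cancel
  for (n in c(3, 7, 100))
    expect_lt(order_R(2 * pi * (0:(n - 1)) / n), 1e-12)
  expect_true(is.na(order_S(c(0.3, NA))))
})

test_that("S and R satisfy the exact pair-sum identity", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    phi <- runif(n, 0, 2 * pi)
    S <- order_S(phi)
    R <- order_R(phi)
    expect_equal(S, 0.5 + (n * R^2 - 1) / (2 * (n - 1)), tolerance = 1e-12)
  }
})

test_that("order parameters are invariant to global shift and relabeling", {
  set.seed(12)
  phi <- runif(40, 0, 2 * pi)
  for (shift in c(0.7, -2, pi)) {
    expect_equal(order_S(phi + shift), order_S(phi), tolerance = 1e-12)
    expect_equal(order_R((phi + shift) %% (2 * pi)), order_R(phi),
                 tolerance = 1e-12)
  }
  perm <- sample(40)
  expect_equal(order_S(phi[perm]), order_S(phi))
  expect_equal(order_R(phi[perm]), order_R(phi))
})

test_that("uniform random phases drive S to its 0.5 large-N limit", {
  set.seed(17)
  S <- replicate(50, order_S(runif(1000, 0, 2 * pi)))
  expect_lt(abs(mean(S) - 0.5), 0.01)
})

test_that("phase assignment is the linear spike-interval interpolation", {
  sp <- list(c(0.1, 0.3, 0.7), c(0.2, 0.6))
  tr <- spike_trains(sp, c(0, 1))
  ph <- suppressWarnings(phases_from_spikes(tr, c(0.1, 0.2, 0.5, 0.8)))
  expect_equal(ph$phi[1, 1], 0)                 # at a spike
  expect_equal(ph$phi[2, 1], 2 * pi * 0.5)      # halfway through cycle 1
  expect_equal(ph$phi[3, 1], 2 * pi * 0.5)      # halfway through cycle 2
  expect_true(is.na(ph$phi[4, 1]))              # beyond the last spike
  expect_equal(ph$phi[3, 2], 2 * pi * 0.75)
  expect_false(ph$valid[1, 2])                  # before neuron 2's first
  # periodic train: sawtooth of the right period
  spp <- seq(0, 2, by = 0.25)
  trp <- spike_trains(list(spp), c(0, 2))
  grid <- seq(0, 1.99, by = 0.01)
  php <- phases_from_spikes(trp, grid)
  expect_equal(php$phi[, 1], 2 * pi * ((grid %% 0.25) / 0.25),
               tolerance = 1e-9)
  # a neuron with < 2 spikes is fully masked, with a warning
  expect_warning(ph2 <- phases_from_spikes(
    spike_trains(list(c(0.1, 0.5), 0.4), c(0, 1)), c(0.2, 0.45)),
    "masked")
  expect_true(all(is.na(ph2$phi[, 2])))
})

test_that("summaries average correctly and kappa matches its definition", {
  s <- summarize_sync(rep(0.8, 10), rep(0.5, 10))
  expect_equal(s$S, 0.8)
  expect_equal(s$kappa_S, 0)
  expect_equal(s$kappa_R, 0)
  # alternating series: hand evaluation of the susceptibility
  s2 <- summarize_sync(rep(c(0.6, 1.0), 50), rep(c(0.6, 1.0), 50))
  expect_equal(s2$S, 0.8)
  expect_equal(s2$kappa_S, 0.25)
  # i.i.d. series: direct recomputation of the population CV
  set.seed(8)
  x <- runif(500, 0.2, 0.9)
  s3 <- summarize_sync(x, x)
  expect_equal(s3$kappa_R,
               sqrt(mean(x^2) - mean(x)^2) / mean(x), tolerance = 1e-12)
  expect_error(summarize_sync(c(NA_real_), c(NA_real_)), "empty")
})

test_that("series-level order parameters equal the direct definitions", {
  set.seed(23)
  phi <- matrix(runif(300, 0, 2 * pi), 10, 30)
  phi[sample(300, 40)] <- NA
  os <- hbsync:::.order_series(phi)
  for (t in 1:10) {
    expect_equal(os$S[t], order_S(phi[t, ]), tolerance = 1e-12)
    expect_equal(os$R[t], order_R(phi[t, ]), tolerance = 1e-12)
  }
})

test_that("LFP weighting follows the cutoff shape function", {
  co <- node_coordinates("ring", N = 8)
  # electrode at the centre, all nodes at distance 1: cutoff 2 keeps all
  cfg <- lfp_config(co, electrode = c(0, 0), cutoff = 2, m = 2)
  V <- matrix(rnorm(16), 2, 8)
  expect_equal(lfp(V, cfg), rowSums(V))
  # m = 0 is the plain sum regardless of distance
  cfg0 <- lfp_config(co, electrode = c(50, 0), cutoff = 0.1, m = 0)
  expect_equal(lfp(V, cfg0), rowSums(V))
  # a node at twice the cutoff with m = 2 carries weight 1/4
  cfg2 <- lfp_config(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE),
                     electrode = c(0, 0), cutoff = 1, m = 2)
  expect_equal(cfg2$weights, c(1, 0.25))
  # zero distance is caught by the cutoff branch
  expect_equal(cfg2$weights[1], 1)
})

test_that("lattice and ring coordinates match the node numbering", {
  co <- node_coordinates("lattice", L = 3)
  expect_equal(nrow(co), 9)
  expect_equal(unname(co[2, ]), c(0, 1))  # row-major: node 2 = (0, 1)
  cr <- node_coordinates("ring", N = 4)
  expect_equal(unname(cr[1, ]), c(1, 0))
  expect_equal(sqrt(rowSums(cr^2)), rep(1, 4))
})
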