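g_full <- msp_config("full")$growth
g_nr <- within(as.list(g_full), use_range <- FALSE)   # pure set-point form

test_that("growth curve crosses zero at eta and the set-point, peaks at nu", {
  # set-point form: exact zeros at eta and eps_center
  expect_equal(growth_rate(0.7, "axonal", g_nr), 0, tolerance = 1e-18)
  expect_equal(growth_rate(0.4, "axonal", g_nr), 0, tolerance = 1e-18)
  expect_equal(growth_rate(0.1, "dendritic", g_nr), 0, tolerance = 1e-18)
  # peak + nu at the midpoint of eta and eps_center
  expect_equal(growth_rate(0.55, "axonal", g_nr), 1e-4)
  expect_equal(growth_rate(0.4, "dendritic", g_nr), 1e-4)
  # far above the set-point the rate saturates at -nu
  expect_equal(growth_rate(10, "axonal", g_nr), -1e-4, tolerance = 1e-9)
  # sign pattern: removal below eta, growth between, removal above eps
  expect_lt(growth_rate(0.2, "axonal", g_nr), 0)
  expect_gt(growth_rate(0.5, "axonal", g_nr), 0)
  expect_lt(growth_rate(0.9, "axonal", g_nr), 0)
})

test_that("the curve's two roots found numerically are eta and eps_center", {
  f <- function(ca) growth_rate(ca, "axonal", g_nr)
  expect_equal(stats::uniroot(f, c(0.2, 0.5), tol = 1e-12)$root, 0.4,
               tolerance = 1e-6)
  expect_equal(stats::uniroot(f, c(0.6, 0.85), tol = 1e-12)$root, 0.7,
               tolerance = 1e-6)
})

test_that("the homeostatic range forces a hard zero plateau", {
  cas <- seq(0.65, 0.75, by = 0.005)
  expect_equal(growth_rate(cas, "axonal", g_full), rep(0, length(cas)))
  expect_equal(growth_rate(cas, "dendritic", g_full), rep(0, length(cas)))
  # just outside the range the Gaussian applies again
  expect_gt(growth_rate(0.649, "axonal", g_full), 0)
  expect_lt(growth_rate(0.751, "axonal", g_full), 0)
})

test_that("element integration is one Euler step plus vacant decay", {
  # z = 5 bound elements growing at the peak rate over a 500 ms window
  W <- matrix(0L, 2, 2); W[2, 1] <- 5L
  net <- make_toy_net(W, is_ex = c(TRUE, TRUE), A = c(5, 0),
                      D_ex = c(0, 5))
  net$ca <- c(0.55, 0.55)             # peak axonal growth, eta_A = 0.4
  out <- integrate_elements(net)
  expect_equal(out$A[1], 5 + 1e-4 * 500)   # no whole vacant element yet

  # negative rates clamp at zero
  net0 <- make_toy_net(matrix(0L, 2, 2), c(TRUE, TRUE), A = c(0.01, 0))
  net0$ca <- c(0, 0)
  expect_equal(integrate_elements(net0)$A[1], 0)
})

test_that("vacant elements live tau_vac updates on average", {
  # z = 6 with 4 bound: two whole vacant elements, each surviving with
  # probability exp(-1/10) per update; expectation 4 + 2 exp(-0.1)
  W <- matrix(0L, 2, 2); W[2, 1] <- 4L
  base <- make_toy_net(W, c(TRUE, TRUE), A = c(6, 0))
  base$ca <- c(0.7, 0.7)              # inside the range: growth zero
  set.seed(42)
  zs <- replicate(4000, integrate_elements(base)$A[1])
  expect_equal(mean(zs), 4 + 2 * exp(-0.1), tolerance = 0.005)
  expect_true(all(zs %in% c(4, 5, 6)))
})

test_that("distance kernel is Gaussian in distance, autapse-free, symmetric", {
  g <- g_full
  expect_equal(distance_kernel(c(0, 0), c(0, 0), g, same_neuron = TRUE), 0)
  expect_equal(distance_kernel(c(10, 20), c(10, 20), g), 1)
  expect_equal(distance_kernel(c(0, 0), c(150, 0), g), exp(-1))
  gf <- g; gf$kernel <- "flat"
  expect_equal(distance_kernel(c(0, 0), c(9000, 0), gf), 1)

  set.seed(1)
  pos <- matrix(runif(12, 0, 1000), ncol = 2)
  K <- mspnet:::kernel_matrix(pos, g)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(0, 6))
  expect_true(all(K >= 0 & K <= 1))
})

test_that("deletion probabilities are multiplicity-proportional per class", {
  W <- matrix(0L, 3, 3)
  W[1, 2] <- 2L; W[1, 3] <- 3L        # incoming onto neuron 1
  is_ex <- c(TRUE, TRUE, TRUE)
  p <- deletion_probabilities(W, 1, "incoming", "excitatory", is_ex)
  expect_equal(unname(p), c(0.4, 0.6))
  expect_equal(sum(p), 1)

  # a single connection takes probability one
  W2 <- matrix(0L, 2, 2); W2[2, 1] <- 7L
  p2 <- deletion_probabilities(W2, 1, "outgoing", is_ex = c(TRUE, TRUE))
  expect_equal(unname(p2), 1)

  # the class is empty: caller must not ask
  expect_error(
    deletion_probabilities(W, 1, "incoming", "inhibitory", is_ex),
    "no incoming"
  )
})

test_that("surplus deletion is forced when only one connection exists", {
  W <- matrix(0L, 2, 2); W[2, 1] <- 3L
  net <- make_toy_net(W, c(TRUE, TRUE), A = c(2.9, 0), D_ex = c(0, 5))
  set.seed(1)
  out <- delete_surplus(net)
  expect_equal(out$W[2, 1], 2L)       # floor(A) = 2 caps the outgoing count
  # the partner's dendritic element survives and is vacant again
  vac <- mspnet:::vacant_counts(out)
  expect_equal(vac$D_ex[2], 3)        # floor(5) - 2 bound
})

test_that("networks without surplus are left untouched", {
  W <- matrix(0L, 3, 3); W[2, 1] <- 2L; W[3, 2] <- 1L
  net <- make_toy_net(W, c(TRUE, TRUE, FALSE), A = c(2, 1, 0),
                      D_ex = c(0, 2, 1), D_in = c(0, 0, 0))
  set.seed(1)
  expect_identical(delete_surplus(net)$W, W)
})

test_that("deletion frequencies follow the multiplicity rule (chi-squared)", {
  W <- matrix(0L, 4, 4)
  W[2, 1] <- 2L; W[3, 1] <- 3L; W[4, 1] <- 5L   # 10 outgoing, floor(A) = 9
  net <- make_toy_net(W, rep(TRUE, 4), A = c(9, 0, 0, 0),
                      D_ex = c(0, 5, 5, 5))
  set.seed(7)
  n_trials <- 10000
  lost <- integer(3)
  for (r in seq_len(n_trials)) {
    out <- delete_surplus(net)
    lost <- lost + (W[2:4, 1] - out$W[2:4, 1])
  }
  expect_equal(sum(lost), n_trials)
  test <- stats::chisq.test(lost, p = c(0.2, 0.3, 0.5))
  expect_gt(test$p.value, 0.01)
})

test_that("formation probabilities follow the vacancy product and kernel", {
  # two sources with one vacant axonal element each, one target: 1/2 each
  P <- formation_probabilities(A_vac = c(1, 1, 0), D_vac = c(0, 0, 1),
                               src_mask = c(TRUE, TRUE, FALSE),
                               K = matrix(1, 3, 3) - diag(3))
  expect_equal(P[3, 1], 0.5)
  expect_equal(P[3, 2], 0.5)
  expect_equal(sum(P), 1)             # flat kernel: total mass exactly one

  # Gaussian-like kernel < 1 leaves a no-formation deficit
  K <- matrix(0.25, 3, 3); diag(K) <- 0
  P2 <- formation_probabilities(c(1, 1, 0), c(0, 0, 1),
                                c(TRUE, TRUE, FALSE), K)
  expect_lt(sum(P2), 1)

  # autapses are excluded through the kernel diagonal
  P3 <- formation_probabilities(c(1, 0), c(1, 1), c(TRUE, FALSE),
                                matrix(1, 2, 2) - diag(2))
  expect_equal(P3[1, 1], 0)

  # an empty vacancy pool gives an all-zero field
  expect_equal(sum(formation_probabilities(c(0, 0), c(1, 1),
                                           c(TRUE, TRUE),
                                           matrix(1, 2, 2) - diag(2))), 0)
})

test_that("formation respects the potential-synapse cap and vacancy bounds", {
  # 3 vacant axonal vs 5 vacant dendritic: at most 3 synapses per update
  net <- make_toy_net(matrix(0L, 4, 4), rep(TRUE, 4),
                      A = c(3, 0, 0, 0), D_ex = c(0, 2, 2, 1))
  set.seed(2)
  out <- form_synapses(net)
  expect_lte(sum(out$W), 3)
  # no pair can gain more than the smaller of the two vacancy pools
  expect_lte(max(out$W[, 1]), 2)
  expect_lte(out$W[4, 1], 1)

  # a vanishing kernel means draws fall beyond the mass: nothing forms
  netk <- make_toy_net(matrix(0L, 3, 3), rep(TRUE, 3),
                       A = c(2, 0, 0), D_ex = c(0, 2, 2),
                       K = matrix(1e-12, 3, 3) - diag(3) * 1e-12)
  set.seed(3)
  expect_equal(sum(form_synapses(netk)$W), 0)
})

test_that("single-draw formation frequencies match the probability field", {
  # one source, three targets with kernel values 0.9, 0.5, 0.2:
  # P(target i) = K_i / 3, P(nothing) = 1 - sum
  K <- matrix(0, 4, 4)
  K[2, 1] <- 0.9; K[3, 1] <- 0.5; K[4, 1] <- 0.2
  net <- make_toy_net(matrix(0L, 4, 4), rep(TRUE, 4),
                      A = c(1, 0, 0, 0), D_ex = c(0, 1, 1, 1), K = K)
  set.seed(13)
  n_trials <- 10000
  hits <- integer(4)                  # targets 2..4 and "none"
  for (r in seq_len(n_trials)) {
    out <- form_synapses(net)
    tgt <- which(out$W[, 1] > 0)
    if (length(tgt)) hits[tgt - 1L] <- hits[tgt - 1L] + 1L
    else hits[4] <- hits[4] + 1L
  }
  probs <- c(0.9, 0.5, 0.2) / 3
  test <- stats::chisq.test(hits, p = c(probs, 1 - sum(probs)))
  expect_gt(test$p.value, 0.01)
})

test_that("repeated-draw acceptance matches an independent enumeration", {
  # one source with two vacant axonal elements, two single-vacancy
  # targets, hence per-pair probabilities p = K/2 and two draws with a
  # cap of one synapse per pair; the joint outcome distribution follows
  # by enumerating the (draw1, draw2) possibilities.
  K <- matrix(0, 3, 3)
  K[2, 1] <- 0.9; K[3, 1] <- 0.6
  net <- make_toy_net(matrix(0L, 3, 3), rep(TRUE, 3),
                      A = c(2, 0, 0), D_ex = c(0, 1, 1), K = K)
  p1 <- 0.9 / 2; p2 <- 0.6 / 2
  set.seed(29)
  n_trials <- 6000
  counts <- matrix(0L, 2, 2, dimnames = list(c("no1", "yes1"),
                                             c("no2", "yes2")))
  for (r in seq_len(n_trials)) {
    out <- form_synapses(net)
    counts[out$W[2, 1] + 1L, out$W[3, 1] + 1L] <-
      counts[out$W[2, 1] + 1L, out$W[3, 1] + 1L] + 1L
  }
  # enumeration over two independent draws with per-pair cap 1
  q_no <- 1 - p1 - p2
  exp_probs <- c(
    no1_no2   = q_no^2,
    yes1_no2  = p1^2 + 2 * p1 * q_no,
    no1_yes2  = p2^2 + 2 * p2 * q_no,
    yes1_yes2 = 2 * p1 * p2
  )
  test <- stats::chisq.test(as.vector(counts),
                            p = exp_probs[c(1, 2, 3, 4)])
  expect_gt(test$p.value, 0.01)
})

test_that("a full update keeps every neuron within its element capacity", {
  cfg <- tiny_config()
  set.seed(21)
  net <- new_network(cfg)
  net$T <- 2000L                      # baseline input regime
  for (k in 1:15) {
    net <- connectivity_update(net)
    b <- mspnet:::bound_counts(net)
    expect_true(all(b$A <= floor(net$A) + 1e-9))
    expect_true(all(b$D_ex <= floor(net$D_ex) + 1e-9))
    expect_true(all(b$D_in <= floor(net$D_in) + 1e-9))
  }
  # conservation: total synapses equal bound axonal and bound dendritic
  b <- mspnet:::bound_counts(net)
  expect_equal(sum(net$W), sum(b$A))
  expect_equal(sum(net$W), sum(b$D_ex) + sum(b$D_in))
})

test_that("a network at rest in the homeostatic range does not rewire", {
  W <- matrix(0L, 3, 3); W[2, 1] <- 2L; W[3, 2] <- 1L
  net <- make_toy_net(W, rep(TRUE, 3), A = c(2, 1, 0),
                      D_ex = c(0, 2, 1))
  net$ca <- rep(0.71, 3)              # stays in range across one window
  net$config$schedule$ext_high <- 0   # no input, no spikes
  net$config$schedule$ext_low <- 0
  net$config$schedule$ext_sd <- 0
  set.seed(8)
  out <- connectivity_update(net)
  expect_identical(out$W, W)
  expect_equal(out$A, net$A)
})

test_that("update trajectories are reproducible under a seed", {
  cfg <- tiny_config()
  run <- function() {
    set.seed(31)
    net <- new_network(cfg)
    net$T <- 2000L
    for (k in 1:8) net <- connectivity_update(net)
    net$W
  }
  expect_identical(run(), run())
})
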