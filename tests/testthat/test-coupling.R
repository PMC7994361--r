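test_that("assemble builds the block weight matrix and disassemble inverts it", {
  pair <- showcase_pair()
  m <- assemble(pair)
  expect_equal(m$weights,
               rbind(c(0, 1.6, -4, 0),
                     c(-1.6, 0, 0, 0),
                     c(-4, 0, 0, 1.6),
                     c(0, 0, -1.6, 0)))
  expect_equal(m$theta, c(-4, 0, -4, 0))

  p2 <- disassemble(m)
  for (f in c("thetaA", "thetaB", "wA", "wB", "wAB", "wBA"))
    expect_identical(p2[[f]], pair[[f]])

  z <- coupled_pair(c(0, 0), c(0, 0), diag(2), diag(2),
                    matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(assemble(z)$weights[1:2, 3:4] == 0))
  expect_false(is_recurrent(z))

  # iterating the assembled module reproduces the two-block update rule
  set.seed(5)
  a <- runif(2); b <- runif(2)
  nx <- nm_step(m, c(a, b))
  expect_equal(nx[1:2],
               as.numeric(pair$thetaA + pair$wA %*% tanh(a) + pair$wAB %*% tanh(b)))
  expect_equal(nx[3:4],
               as.numeric(pair$thetaB + pair$wB %*% tanh(b) + pair$wBA %*% tanh(a)))
})

test_that("the synchronization condition is checked entrywise with recurrence", {
  expect_true(check_sync_condition(showcase_pair()))
  expect_true(check_sync_condition(stable_pair()))

  one_way <- coupled_pair(0, 0, matrix(1), matrix(1),
                          matrix(2), matrix(0))
  expect_false(check_sync_condition(one_way))

  perturbed <- coupled_pair(0, 0, matrix(1), matrix(1.1),
                            matrix(0.5), matrix(0.5))
  expect_false(check_sync_condition(perturbed, tol = 1e-9))
  expect_error(sync_matrix(perturbed), "violated.*0\\.1")

  expect_error(coupled_pair(c(0, 0), 0, diag(2), diag(2), diag(2), diag(2)),
               "unequal dimension")
})

test_that("synchronization and obstruction matrices match the worked example", {
  pair <- showcase_pair()
  core <- sync_matrix(pair)
  expect_equal(core$w_plus, rbind(c(-4, 1.6), c(-1.6, 0)))
  expect_equal(core$theta, c(-4, 0))
  expect_equal(obstruction_matrix(pair), rbind(c(4, 1.6), c(-1.6, 0)))

  # the conservative configuration shares the same core
  expect_equal(sync_matrix(stable_pair())$w_plus, rbind(c(-4, 1.6), c(-1.6, 0)))
  expect_equal(obstruction_matrix(stable_pair()),
               rbind(c(-1.35, 0.6), c(-0.6, 0)))

  # a coupling equal to the module weights cancels the obstruction
  w <- rbind(c(0, 1), c(-1, 0.5))
  pz <- coupled_pair(c(0, 0), c(0, 0), w, w, w, w)
  expect_equal(obstruction_matrix(pz), matrix(0, 2, 2))

  expect_error(sync_matrix(coupled_pair(c(0, 0), c(0, 0), w, w,
                                        matrix(0, 2, 2), matrix(0, 2, 2))),
               "recurrent")
})

test_that("identical-module split halves w+ and w- and round-trips", {
  w_plus <- rbind(c(-4, 1.6), c(-1.6, 0))
  w_minus <- rbind(c(-1.35, 0.6), c(-0.6, 0))
  p <- identical_module_split(w_plus, w_minus)
  expect_equal(p$wA, rbind(c(-2.675, 1.1), c(-1.1, 0)))
  expect_equal(p$wAB, rbind(c(-1.325, 0.5), c(-0.5, 0)))

  p2 <- identical_module_split(w_plus, rbind(c(4, 1.6), c(-1.6, 0)))
  expect_equal(p2$wA, rbind(c(0, 1.6), c(-1.6, 0)))
  expect_equal(p2$wAB, rbind(c(-4, 0), c(0, 0)))

  expect_warning(identical_module_split(w_plus, w_plus), "non-recurrent")

  # exact reconstruction for random prescribed (w+, w-)
  set.seed(8)
  for (k in 1:20) {
    n <- sample(2:4, 1)
    P <- matrix(runif(n * n, -2, 2), n)
    M <- matrix(runif(n * n, -2, 2), n)
    pr <- identical_module_split(P, M)
    expect_true(check_sync_condition(pr, tol = 0))
    expect_equal(sync_matrix(pr)$w_plus, P)
    expect_equal(obstruction_matrix(pr), M)
  }
})

test_that("(xi, eta) coordinates invert exactly and label the manifolds", {
  s <- to_xi_eta(c(1, 2), c(1, 2))
  expect_equal(s$xi, c(1, 2))
  expect_equal(s$eta, c(0, 0))

  s2 <- to_xi_eta(c(1, 0), c(-1, 0))
  expect_equal(s2$xi, c(0, 0))
  expect_equal(s2$eta, c(1, 0))

  set.seed(13)
  for (k in 1:20) {
    a <- runif(3, -5, 5); b <- runif(3, -5, 5)
    ab <- from_xi_eta(to_xi_eta(a, b))
    expect_equal(ab$a, a, tolerance = 1e-15)
    expect_equal(ab$b, b, tolerance = 1e-15)
  }
  expect_error(to_xi_eta(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("the (xi, eta) route reproduces the direct (a, b) route", {
  pair <- showcase_pair()
  m <- assemble(pair)
  set.seed(17)
  for (k in 1:10) {
    a <- runif(2, -2, 2); b <- runif(2, -2, 2)
    direct <- nm_step(m, c(a, b))
    s <- xi_eta_step(pair, to_xi_eta(a, b))
    ab <- from_xi_eta(s)
    expect_equal(c(ab$a, ab$b), direct, tolerance = 1e-12)
  }

  # eta stays exactly zero on the manifold when the condition holds
  s0 <- to_xi_eta(c(0.4, -0.3), c(0.4, -0.3))
  s1 <- xi_eta_step(pair, s0)
  expect_lt(max(abs(s1$eta)), 1e-12)

  # on the obstruction manifold with zero bias the eta update is
  # w- tanh(eta), evaluated independently
  p0 <- showcase_pair(theta1 = 0)
  p0$thetaA[2] <- p0$thetaB[2] <- 0
  eta <- c(0.3, -0.8)
  s <- xi_eta_step(p0, structure(list(xi = c(0, 0), eta = eta),
                                 class = "xi_eta"))
  expect_equal(s$eta,
               as.numeric(rbind(c(4, 1.6), c(-1.6, 0)) %*% tanh(eta)),
               tolerance = 1e-12)
})

test_that("route equivalence holds over 100 steps on random synchronizable pairs", {
  worst <- 0
  for (sd in 1:40) {
    p <- random_sync_pair(n = 3, seed = sd)
    m <- assemble(p)
    set.seed(5000 + sd)
    a <- runif(3, -1, 1); b <- runif(3, -1, 1)
    direct <- nm_iterate(m, c(a, b), 0, 101)$states
    s <- to_xi_eta(a, b)
    for (t in 1:100) {
      s <- xi_eta_step(p, s)
      ab <- from_xi_eta(s)
      worst <- max(worst, max(abs(c(ab$a, ab$b) - direct[t + 1, ])))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the synchronized module reproduces the manifold dynamics", {
  pair <- stable_pair()
  core <- synchronized_module(pair)
  expect_equal(core$weights, rbind(c(-4, 1.6), c(-1.6, 0)))
  expect_equal(core$theta, c(-4, 0))

  # same trajectory through the full coupled system started on the
  # diagonal and through the n-dimensional core module.  The bias is
  # placed in a regular (non-chaotic) range: on a chaotic orbit any
  # comparison of two floating-point evaluation orders is destroyed by
  # exponential error growth, which is a property of chaos, not of the
  # reduction.
  pair1 <- stable_pair(-1)
  core1 <- synchronized_module(pair1)
  xi0 <- c(0.37, -0.81)
  full <- nm_iterate(assemble(pair1), c(xi0, xi0), 0, 1000)$states
  reduced <- nm_iterate(core1, xi0, 0, 1000)$states
  expect_lt(max(abs(full[, 1:2] - reduced)), 1e-9)
  expect_lt(max(abs(full[, 3:4] - reduced)), 1e-9)

  # in the chaotic range the two routes still agree to full precision
  # over a horizon short enough that roundoff cannot be amplified
  # above tolerance
  full2 <- nm_iterate(assemble(pair), c(xi0, xi0), 0, 40)$states
  reduced2 <- nm_iterate(core, xi0, 0, 40)$states
  expect_lt(max(abs(full2[, 1:2] - reduced2)), 1e-9)
})

test_that("obstruction map is bias-free with a fixed point at the origin", {
  pair <- showcase_pair()
  expect_equal(obstruction_map(pair, c(0, 0)), c(0, 0))
  eta <- c(0.1, 0.1)
  expect_equal(obstruction_map(stable_pair(), eta),
               as.numeric(rbind(c(-1.35, 0.6), c(-0.6, 0)) %*% tanh(eta)))
  # bias does not enter
  expect_equal(obstruction_map(showcase_pair(-1), eta),
               obstruction_map(showcase_pair(-4), eta))

  # entrywise-small obstruction: the origin attracts globally
  w_minus <- rbind(c(0.2, 0.3), c(0.1, 0))
  wA <- rbind(c(0.25, 0.3), c(0.1, 0.05))
  coup <- wA - w_minus
  pw <- coupled_pair(c(0, 0), c(0, 0), wA, wA, coup, coup)
  expect_equal(obstruction_matrix(pw), w_minus)
  eta <- c(3, -2)
  for (t in 1:10000) eta <- obstruction_map(pw, eta)
  expect_lt(max(abs(eta)), 1e-6)
})

test_that("coupling classification finds generative witnesses", {
  g <- classify_coupling(showcase_pair())
  expect_equal(g$label, "generative")
  expect_equal(unname(g$witnesses[1, ]), c(1L, 1L))

  expect_equal(classify_coupling(stable_pair())$label, "conservative")

  # coupling supported only where the modules already connect
  w <- rbind(c(0, 1), c(-1, 0))
  cp <- coupled_pair(c(0, 0), c(0, 0), w, w, 0.3 * w, 0.3 * w)
  expect_equal(classify_coupling(cp)$label, "conservative")

  # invariant under positive rescaling of all weights
  p <- showcase_pair()
  for (f in c("wA", "wB", "wAB", "wBA")) p[[f]] <- 2.5 * p[[f]]
  expect_equal(classify_coupling(p)$label, "generative")
})

test_that("synchronization equivalence compares sign cores", {
  expect_true(sync_equivalent(showcase_pair(), stable_pair()))
  expect_true(sync_equivalent(showcase_pair(), showcase_pair()))

  # flip the core self-connection sign: no longer equivalent
  w <- rbind(c(2, 1.6), c(-1.6, 0))     # positive self-connection core
  other <- identical_module_split(w, rbind(c(0.5, 0.4), c(-0.4, 0)))
  expect_false(sync_equivalent(showcase_pair(), other))

  # permuted labels only match when permutation mode is on
  wp <- rbind(c(0, -1.6), c(1.6, -4))   # showcase core with neurons swapped
  perm_pair <- identical_module_split(wp, 0.5 * wp)
  expect_false(sync_equivalent(showcase_pair(), perm_pair))
  expect_true(sync_equivalent(showcase_pair(), perm_pair,
                              up_to_permutation = TRUE))
})

test_that("the manifold is dynamically invariant for constructed pairs", {
  worst <- 0
  for (sd in 1:50) {
    p <- random_sync_pair(n = 3, seed = sd, generative = sd %% 2 == 0)
    expect_true(check_sync_condition(p, tol = 0))
    m <- assemble(p)
    set.seed(9000 + sd)
    x0 <- runif(3, -1, 1)
    tr <- nm_iterate(m, c(x0, x0), 0, 1000)$states
    worst <- max(worst, max(abs(tr[, 1:3] - tr[, 4:6])))
  }
  expect_lt(worst, 1e-6)
})
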