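test_that("the showcase system is s-decomposable with a generative label", {
  m <- assemble(showcase_pair())
  decs <- s_decompose(m)
  expect_gt(length(decs), 0)
  hit <- Filter(function(d) identical(d$partition_A, c(1L, 2L)) &&
                  identical(d$partition_B, c(3L, 4L)), decs)
  expect_equal(length(hit), 1)
  expect_equal(hit[[1]]$label, "generative")
  expect_equal(hit[[1]]$core$structure$entries,
               matrix(as.integer(c(-1, -1, 1, 0)), 2))
  expect_false(is_basic(m))

  decs2 <- s_decompose(assemble(stable_pair()))
  hit2 <- Filter(function(d) identical(d$partition_A, c(1L, 2L)) &&
                   identical(d$partition_B, c(3L, 4L)), decs2)
  expect_equal(length(hit2), 1)
  expect_equal(hit2[[1]]$label, "conservative")
})

test_that("degenerate and odd-dimensional inputs are rejected or empty", {
  ff <- neuromodule(c(0, 0), rbind(c(0, 1), c(0, 0)))
  expect_equal(length(s_decompose(ff)), 0)
  expect_true(is_basic(ff))

  expect_error(s_decompose(neuromodule(c(0, 0, 0), diag(3))), "even dimension")
  expect_error(s_decompose(neuromodule(numeric(14), diag(14))), "refusing")
})

test_that("returned decompositions are sound and reassemble the module", {
  for (sd in c(2, 9, 23)) {
    p <- random_sync_pair(n = 2, seed = sd)
    m <- assemble(p)
    set.seed(sd)
    ms <- permute_module(m, sample(4))
    decs <- s_decompose(ms, tol = 0)
    expect_gt(length(decs), 0)
    for (d in decs) {
      expect_true(check_sync_condition(d$pair, tol = 0))
      idx <- c(d$partition_A, d$partition_B)
      expect_identical(assemble(d$pair)$weights,
                       ms$weights[idx, idx, drop = FALSE])
      expect_identical(assemble(d$pair)$theta, ms$theta[idx])
    }
  }
})

test_that("exhaustive search agrees with an independent brute-force check", {
  # all-excitatory 4-ring: enumerate every bipartition/pairing by hand
  w <- matrix(0, 4, 4)
  w[2, 1] <- w[3, 2] <- w[4, 3] <- w[1, 4] <- 1
  ring <- neuromodule(numeric(4), w)

  brute <- function(mod) {
    n <- mod$n; m <- n %/% 2
    for (A in utils::combn(n, m, simplify = FALSE)) {
      if (A[1] != 1L) next
      B0 <- setdiff(seq_len(n), A)
      for (p in perms_of(B0)) {
        wA <- mod$weights[A, A, drop = FALSE]
        wB <- mod$weights[p, p, drop = FALSE]
        wAB <- mod$weights[A, p, drop = FALSE]
        wBA <- mod$weights[p, A, drop = FALSE]
        if (!any(wAB != 0) || !any(wBA != 0)) next
        if (max(abs((wA - wBA) - (wB - wAB))) > 1e-12) next
        if (max(abs(mod$theta[A] - mod$theta[p])) > 1e-12) next
        ok_conn <- is_strongly_connected(neuromodule(mod$theta[A], wA)) &&
          is_strongly_connected(neuromodule(mod$theta[p], wB))
        if (ok_conn) return(TRUE)
      }
    }
    FALSE
  }
  expect_equal(length(s_decompose(ring)) > 0, brute(ring))
  expect_equal(is_basic(ring), !brute(ring))

  # same cross-check on a handful of random even modules
  set.seed(77)
  for (k in 1:10) {
    w <- matrix(rbinom(16, 1, 0.4) * sample(c(-1, 1), 16, TRUE) *
                  sample(1:4, 16, TRUE) / 4, 4)
    mod <- neuromodule(numeric(4), w)
    expect_equal(length(s_decompose(mod)) > 0, brute(mod))
  }
})

test_that("planted decompositions are recovered after shuffling", {
  ok2 <- 0; ok3 <- 0
  for (sd in 1:40) {
    p <- random_sync_pair(n = 2, seed = sd, generative = sd %% 2 == 0)
    set.seed(10000 + sd)
    ms <- permute_module(assemble(p), sample(4))
    ok2 <- ok2 + (length(s_decompose(ms, tol = 0)) > 0)
  }
  for (sd in 1:20) {
    p <- random_sync_pair(n = 3, seed = sd, density = 0.6)
    set.seed(20000 + sd)
    ms <- permute_module(assemble(p), sample(6))
    ok3 <- ok3 + (length(s_decompose(ms, tol = 0)) > 0)
  }
  expect_equal(ok2, 40)
  expect_equal(ok3, 20)
})

test_that("exchange symmetry is deduplicated", {
  decs <- s_decompose(assemble(showcase_pair()))
  for (d in decs) expect_true(1L %in% d$partition_A)
  keys <- vapply(decs, function(d)
    paste(c(d$partition_A, d$partition_B), collapse = "-"), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("sign-level feasibility matches a numeric magnitude search", {
  # every 2-of-4 sign case of the paired-entry relation, checked
  # against random magnitude search for x_A - x_BA = x_B - x_AB
  numeric_feasible <- function(sA, sBA, sB, sAB) {
    draw <- function(s) if (s == 0) 0 else s * runif(1, 0.1, 2)
    for (t in 1:4000) {
      xA <- draw(sA); xBA <- draw(sBA); xB <- draw(sB); xAB <- draw(sAB)
      # one free magnitude can absorb the balance: solve for the last
      # nonzero slot instead of sampling it
      nz <- which(c(sA, sBA, sB, sAB) != 0)
      if (length(nz) > 0) {
        k <- nz[length(nz)]
        v <- c(xA, xBA, xB, xAB)
        coef <- c(1, -1, -1, 1)
        rhs <- -sum((coef * v)[-k])
        val <- rhs / coef[k]
        if (sign(val) == c(sA, sBA, sB, sAB)[k]) return(TRUE)
      } else return(TRUE)
    }
    FALSE
  }
  set.seed(55)
  for (sA in -1:1) for (sBA in -1:1) for (sB in -1:1) for (sAB in -1:1) {
    expect_equal(syncore:::signs_feasible(sA, sBA, sB, sAB),
                 numeric_feasible(sA, sBA, sB, sAB),
                 info = paste(sA, sBA, sB, sAB))
  }
})

test_that("structure-level feasibility brackets configuration decomposability", {
  m <- assemble(showcase_pair())
  expect_true(structure_s_feasible(structure_matrix(m))$feasible)

  ff <- signed_structure(rbind(c(0, 1), c(0, 0)))
  expect_false(structure_s_feasible(ff)$feasible)

  # a 4-node pattern whose every bipartition leaves a lone nonzero sign
  # in some paired position: take two disjoint 2-cycles plus a single
  # one-way cross link; the lone link is always unbalanced
  s <- matrix(0L, 4, 4)
  s[2, 1] <- s[1, 2] <- 1L
  s[4, 3] <- s[3, 4] <- 1L
  s[3, 1] <- 1L
  expect_false(structure_s_feasible(signed_structure(s))$feasible)

  # configuration-level decomposability implies sign-level feasibility
  for (sd in 1:15) {
    p <- random_sync_pair(n = 2, seed = sd)
    set.seed(30000 + sd)
    ms <- permute_module(assemble(p), sample(4))
    if (length(s_decompose(ms, tol = 0)) > 0)
      expect_true(structure_s_feasible(structure_matrix(ms))$feasible)
  }
})
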