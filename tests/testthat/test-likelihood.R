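test_that("tip encodings", {
  g10 <- build_grid(0, 10, 10)
  v <- encode_tip(tip_point(6.5), g10)
  expect_equal(which(v == 1), 7L)
  expect_equal(sum(v), 1)

  g6 <- build_grid(-3, 3, 6)
  v <- encode_tip(tip_discrete(1), g6, thresholds = 0)
  expect_equal(v, c(1, 1, 1, 0, 0, 0))
  v2 <- encode_tip(tip_discrete(2), g6, thresholds = 0)
  expect_equal(v2, c(0, 0, 0, 1, 1, 1))

  g8 <- build_grid(-4, 4, 8)
  v3 <- encode_tip(tip_censored("high", at = 1), g8)
  expect_equal(v3, c(0, 0, 0, 0, 0, 1, 1, 1))
  v4 <- encode_tip(tip_censored("low", at = -1), g8)
  expect_equal(v4, c(1, 1, 1, 0, 0, 0, 0, 0))

  expect_equal(encode_tip(tip_missing(), g6), rep(1, 6))
  expect_equal(encode_tip(tip_interval(-1, 2), g6), c(0, 0, 1, 1, 1, 0))

  # joint model: level-major layout
  vj <- encode_tip(tip_joint(2, 0.5), g6, k = 2)
  expect_equal(which(vj == 1), 6L + 4L)
  vd <- encode_tip(tip_discrete(1), g6, k = 2)
  expect_equal(vd, c(rep(1, 6), rep(0, 6)))

  expect_error(encode_tip(tip_point(99), g6), "outside")
  expect_error(encode_tip(tip_discrete(1), g6, thresholds = 5),
               "outside grid")
})

test_that("edge propagator matches the two-state closed form", {
  q <- 0.37
  Q <- matrix(c(-q, q, q, -q), 2, 2)
  for (t in c(0.2, 1, 4)) {
    P <- edge_propagator(Q, t)
    expect_equal(P[1, 1], (1 + exp(-2 * q * t)) / 2, tolerance = 1e-12)
    expect_equal(P[1, 2], (1 - exp(-2 * q * t)) / 2, tolerance = 1e-12)
  }
  expect_equal(edge_propagator(Q, 0), diag(2))
  # non-symmetric generator goes through the uniformized path
  Qa <- matrix(c(-1, 1, 0.2, -0.2), 2, 2, byrow = TRUE)
  P <- edge_propagator(Qa, 0.8)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-10)
  # exact 2-state general solution: P = pi + (I - pi) exp(-(a+b) t)
  a <- 1; b <- 0.2; t <- 0.8
  pi1 <- b / (a + b)
  expect_equal(P[1, 1], pi1 + (1 - pi1) * exp(-(a + b) * t),
               tolerance = 1e-9)
})

test_that("pruning agrees with hand computation and marginalizes", {
  # cherry, binary symmetric chain, both tips in state 1
  t1 <- 0.6; t2 <- 1.1; q <- 0.5
  Q <- matrix(c(-q, q, q, -q), 2, 2)
  tr <- cherry(t1, t2)
  tipL <- rbind(c(1, 0), c(1, 0))
  P1 <- (1 + exp(-2 * q * t1)) / 2
  P2 <- (1 + exp(-2 * q * t2)) / 2
  hand <- 0.5 * (P1 * P2 + (1 - P1) * (1 - P2))
  expect_equal(as.numeric(prune_loglik(tr, Q, tipL, "flat")), log(hand),
               tolerance = 1e-10)

  # zero-length pendant edge pins the tip state at the node
  tr0 <- parse_newick("(A:1e-12,B:1);", allow_zero = TRUE)
  g <- build_grid(-2, 2, 20)
  Qd <- generator_diffusion(g, 1)
  tipA <- encode_tip(tip_point(0.5), g)
  tipL0 <- rbind(tipA, rep(1, 20))
  b <- bin_index(g, 0.5)
  expect_equal(as.numeric(prune_loglik(tr0, Qd, tipL0, root_prior = b)),
               0, tolerance = 1e-6)

  # all-ambiguous tips: total probability is 1 for any generator
  tr5 <- simulate_pure_birth(12, 1, seed = 3)
  tipL1 <- matrix(1, 12, 20)
  expect_equal(as.numeric(prune_loglik(tr5, Qd, tipL1, "flat")), 0,
               tolerance = 1e-9)
  Qt <- generator_trend(g, 1, 0.7)
  expect_equal(as.numeric(prune_loglik(tr5, Qt, tipL1, "flat")), 0,
               tolerance = 1e-9)
})

test_that("pruning is invariant to child order and re-rooting", {
  # same unrooted metric tree rooted on two different edges
  r1 <- parse_newick("((A:1,B:1):0.5,C:1.0);")
  r2 <- parse_newick("((B:1,C:1.5):0.4,A:0.6);")
  g <- build_grid(-3, 3, 40)
  Q <- generator_diffusion(g, 0.8)
  obs <- list(A = tip_point(0.3), B = tip_point(-0.4),
              C = tip_point(1.1))
  l1 <- prune_loglik(r1, Q, encode_tips(obs, r1, g), "flat")
  l2 <- prune_loglik(r2, Q, encode_tips(obs, r2, g), "flat")
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-8)
  # child order swap
  r1s <- parse_newick("(C:1.0,(B:1,A:1):0.5);")
  l3 <- prune_loglik(r1s, Q, encode_tips(obs, r1s, g), "flat")
  expect_equal(as.numeric(l1), as.numeric(l3), tolerance = 1e-10)
})

test_that("probability-to-density back-transform", {
  expect_equal(loglik_density(log(0.01), 0.1, 2), log(1))
  expect_equal(loglik_density(log(0.37), 0.05, 0), log(0.37))
  # halving delta with p halved per point tip leaves the density fixed
  lp <- log(0.2)
  expect_equal(loglik_density(lp, 0.1, 1),
               loglik_density(lp + log(0.5), 0.05, 1))
  expect_error(loglik_density(0, 0.1, -1), "m must")
})

test_that("discretized density converges to the exact threshold probability", {
  # 3-taxon tree, fixed thresholds and root: dual route against the
  # nested-quadrature oracle
  tr <- parse_newick("((A:0.6,B:0.6):0.4,C:1.0);")
  thr <- c(0, 0.8)
  lv <- c(A = 1L, B = 2L, C = 3L)
  p_exact <- threshold_prob_exact(tr, thr, lv, root_liability = 0.2)
  errs <- sapply(c(201, 801), function(n) {
    g <- build_grid(-6, 6, n)
    Q <- generator_diffusion(g, 1)
    tipL <- t(sapply(c("A", "B", "C"), function(l)
      encode_tip(tip_discrete(lv[[l]]), g, thresholds = thr)))
    lp <- prune_loglik(tr, Q, tipL, root_prior = bin_index(g, 0.2))
    abs(exp(as.numeric(lp)) - p_exact)
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 1e-3)
})

test_that("tip tables map to observations", {
  df <- data.frame(taxon = c("A", "B", "C", "D"),
                   value = c(0.5, NA, 1, -1),
                   state = c(NA, "b", "a", NA),
                   censored = c(NA, NA, NA, "low"),
                   stringsAsFactors = FALSE)
  obs <- ddpcm:::tip_table_to_obs(df, levels = c("a", "b"))
  expect_equal(obs$A$kind, "point")
  expect_equal(obs$B$kind, "discrete")
  expect_equal(obs$C$kind, "joint")
  expect_equal(obs$C$level, 1L)
  expect_equal(obs$D$kind, "censored")
})
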