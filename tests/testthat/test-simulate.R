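test_that("Brownian simulator reproduces the tree's moment structure", {
  tr <- fig_tree_stem()
  set.seed(42)
  nrep <- 10000
  xs <- matrix(NA_real_, nrep, 2)
  for (r in seq_len(nrep)) xs[r, ] <- sim_bm(tr, 0, 0.8)[c("T1", "T2")]
  # target variances 0.80 / 0.56 and covariance 0.32; Monte-Carlo SEs of a
  # sample (co)variance are ~ sqrt(2) v / sqrt(n)
  expect_lt(abs(var(xs[, 1]) - 0.80), 3 * sqrt(2) * 0.8 / sqrt(nrep))
  expect_lt(abs(var(xs[, 2]) - 0.56), 3 * sqrt(2) * 0.56 / sqrt(nrep))
  expect_lt(abs(cov(xs[, 1], xs[, 2]) - 0.32), 0.03)

  expect_equal(unname(sim_bm(tr, 1.5, 0)), c(1.5, 1.5))
  expect_identical(sim_bm(tr, 0, 1, seed = 9), sim_bm(tr, 0, 1, seed = 9))
})

test_that("bounded simulator: stationary law and unbounded reduction", {
  # single long edge: after many relaxation times the tip is uniform
  tr <- parse_newick("(A:20,B:20);")
  x <- sim_bounded(tr, 0, sigma2 = 3, a = -2, b = 2, dt = 5e-3,
                   seed = 13, nrep = 3000)
  v <- var(as.vector(x))
  expect_lt(abs(v - 16 / 12), 4 * (16 / 12) * sqrt(0.8 / (2 * 3000)))
  expect_lt(abs(mean(x)), 4 * sqrt(16 / 12 / 6000))
  # very wide bounds: matches plain Brownian motion moments
  tr2 <- cherry(1, 1)
  xb <- sim_bounded(tr2, 0, 1, a = -50, b = 50, dt = 1e-3, seed = 14,
                    nrep = 3000)
  expect_lt(abs(var(xb[, 1]) - 1), 0.08)
  expect_lt(abs(cov(xb[, 1], xb[, 2])), 0.08)
  expect_error(sim_bounded(tr2, x0 = 3, a = -1, b = 1), "inside")
})

test_that("threshold simulator shares the Brownian stream", {
  tr <- simulate_pure_birth(40, 3, seed = 15)
  sim <- sim_threshold(tr, x0 = 0.5, thresholds = c(0, 0.8, 1), seed = 16)
  liab <- sim_bm(tr, x0 = 0.5, sigma2 = 1, seed = 16)
  expect_identical(sim$liability, liab)
  expect_identical(unname(sim$states),
                   letters[findInterval(liab, c(0, 0.8, 1)) + 1L])
  # single threshold at 0, x0 = 0: each level has marginal probability 1/2
  set.seed(17)
  ps <- replicate(400, mean(sim_threshold(cherry(), 0, 1, 0)$states == "a"))
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("semi-threshold simulator censors outside the window", {
  tr <- simulate_pure_birth(50, 1, seed = 18)
  tiny <- sim_semithreshold(tr, 0, sigma2 = 1e-8, clamp = c(-1, 1),
                            seed = 19)
  expect_true(all(is.na(tiny$obs$censored)))
  huge <- sim_semithreshold(tr, 0, sigma2 = 400, clamp = c(-1, 1),
                            seed = 20)
  expect_gt(mean(!is.na(huge$obs$censored)), 0.9)
  mid <- sim_semithreshold(tr, 0, 2, clamp = c(-1, 1), seed = 21)
  cen <- !is.na(mid$obs$censored)
  expect_true(all(abs(mid$obs$value[!cen]) < 1))
  expect_identical(mid$obs$censored[cen],
                   unname(ifelse(mid$liability[mid$obs$taxon[cen]] <= -1,
                                 "low", "high")))
})

test_that("Gillespie history simulator", {
  tr <- cherry(1, 1)
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h0 <- sim_mk_history(tr, Q0, root_level = 2, seed = 22)
  expect_true(all(h0$tip_states == "b"))
  expect_true(all(vapply(h0$edge_segments, nrow, 1L) == 1))

  q <- 0.8
  Qd <- matrix(c(-q, q, q, -q), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  set.seed(23)
  nrep <- 1500
  nochange <- tipa <- logical(nrep)
  for (r in seq_len(nrep)) {
    h <- sim_mk_history(tr, Qd, root_level = 1)
    segA <- h$edge_segments[[which(h$tree$edge[, 2] ==
                                     which(h$tree$tip.label == "A"))]]
    nochange[r] <- nrow(segA) == 1
    tipa[r] <- h$tip_states[["A"]] == "a"
  }
  # jump count on one edge is Poisson-free: P(no event) = exp(-q t)
  expect_lt(abs(mean(nochange) - exp(-q)),
            3 * sqrt(exp(-q) * (1 - exp(-q)) / nrep))
  # tip-level frequencies match the propagator marginal
  p_aa <- (1 + exp(-2 * q)) / 2
  expect_lt(abs(mean(tipa) - p_aa),
            3 * sqrt(p_aa * (1 - p_aa) / nrep))
})

test_that("state-dependent simulator has the right conditional moments", {
  tr <- cherry(1, 2)
  # hand-built history: A spends 0.4 in a then 0.6 in b; B all 2.0 in a
  h <- structure(list(
    edge_segments = list(
      data.frame(state = c("a", "b"), duration = c(0.4, 0.6)),
      data.frame(state = "a", duration = 2.0)),
    tip_states = c(A = "b", B = "a"),
    node_states = c("b", "a", "a"),
    levels = c("a", "b"),
    tree = ape::reorder.phylo(tr, "cladewise")), class = "ddpcm_history")
  set.seed(24)
  xs <- replicate(4000, sim_statedep(tr, h, c(a = 0.5, b = 4),
                                     mu_by_state = c(a = 1, b = -2),
                                     x0 = 1)["A"])
  expect_lt(abs(mean(xs) - (1 + 0.4 * 1 + 0.6 * (-2))), 0.1)
  expect_lt(abs(var(xs) - (0.4 * 0.5 + 0.6 * 4)), 0.2)
  # equal rates, zero trend: same law as plain Brownian motion
  xeq <- replicate(4000, sim_statedep(tr, h, c(a = 2, b = 2), x0 = 0)["B"])
  expect_lt(abs(var(xeq) - 2 * 2), 0.4)
})

test_that("x-dependent simulator limits", {
  tr <- cherry(1, 1)
  none <- make_sigmoid(0, 0, 0, 1)
  s <- sim_xdep(tr, 0, 1, none, none, level0 = "a", seed = 25)
  expect_true(all(s$states == "a"))
  # flat hazards: switch process is the constant-rate chain
  q <- 0.6
  flat <- make_sigmoid(q, q, 0, 0)
  set.seed(26)
  tips <- replicate(1200, sim_xdep(tr, 0, 1, flat, flat,
                                   level0 = "a")$states[["A"]])
  p_aa <- (1 + exp(-2 * q)) / 2
  expect_lt(abs(mean(tips == "a") - p_aa),
            3.5 * sqrt(p_aa * (1 - p_aa) / 1200))
})

test_that("simmap text round-trips a history", {
  tr <- simulate_pure_birth(8, 2, seed = 27)
  q <- 0.7
  Qd <- matrix(c(-q, q, q, -q), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  h <- sim_mk_history(tr, Qd, seed = 28)
  txt <- write_simmap(h)
  h2 <- read_simmap(txt)
  expect_identical(h2$tip_states[names(h$tip_states)], h$tip_states)
  d1 <- vapply(h$edge_segments, function(s) sum(s$duration), 1)
  d2 <- vapply(h2$edge_segments, function(s) sum(s$duration), 1)
  expect_equal(sort(d1), sort(d2), tolerance = 1e-8)
  # per-edge segment states survive the round trip
  po1 <- ape::reorder.phylo(h$tree, "postorder")
  expect_equal(sum(vapply(h$edge_segments, nrow, 1L)),
               sum(vapply(h2$edge_segments, nrow, 1L)))
})
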