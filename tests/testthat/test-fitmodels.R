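test_that("analytic Brownian fit: star-tree reduction and identities", {
  st <- star_tree(30, 1)
  set.seed(40)
  x <- setNames(rnorm(30, 2, 1.3), st$tip.label)
  f <- fit_bm_analytic(st, x)
  expect_equal(f$params$x0, mean(x), tolerance = 1e-10)
  expect_equal(f$params$sigma2, mean((x - mean(x))^2), tolerance = 1e-10)
  expect_equal(f$loglik,
               bm_logdensity(st, f$params$x0, f$params$sigma2, x),
               tolerance = 1e-10)
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)

  xc <- setNames(rep(1.7, 30), st$tip.label)
  fc <- fit_bm_analytic(st, xc)
  expect_equal(fc$params$sigma2, 0)
  expect_match(paste(fc$notes, collapse = ""), "boundary")
})

test_that("bounded fit with wide bounds recovers the unbounded likelihood", {
  tr <- simulate_pure_birth(20, 1, seed = 41)
  x <- sim_bm(tr, 0, 1.5, seed = 42)
  bounds <- range(x) + c(-10, 10)
  grid <- build_grid(bounds[1], bounds[2], 600)
  xs <- setNames(grid$centers[bin_index(grid, x)], names(x))  # snap
  fb <- suppressWarnings(fit_bounded_bm(tr, xs, bounds = bounds,
                                        n_bins = 600))
  fu <- fit_bm_analytic(tr, xs)
  expect_equal(fb$loglik, fu$loglik, tolerance = 0.05)
  expect_equal(fb$params$sigma2, fu$params$sigma2, tolerance = 0.1)
  expect_equal(fb$nparam, 2)  # fixed bounds are not free parameters

  w <- capture_warnings(fit_bounded_bm(cherry(), c(A = 0, B = 1),
                                       n_bins = 50))
  expect_true(any(grepl("fewer than 3", w)))
})

test_that("bounded-model recovery is unbiased where plain BM is biased down", {
  df <- run_study("bounded", n_reps = 20, n_taxa = 80, seed = 43,
                  n_bins = 100)
  expect_gte(nrow(df), 18)
  sl <- coef(lm(log(est_sigma2_bounded) ~ log(gen_sigma2), df))[2]
  expect_gt(sl, 0.85)
  expect_lt(sl, 1.15)
  # plain Brownian motion underestimates increasingly with sigma2
  hi <- df$gen_sigma2 > median(df$gen_sigma2)
  rel_bm <- df$est_sigma2_bm / df$gen_sigma2
  rel_bd <- df$est_sigma2_bounded / df$gen_sigma2
  expect_lt(median(rel_bm[hi]), 0.8)
  expect_gt(median(rel_bd[hi]), 0.7)
  expect_lt(median(rel_bm[hi]), median(rel_bd[hi]))
  expect_gt(mean(rel_bm[!hi]), mean(rel_bm[hi]))  # bias grows with rate
})

test_that("threshold fit: binary symmetry and threshold recovery scale", {
  tr <- simulate_pure_birth(80, 4, seed = 44)
  sim <- sim_threshold(tr, x0 = 0, sigma2 = 1, thresholds = 0, seed = 45)
  f <- fit_threshold(tr, sim$states, n_bins = 150)
  expect_equal(unname(f$params$thresholds), 0)
  expect_lt(abs(f$params$root_liability), 0.75)
  expect_equal(f$nparam, 1)
  expect_equal(f$params$sigma2, 1)

  expect_error(fit_threshold(tr, setNames(rep("a", 80), tr$tip.label)),
               "single observed level")
})

test_that("semi-threshold fit: censoring-free reduction and oracle convergence", {
  tr <- simulate_pure_birth(25, 1, seed = 46)
  x <- sim_bm(tr, 0, 0.8, seed = 47)
  obs <- data.frame(taxon = names(x), value = as.numeric(x),
                    censored = NA_character_)
  f <- fit_semithreshold(tr, obs, clamp = range(x) + c(-0.01, 0.01),
                         n_bins = 500)
  fu <- fit_bm_analytic(tr, x)
  expect_equal(f$params$sigma2, fu$params$sigma2, tolerance = 0.12)
  expect_equal(f$loglik, fu$loglik, tolerance = 0.35)

  # 4-taxon mixed observation: discretized density converges to the
  # nested-quadrature oracle as bins increase
  t4 <- parse_newick("((A:0.5,B:0.5):0.5,(C:0.7,D:0.7):0.3);")
  obs4 <- data.frame(taxon = c("A", "B", "C", "D"),
                     value = c(0.3, NA, -0.5, NA),
                     censored = c(NA, "high", NA, "low"))
  exact <- semithreshold_logdensity_exact(t4, 0, 1.2, c(-1, 1), obs4)
  errs <- sapply(c(101, 401), function(n) {
    g <- build_grid(-7, 7, n)
    Q <- generator_diffusion(g, 1.2)
    enc <- list(A = tip_point(0.3), B = tip_censored("high", at = 1),
                C = tip_point(-0.5), D = tip_censored("low", at = -1))
    tipL <- encode_tips(enc, t4, g)
    lp <- prune_loglik(t4, Q, tipL, root_prior = bin_index(g, 0))
    ld <- loglik_density(lp, g$delta, 2)
    # compare against the oracle evaluated at the snapped point values
    obs_s <- obs4
    ok <- !is.na(obs_s$value)
    obs_s$value[ok] <- g$centers[bin_index(g, obs_s$value[ok])]
    exact_s <- semithreshold_logdensity_exact(t4, 0, 1.2, c(-1, 1), obs_s)
    abs(ld - exact_s)
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)

  obs_one <- data.frame(taxon = names(x), value = NA_real_,
                        censored = "high")
  expect_error(fit_semithreshold(tr, obs_one, clamp = c(-1, 1)),
               "unidentifiable")
})

test_that("Mk fits match a brute-force grid search and constraints", {
  tr <- parse_newick("((A:0.5,B:0.5):0.5,(C:0.7,D:0.7):0.3);")
  y <- c(A = "0", B = "0", C = "1", D = "1")
  f <- fit_mk(tr, y, "ER")
  # brute force over q with exact 2-state propagators
  qs <- exp(seq(-6, 3, length.out = 4000))
  lls <- vapply(qs, function(q) {
    Q <- matrix(c(-q, q, q, -q), 2, 2)
    tipL <- matrix(0, 4, 2)
    tipL[cbind(1:4, match(y[tr$tip.label], c("0", "1")))] <- 1
    as.numeric(prune_loglik(tr, Q, tipL, "flat"))
  }, numeric(1))
  qhat_grid <- qs[which.max(lls)]
  expect_equal(f$params$rates[[1]], qhat_grid, tolerance = 0.02)
  expect_equal(f$loglik, max(lls), tolerance = 1e-4)

  # ordered variants keep non-adjacent rates at zero
  tr2 <- simulate_pure_birth(60, 3, seed = 48)
  sim <- sim_threshold(tr2, x0 = 0.8, thresholds = c(0, 0.8, 1),
                       seed = 49)
  lev <- sort(unique(sim$states))
  if (length(lev) >= 3) {
    fo <- fit_mk(tr2, sim$states, "ordered-asym", levels = lev)
    Qo <- fo$params$Q
    far <- abs(row(Qo) - col(Qo)) > 1
    expect_true(all(Qo[far] == 0))
    expect_equal(fo$nparam, 2 * (length(lev) - 1))
  }

  # monomorphic data with declared levels: rate collapses to zero
  ym <- setNames(rep("0", 4), tr$tip.label)
  fm <- fit_mk(tr, ym, "ER", levels = c("0", "1"))
  expect_lt(fm$params$rates[[1]], 0.01)
})

test_that("Akaike weights", {
  mk_fit <- function(ll, k, id = "d")
    ddpcm:::new_fit("m", list(), ll, k, data_id = id)
  w <- akaike_weights(list(a = mk_fit(-10, 2), b = mk_fit(-10, 2)))
  expect_equal(unname(w), c(0.5, 0.5))
  w2 <- akaike_weights(list(a = mk_fit(-10, 2), b = mk_fit(-10, 3)))
  expect_equal(unname(w2), c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  set.seed(50)
  lls <- rnorm(4, -20, 3)
  w3 <- akaike_weights(lapply(lls, mk_fit, k = 3))
  expect_equal(sum(w3), 1)
  expect_error(akaike_weights(list(mk_fit(-1, 1, "x"), mk_fit(-1, 1, "y"))),
               "fingerprints")
})

test_that("maximized likelihoods nest across model families", {
  set.seed(51)
  tr <- make_nonultrametric(simulate_pure_birth(50, depth = 2, seed = 52),
                            seed = 53)
  q <- 1.5
  Qd <- matrix(c(-q, q, q, -q), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  h <- sim_mk_history(tr, Qd, seed = 54)
  x <- sim_statedep(tr, h, c(a = 0.5, b = 3), x0 = 0, seed = 55)
  y <- h$tip_states
  nb <- 60
  fsd <- fit_statedep_bm(tr, y, x, n_bins = nb, restarts = 1)
  fmt <- fit_multitrend(tr, y, x, n_bins = nb, restarts = 1)
  f1 <- fit_joint_single_sigma(tr, y, x, n_bins = nb)
  # richer families cannot do worse than their nested special cases
  expect_gte(fmt$loglik, fsd$loglik - 0.05)
  expect_gte(fsd$loglik, f1$loglik - 0.05)
  fx <- fit_xdep_mk(tr, x, y, n_bins = nb, restarts = 1)
  expect_gte(fx$loglik, f1$loglik - 0.05)
  # multitrend on an ultrametric tree warns about mu/x0 confounding
  tru <- simulate_pure_birth(20, 1, seed = 56)
  hu <- sim_mk_history(tru, Qd, seed = 57)
  xu <- sim_statedep(tru, hu, c(a = 1, b = 1), x0 = 0, seed = 58)
  expect_warning(fit_multitrend(tru, hu$tip_states, xu, n_bins = 50,
                                restarts = 0),
                 "non-identifiable")
})

test_that("equal-rate truth: state-dependent fit stays near the single rate", {
  set.seed(59)
  lr <- replicate(4, {
    tr <- simulate_pure_birth(50, 1)
    q <- 2
    Qd <- matrix(c(-q, q, q, -q), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    h <- sim_mk_history(tr, Qd)
    if (length(unique(h$tip_states)) < 2) return(NA_real_)
    x <- sim_statedep(tr, h, c(a = 1.2, b = 1.2), x0 = 0)
    fsd <- fit_statedep_bm(tr, h$tip_states, x, n_bins = 60,
                           restarts = 1)
    f1 <- fit_joint_single_sigma(tr, h$tip_states, x, n_bins = 60)
    2 * (fsd$loglik - f1$loglik)
  })
  lr <- lr[!is.na(lr)]
  expect_true(all(lr > -0.2))        # nesting, up to optimizer noise
  expect_lt(median(lr), 5)           # no spurious rate difference
})

test_that("x-dependent fit recovers the generating curves qualitatively", {
  tr <- simulate_pure_birth(400, depth = 3, seed = 53)
  pab <- make_sigmoid(0.2, 2, 0, -1.5)
  pba <- make_sigmoid(0.2, 2, 0, 1.5)
  sim <- sim_xdep(tr, x0 = 0, sigma2 = 1, p_ab = pab, p_ba = pba,
                  seed = 54)
  # the generating curves induce an association: b at low x, a at high x
  expect_gt(mean(sim$x[sim$states == "a"]), mean(sim$x[sim$states == "b"]))
  set.seed(55)
  f <- fit_xdep_mk(tr, sim$x, sim$states, n_bins = 80)
  expect_equal(f$params$sigma2, 1, tolerance = 0.5)
  xs <- seq(-2, 2, 0.5)
  est_ab <- sigmoid_rate(xs, f$params$p_ab)
  est_ba <- sigmoid_rate(xs, f$params$p_ba)
  # monotonicity directions match the generating steepness signs
  expect_lt(est_ab[9], est_ab[1])
  expect_gt(est_ba[9], est_ba[1])
  # curve error threshold frozen from a reference run of this scenario
  expect_lt(sqrt(mean((est_ab - sigmoid_rate(xs, pab))^2)), 0.6)
  expect_lt(sqrt(mean((est_ba - sigmoid_rate(xs, pba))^2)), 0.6)
})
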