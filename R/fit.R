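new_fit <- function(model, params, loglik, nparam, convergence = TRUE,
                    restarts = 0, grid = NULL, data_id = NULL,
                    notes = character()) {
  structure(list(model = model, params = params, loglik = loglik,
                 nparam = nparam, aic = 2 * nparam - 2 * loglik,
                 convergence = convergence, restarts = restarts,
                 grid = grid, data_id = data_id, notes = notes),
            class = "ddpcm_fit")
}

#' @export
print.ddpcm_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AIC = %.4f%s\n", x$model,
              x$loglik, x$nparam, x$aic,
              if (!isTRUE(x$convergence)) " (not converged)" else ""))
  print(signif(unlist(x$params), 5))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
logLik.ddpcm_fit <- function(object, ...) {
  structure(object$loglik, df = object$nparam, class = "logLik")
}

#' @export
coef.ddpcm_fit <- function(object, ...) unlist(object$params)

.data_id <- function(tree, x = NULL, y = NULL) {
  paste(length(tree$tip.label),
        format(sum(tree$edge.length), digits = 12),
        if (!is.null(x)) format(sum(as.numeric(x)), digits = 12) else "",
        if (!is.null(y)) paste(sort(as.character(y)), collapse = "") else "",
        sep = "|")
}

# Robust 1-D minimization: coarse scan over the interval to locate the
# basin (profile likelihoods can have flat high-rate plateaus that defeat
# golden-section search), then a local optimize() within the bracket.
.scan_optimize <- function(obj, interval, n_scan = 21, tol = 1e-6) {
  xs <- seq(interval[1], interval[2], length.out = n_scan)
  vs <- vapply(xs, obj, numeric(1))
  i <- which.min(vs)
  op <- stats::optimize(obj, c(xs[max(1, i - 1)], xs[min(n_scan, i + 1)]),
                        tol = tol)
  if (vs[i] < op$objective) list(minimum = xs[i], objective = vs[i])
  else op
}

# Nelder-Mead with random restarts on an unconstrained (transformed)
# parameter vector; returns the best minimum found.
.nm_optim <- function(par0, fn, restarts = 2, jitter = 0.5, maxit = 1000) {
  best <- NULL
  for (r in 0:restarts) {
    p0 <- if (r == 0) par0
          else par0 + stats::rnorm(length(par0), 0, jitter)
    o <- tryCatch(
      if (length(par0) == 1)
        stats::optim(p0, fn, method = "Brent", lower = p0 - 15,
                     upper = p0 + 15)
      else
        stats::optim(p0, fn, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed in every restart")
  list(par = best$par, value = best$value,
       converged = best$convergence == 0, restarts = restarts)
}

# Profile log-density for a continuous-trait generator: root bin profiled
# at its ML value, probability back-transformed to a density over the m
# point-valued tips.
.profile_logdens <- function(tree, Q, tipL, m, delta) {
  lp <- prune_loglik(tree, Q, tipL, "ml-bin")
  structure(loglik_density(lp, delta, m),
            root_bin = attr(lp, "root_bin"),
            root_value = attr(lp, "root_value"))
}

#' Analytic maximum-likelihood fit of unbounded Brownian motion
#'
#' Closed-form GLS estimates of `sigma2` and `x0` under the multivariate
#' normal likelihood \eqn{x \sim \mathrm{MVN}(x_0 1, \sigma^2 C)}.
#'
#' @param tree A `"phylo"` object.
#' @param x Named tip values.
#' @return A `"ddpcm_fit"`.
#' @export
fit_bm_analytic <- function(tree, x) {
  N <- length(tree$tip.label)
  if (N < 3) warning("fewer than 3 tips: estimates are unreliable")
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular covariance (duplicate zero-length tips?)"))
  Ci <- chol2inv(ch)
  one <- rep(1, N)
  x0 <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  r <- x - x0
  s2 <- as.numeric(r %*% Ci %*% r) / N
  ll <- if (s2 > 0)
    -0.5 * (N * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + N)
  else NA_real_
  new_fit("bm", list(sigma2 = s2, x0 = x0), ll, 2,
          data_id = .data_id(tree, x),
          notes = if (s2 == 0) "sigma2 at zero boundary" else character())
}

#' Fit bounded Brownian motion by the discretized diffusion approximation
#'
#' The trait interval between the bounds is binned, the reflective
#' diffusion generator built, and the log-density maximized over
#' \eqn{\sigma^2} (1-D search on the log scale) with the root state
#' profiled over bins. By default the bounds are set to the observed trait
#' range, which is their maximum-likelihood estimate; pass fixed `bounds`
#' to override (then only `sigma2` and `x0` count as free parameters).
#'
#' @param tree A `"phylo"` object (>= 3 tips recommended).
#' @param x Named tip values.
#' @param bounds Optional fixed `(a, b)`; default the observed range.
#' @param n_bins Number of bins (default 200).
#' @param boundary Boundary convention (see [generator_diffusion()]).
#' @return A `"ddpcm_fit"` with estimates `sigma2`, `x0`, `a`, `b`.
#' @export
fit_bounded_bm <- function(tree, x, bounds = NULL, n_bins = 200,
                           boundary = "reassign") {
  N <- length(tree$tip.label)
  if (N < 3) warning("fewer than 3 tips: estimates are unreliable")
  est_bounds <- is.null(bounds)
  if (est_bounds) bounds <- range(x)
  if (any(x < bounds[1]) || any(x > bounds[2]))
    stop("data outside the supplied bounds")
  grid <- build_grid(bounds[1], bounds[2], n_bins)
  tipL <- t(vapply(tree$tip.label,
                   function(l) encode_tip(tip_point(x[[l]]), grid),
                   numeric(grid$n)))
  anchor <- fit_bm_analytic(tree, x)$params$sigma2
  if (!is.finite(anchor) || anchor <= 0) anchor <- stats::var(x) + 1e-8
  obj <- function(ls2) {
    Q <- generator_diffusion(grid, exp(ls2), boundary)
    -.profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
  }
  op <- .scan_optimize(obj, log(anchor) + c(-7, 7))
  s2 <- exp(op$minimum)
  Q <- generator_diffusion(grid, s2, boundary)
  ld <- .profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
  new_fit("bounded_bm",
          list(sigma2 = s2, x0 = attr(ld, "root_value"),
               a = bounds[1], b = bounds[2]),
          as.numeric(ld), nparam = 2 + 2 * est_bounds, grid = grid,
          data_id = .data_id(tree, x))
}

#' Fit the multi-state threshold model
#'
#' Liability evolves by Brownian motion with \eqn{\sigma^2} fixed at 1 (the
#' liability scale is arbitrary) and the first threshold fixed at 0; the
#' remaining thresholds are estimated as ordered log-increments and the
#' root liability is profiled over grid bins. The liability generator does
#' not depend on the thresholds, so its eigendecomposition is computed once
#' per fit and reused for every optimizer evaluation.
#'
#' @param tree A `"phylo"` object.
#' @param states Named character vector of tip states.
#' @param levels Ordered level names (default: sorted unique states; order
#'   defines the threshold ordering).
#' @param n_bins Number of liability bins (default 200).
#' @param grid Optional `"trait_grid"` for the liability space; default
#'   spans +/- 6 sqrt(depth) around 0.
#' @param restarts Optimizer restarts (default 2).
#' @return A `"ddpcm_fit"` with the free thresholds and root liability.
#' @export
fit_threshold <- function(tree, states, levels = NULL, n_bins = 200,
                          grid = NULL, restarts = 2) {
  states <- states[tree$tip.label]
  if (length(unique(states)) < 2)
    stop("single observed level: the threshold model has no information")
  if (is.null(levels)) levels <- sort(unique(states))
  L <- length(levels)
  if (is.null(grid)) {
    Tdep <- tree_depth(tree)
    h <- 6 * sqrt(Tdep)
    grid <- build_grid(-h, h, n_bins)
  }
  Q <- generator_diffusion(grid, 1)
  dec <- ctmc_decompose(Q)
  lev_idx <- match(states, levels)
  encode <- function(thr) {
    t(vapply(seq_along(lev_idx), function(i)
      encode_tip(tip_discrete(lev_idx[i]), grid, thresholds = thr),
      numeric(grid$n)))
  }
  nfree <- L - 2
  obj <- function(eta) {
    thr <- cumsum(c(0, exp(eta)))
    if (max(thr) > grid$hi - 2 * grid$delta) return(1e10)
    -as.numeric(prune_loglik(tree, dec, encode(thr), "ml-bin"))
  }
  if (nfree > 0) {
    op <- .nm_optim(rep(log(0.5), nfree), obj, restarts = restarts)
    thr <- cumsum(c(0, exp(op$par)))
    converged <- op$converged
  } else {
    thr <- 0
    converged <- TRUE
  }
  lp <- prune_loglik(tree, dec, encode(thr), "ml-bin")
  names(thr) <- paste(levels[-L], levels[-1], sep = "|")
  new_fit("threshold",
          list(thresholds = thr, root_liability = attr(lp, "root_value"),
               sigma2 = 1),
          as.numeric(lp), nparam = nfree + 1, grid = grid,
          convergence = converged, restarts = restarts,
          data_id = .data_id(tree, y = states))
}

#' Fit the semi-threshold (censored Brownian) model
#'
#' Tips inside the observable window contribute densities, clamped tips
#' contribute semi-infinite interval probabilities; \eqn{\sigma^2} is found
#' by 1-D search on the log scale with `x0` profiled over bins. The grid
#' extends past the clamps by a margin tied to the current rate estimate
#' and is enlarged and refit (up to twice) if the fitted rate implies the
#' margin was too small.
#'
#' @param tree A `"phylo"` object.
#' @param obs Data frame with `taxon`, `value`, `censored` columns (see
#'   [sim_semithreshold()]).
#' @param clamp Observable window `(low, high)`.
#' @param n_bins Number of bins (default 200).
#' @return A `"ddpcm_fit"` with `sigma2` and `x0`.
#' @export
fit_semithreshold <- function(tree, obs, clamp, n_bins = 200) {
  obs <- obs[match(tree$tip.label, obs$taxon), ]
  cen <- !is.na(obs$censored) & nzchar(obs$censored)
  if (all(cen) && length(unique(obs$censored[cen])) == 1)
    stop("all tips censored to the same side: sigma2 is unidentifiable")
  Tdep <- tree_depth(tree)
  xfill <- ifelse(cen, ifelse(obs$censored == "low", clamp[1], clamp[2]),
                  obs$value)
  names(xfill) <- obs$taxon
  s2a <- max(fit_bm_analytic(tree, xfill)$params$sigma2, 1e-4)
  N <- length(tree$tip.label)
  m <- sum(!cen)
  fit_once <- function(pad) {
    grid <- build_grid(clamp[1] - pad, clamp[2] + pad, n_bins)
    tipL <- t(vapply(seq_len(N), function(i) {
      o <- if (cen[i]) tip_censored(obs$censored[i],
                                    at = if (obs$censored[i] == "low")
                                      clamp[1] else clamp[2])
           else tip_point(obs$value[i])
      encode_tip(o, grid)
    }, numeric(grid$n)))
    obj <- function(ls2) {
      Q <- generator_diffusion(grid, exp(ls2))
      -.profile_logdens(tree, Q, tipL, m = m, delta = grid$delta)
    }
    op <- .scan_optimize(obj, log(s2a) + c(-5, 8))
    list(grid = grid, s2 = exp(op$minimum), tipL = tipL)
  }
  pad <- max(8 * sqrt(s2a * Tdep), diff(clamp))
  for (i in 1:3) {
    res <- fit_once(pad)
    need <- 4 * sqrt(res$s2 * Tdep)
    if (need <= pad || i == 3) break
    pad <- 1.5 * need
  }
  grid <- res$grid
  Q <- generator_diffusion(grid, res$s2)
  ld <- .profile_logdens(tree, Q, res$tipL, m = m, delta = grid$delta)
  new_fit("semithreshold",
          list(sigma2 = res$s2, x0 = attr(ld, "root_value"),
               clamp_low = clamp[1], clamp_high = clamp[2]),
          as.numeric(ld), nparam = 2, grid = grid,
          data_id = .data_id(tree, x = xfill))
}

#' Fit an Mk model of discrete character evolution
#'
#' Variants: `"ER"` (one rate, all transitions), `"ordered-sym"`
#' (nearest-level moves only, one symmetric rate per adjacent pair) and
#' `"ordered-asym"` (nearest-level moves with distinct up and down rates).
#' The root prior is flat over levels.
#'
#' @param tree A `"phylo"` object.
#' @param y Named character vector of tip states.
#' @param variant One of `"ER"`, `"ordered-sym"`, `"ordered-asym"`.
#' @param levels Ordered level names (default sorted unique states).
#' @param restarts Optimizer restarts (default 2).
#' @return A `"ddpcm_fit"`; `params$Q` holds the fitted rate matrix.
#' @export
fit_mk <- function(tree, y, variant = c("ER", "ordered-sym",
                                        "ordered-asym"),
                   levels = NULL, restarts = 2) {
  variant <- match.arg(variant)
  y <- y[tree$tip.label]
  if (is.null(levels)) levels <- sort(unique(y))
  L <- length(levels)
  if (L < 2) stop("need at least 2 levels")
  tipL <- matrix(0, length(y), L)
  tipL[cbind(seq_along(y), match(y, levels))] <- 1
  build_Q <- function(logr) {
    r <- exp(logr)
    Q <- matrix(0, L, L, dimnames = list(levels, levels))
    if (variant == "ER") {
      Q[row(Q) != col(Q)] <- r[1]
    } else {
      for (i in seq_len(L - 1)) {
        up <- if (variant == "ordered-sym") r[i] else r[i]
        dn <- if (variant == "ordered-sym") r[i] else r[L - 1 + i]
        Q[i, i + 1] <- up
        Q[i + 1, i] <- dn
      }
    }
    diag(Q) <- -rowSums(Q)
    Q
  }
  np <- switch(variant, ER = 1L, `ordered-sym` = L - 1L,
               `ordered-asym` = 2L * (L - 1L))
  obj <- function(logr) {
    if (any(logr > 12) || any(logr < -14)) return(1e10)
    -as.numeric(prune_loglik(tree, build_Q(logr), tipL, "flat"))
  }
  q0 <- log(max(L / sum(tree$edge.length) * 4, 1e-3))
  if (np == 1) {
    op <- .scan_optimize(obj, q0 + c(-10, 10), n_scan = 31, tol = 1e-7)
    par <- op$minimum
    value <- op$objective
    converged <- TRUE
  } else {
    # warm start from the nested simpler model (one shared ordered rate;
    # for the asymmetric variant, the symmetric MLE duplicated): a cold
    # multi-rate Nelder-Mead can stall and understate this competitor in
    # model comparisons
    op1 <- .scan_optimize(function(l) obj(rep(l, np)), q0 + c(-10, 10),
                          n_scan = 31)
    par0 <- rep(op1$minimum, np)
    if (variant == "ordered-asym") {
      fs <- fit_mk(tree, y, "ordered-sym", levels = levels,
                   restarts = max(1, restarts - 1))
      par0 <- log(pmax(rep(fs$params$rates, 2), 1e-6))
    }
    o <- .nm_optim(par0, obj, restarts = restarts)
    par <- o$par; value <- o$value; converged <- o$converged
    v0 <- obj(par0)
    if (v0 < value) { par <- par0; value <- v0 }  # never below the start
  }
  Q <- build_Q(par)
  new_fit(paste0("mk-", variant),
          list(rates = stats::setNames(exp(par), paste0("r", seq_len(np))),
               Q = Q),
          -value, nparam = np, convergence = converged,
          restarts = restarts, data_id = .data_id(tree, y = y))
}

#' Fit discrete-state dependent multi-rate Brownian motion jointly
#'
#' Joint generator over (level, bin) states: per-level diffusion rates
#' \eqn{\sigma_i^2} and the discrete transition rate `q` (equal forward and
#' backward rates by default) are estimated together; `x0` is profiled
#' over bins under a root prior flat across levels.
#'
#' @param tree A `"phylo"` object.
#' @param y Named tip states (k >= 2 observed levels).
#' @param x Named tip values.
#' @param n_bins Bins for the continuous trait (default 200).
#' @param padding Grid padding factor (default 0.5 of the observed range).
#' @param q_model `"equal"` (q_ab = q_ba, default) or `"ARD"`.
#' @param restarts Optimizer restarts (default 2).
#' @return A `"ddpcm_fit"` with per-level `sigma2`, `q`, `x0`.
#' @export
fit_statedep_bm <- function(tree, y, x, n_bins = 200, padding = 0.5,
                            q_model = c("equal", "ARD"), restarts = 2) {
  q_model <- match.arg(q_model)
  y <- y[tree$tip.label]; x <- x[tree$tip.label]
  levels <- sort(unique(y))
  k <- length(levels)
  if (k < 2) stop("need at least 2 observed levels")
  grid <- default_grid(x, n_bins, padding)
  N <- length(x)
  obs <- lapply(seq_len(N), function(i)
    tip_joint(match(y[i], levels), x[[i]]))
  names(obs) <- tree$tip.label
  tipL <- encode_tips(obs, tree, grid, k = k)
  Tdep <- tree_depth(tree)
  nq <- if (q_model == "equal") 1L else k * (k - 1L)
  s2_init <- vapply(levels, function(l)
    max(stats::var(x[y == l]) / Tdep, 1e-4), numeric(1))
  if (anyNA(s2_init)) s2_init[is.na(s2_init)] <- stats::var(x) / Tdep
  q_init <- fit_mk(tree, y, "ER", levels = levels,
                   restarts = 0)$params$rates[[1]]
  par0 <- c(log(s2_init), rep(log(max(q_init, 1e-3)), nq))
  build_Q <- function(par) {
    s2 <- exp(par[seq_len(k)])
    qr <- exp(par[k + seq_len(nq)])
    qd <- matrix(0, k, k)
    if (q_model == "equal") qd[row(qd) != col(qd)] <- qr[1]
    else qd[row(qd) != col(qd)] <- qr
    generator_joint(grid, s2, qd, level_names = levels)
  }
  obj <- function(par) {
    if (any(abs(par) > 20)) return(1e10)
    -.profile_logdens(tree, build_Q(par), tipL, m = N,
                      delta = grid$delta)
  }
  o <- .nm_optim(par0, obj, restarts = restarts, jitter = 0.7)
  s2 <- stats::setNames(exp(o$par[seq_len(k)]), paste0("sigma2_", levels))
  qr <- exp(o$par[k + seq_len(nq)])
  ld <- .profile_logdens(tree, build_Q(o$par), tipL, m = N,
                         delta = grid$delta)
  notes <- character()
  if (any(!levels %in% y)) notes <- "level with no tips: rate weakly identified"
  new_fit("statedep_bm",
          c(as.list(s2), list(q = qr, x0 = attr(ld, "root_value"))),
          as.numeric(ld), nparam = k + nq + 1, grid = grid,
          convergence = o$converged, restarts = restarts,
          data_id = .data_id(tree, x = x, y = y), notes = notes)
}

#' Fit the discrete-state dependent multi-trend Brownian model
#'
#' Adds per-level linear trends \eqn{\mu_i} to the joint model; the
#' non-negativity constraint on the birth-death-chain rates
#' (\eqn{|\mu_i| \le \sigma_i^2/\delta}) is enforced by construction
#' through a scaled-tanh reparameterization
#' (\eqn{\mu_i = 0.99\,(\sigma_i^2/\delta)\tanh m_i}). A warning is issued
#' for ultrametric trees, on which `mu` and `x0` are mutually
#' non-identifiable.
#'
#' @inheritParams fit_statedep_bm
#' @return A `"ddpcm_fit"` with per-level `sigma2` and `mu`, `q`, `x0`.
#' @export
fit_multitrend <- function(tree, y, x, n_bins = 200, padding = 0.5,
                           restarts = 2) {
  y <- y[tree$tip.label]; x <- x[tree$tip.label]
  levels <- sort(unique(y))
  k <- length(levels)
  if (k < 2) stop("need at least 2 observed levels")
  if (ape::is.ultrametric(tree, tol = 1e-8))
    warning("tree is ultrametric: mu and x0 are mutually non-identifiable")
  N <- length(x)
  obs <- lapply(seq_len(N), function(i)
    tip_joint(match(y[i], levels), x[[i]]))
  names(obs) <- tree$tip.label
  Tdep <- tree_depth(tree)
  s2_init <- vapply(levels, function(l)
    max(stats::var(x[y == l]) / Tdep, 1e-4), numeric(1))
  q_init <- fit_mk(tree, y, "ER", levels = levels,
                   restarts = 0)$params$rates[[1]]
  # naive trend init: overall regression of tip value on tip height
  h <- node_heights(tree)[tree$tip.label]
  sl <- if (stats::var(h) > 1e-10) stats::cov(h, x) / stats::var(h) else 0
  # objective on a given grid; parameters are physical so stages with
  # different grids share them
  make_obj <- function(grid) {
    d <- grid$delta
    tipL <- encode_tips(obs, tree, grid, k = k)
    unpack <- function(par) {
      s2 <- exp(par[seq_len(k)])
      mu <- 0.99 * (s2 / d) * tanh(par[k + seq_len(k)])
      list(s2 = s2, mu = mu, q = exp(par[2 * k + 1]))
    }
    pack <- function(s2, mu, q) {
      b <- 0.99 * s2 / d
      c(log(s2), atanh(pmax(pmin(mu / b, 0.999), -0.999)),
        log(max(q, 1e-6)))
    }
    obj <- function(par) {
      if (any(abs(par[c(seq_len(k), 2 * k + 1)]) > 20) ||
          any(abs(par[k + seq_len(k)]) > 12)) return(1e10)
      p <- unpack(par)
      qd <- matrix(p$q, k, k); diag(qd) <- 0
      Q <- generator_joint(grid, p$s2, qd, mu_by_state = p$mu,
                           level_names = levels)
      -.profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
    }
    list(obj = obj, unpack = unpack, pack = pack, tipL = tipL)
  }
  # stage 1: global search on a coarse grid; stage 2: polish on the full
  # grid from the stage-1 optimum
  grid1 <- default_grid(x, max(80L, n_bins %/% 2L), padding)
  st1 <- make_obj(grid1)
  mu0 <- rep(sl, k)
  o1 <- .nm_optim(st1$pack(s2_init, mu0, q_init), st1$obj,
                  restarts = restarts, jitter = 0.6, maxit = 600)
  p1 <- st1$unpack(o1$par)
  grid <- default_grid(x, n_bins, padding)
  st2 <- make_obj(grid)
  o <- stats::optim(st2$pack(p1$s2, p1$mu, p1$q), st2$obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 800, reltol = 1e-9))
  o <- list(par = o$par, value = o$value,
            converged = o$convergence == 0, restarts = restarts)
  p <- st2$unpack(o$par)
  tipL <- st2$tipL
  qd <- matrix(p$q, k, k); diag(qd) <- 0
  Q <- generator_joint(grid, p$s2, qd, mu_by_state = p$mu,
                       level_names = levels)
  ld <- .profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
  notes <- character()
  if (any(abs(tanh(o$par[k + seq_len(k)])) > 0.98))
    notes <- "trend constraint active: |mu| at the sigma2/delta box"
  new_fit("multitrend",
          c(as.list(stats::setNames(p$s2, paste0("sigma2_", levels))),
            as.list(stats::setNames(p$mu, paste0("mu_", levels))),
            list(q = p$q, x0 = attr(ld, "root_value"))),
          as.numeric(ld), nparam = 2 * k + 2, grid = grid,
          convergence = o$converged, restarts = restarts,
          data_id = .data_id(tree, x = x, y = y), notes = notes)
}

#' Fit continuous-character dependent discrete trait evolution
#'
#' Binary discrete trait whose switch rates vary with the continuous trait
#' through two four-parameter sigmoid curves (lower and upper asymptote,
#' midpoint, steepness per direction), plus a shared diffusion rate.
#' Asymptotes are optimized on the log scale; `x0` is profiled.
#'
#' @param tree A `"phylo"` object.
#' @param x Named tip values.
#' @param y Named binary tip states.
#' @param n_bins Bins (default 100; this is the heaviest model).
#' @param padding Grid padding factor.
#' @param restarts Optimizer restarts (default 2; initial steepness signs
#'   are alternated across restarts).
#' @return A `"ddpcm_fit"` with `sigma2` and the two sigmoid curves.
#' @export
fit_xdep_mk <- function(tree, x, y, n_bins = 100, padding = 0.5,
                        restarts = 2) {
  y <- y[tree$tip.label]; x <- x[tree$tip.label]
  levels <- sort(unique(y))
  if (length(levels) != 2) stop("y must be binary")
  grid <- default_grid(x, n_bins, padding)
  N <- length(x)
  obs <- lapply(seq_len(N), function(i)
    tip_joint(match(y[i], levels), x[[i]]))
  names(obs) <- tree$tip.label
  tipL <- encode_tips(obs, tree, grid, k = 2)
  Tdep <- tree_depth(tree)
  s2_init <- max(fit_bm_analytic(tree, x)$params$sigma2, 1e-4)
  q_init <- max(fit_mk(tree, y, "ER", restarts = 0)$params$rates[[1]],
                1e-3)
  sx <- stats::sd(x)
  # par = (log s2, log lo_ab, log up_ab, mid_ab, steep_ab, ... _ba)
  par0 <- c(log(s2_init),
            log(q_init), log(q_init), stats::median(x), 1 / sx,
            log(q_init), log(q_init), stats::median(x), -1 / sx)
  unpack <- function(par) {
    list(s2 = exp(par[1]),
         p_ab = make_sigmoid(exp(par[2]), exp(par[3]), par[4], par[5]),
         p_ba = make_sigmoid(exp(par[6]), exp(par[7]), par[8], par[9]))
  }
  obj <- function(par) {
    if (any(abs(par[c(1:3, 6:7)]) > 20)) return(1e10)
    p <- unpack(par)
    Q <- generator_xdep(grid, p$s2, p$p_ab, p$p_ba)
    -.profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
  }
  best <- NULL
  for (r in 0:restarts) {
    p0 <- par0
    if (r %% 2 == 1) { p0[5] <- -p0[5]; p0[9] <- -p0[9] }
    if (r > 1) p0 <- p0 + stats::rnorm(length(p0), 0, 0.4)
    o <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000,
                                              reltol = 1e-8)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimization failed")
  p <- unpack(best$par)
  Q <- generator_xdep(grid, p$s2, p$p_ab, p$p_ba)
  ld <- .profile_logdens(tree, Q, tipL, m = N, delta = grid$delta)
  notes <- character()
  if (abs(p$p_ab$steepness) * sx < 0.1 ||
      abs(p$p_ba$steepness) * sx < 0.1)
    notes <- "near-flat fitted curve: asymptotes weakly identified"
  new_fit("xdep_mk",
          list(sigma2 = p$s2, p_ab = p$p_ab, p_ba = p$p_ba,
               x0 = attr(ld, "root_value")),
          as.numeric(ld), nparam = 10,
          convergence = best$convergence == 0, restarts = restarts,
          grid = grid, data_id = .data_id(tree, x = x, y = y),
          notes = notes)
}

#' Akaike weights for a set of fits on the same data
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}.
#'
#' @param fits List of `"ddpcm_fit"` objects fitted to identical data.
#' @return Named numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  ids <- vapply(fits, function(f) f$data_id %||% NA_character_, "")
  if (length(unique(ids[!is.na(ids)])) > 1)
    stop("mismatched data fingerprints: fits are not on identical data")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  nm <- names(fits) %||% vapply(fits, function(f) f$model, "")
  d <- aic - min(aic)
  w <- exp(-d / 2)
  stats::setNames(w / sum(w), nm)
}
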