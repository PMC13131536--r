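# k-state pruning that keeps every node's partial-likelihood vector and
# per-edge transition matrices; k is small so this stays in R.
mk_partials <- function(tree, y, Q, levels) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  k <- nrow(Q)
  L <- matrix(1, nnode, k)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), match(y[tr$tip.label], levels))] <- 1
  P <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge)))
    P[[e]] <- edge_propagator(Q, tr$edge.length[e])
  up <- matrix(NA_real_, nrow(tr$edge), k)  # P_e %*% L[child]
  for (e in seq_len(nrow(tr$edge))) {
    up[e, ] <- as.vector(P[[e]] %*% L[tr$edge[e, 2], ])
    s <- sum(up[e, ])
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] * (up[e, ] / s)
  }
  list(tree = tr, L = L, P = P, up = up, root = tr$edge[nrow(tr$edge), 1])
}

# Endpoint-conditioned CTMC path on one edge by uniformization sampling:
# draw the uniformized jump count given the endpoints, then the jump chain
# as a bridge through powers of M, then jump times as uniform order
# statistics; virtual (self) jumps collapse away.
sample_bridge <- function(t, s_from, s_to, M, pow, Pt, lam) {
  k <- nrow(M)
  denom <- Pt[s_from, s_to]
  a <- lam * t
  nmax <- length(pow) - 1
  probs <- numeric(0)
  p_pois <- exp(-a)
  cum <- 0
  n_jump <- NA
  u <- stats::runif(1)
  n <- 0
  repeat {
    pn <- p_pois * pow[[n + 1]][s_from, s_to] / denom
    cum <- cum + pn
    if (u <= cum) { n_jump <- n; break }
    n <- n + 1
    if (n > nmax) { n_jump <- nmax; break }  # tail cut; negligible mass
    p_pois <- p_pois * a / (n)
  }
  states <- integer(n_jump + 1)
  states[1] <- s_from
  if (n_jump > 0) {
    for (j in seq_len(n_jump - 1)) {
      w <- M[states[j], ] * pow[[n_jump - j + 1]][, s_to]
      states[j + 1] <- sample.int(k, 1, prob = w)
    }
    states[n_jump + 1] <- s_to
    times <- sort(stats::runif(n_jump, 0, t))
  } else times <- numeric(0)
  # collapse virtual (self) jumps into segments
  keep <- c(TRUE, diff(states) != 0)
  st <- states[keep]
  bounds <- c(0, times[keep[-1]], t)
  data.frame(state = st, duration = diff(bounds))
}

#' Sample stochastic character maps of a discrete trait
#'
#' Histories are drawn in proportion to their probability under the given
#' rate matrix: node states are sampled from the pruning-conditional
#' distributions root-down, then each edge path is filled in by
#' endpoint-conditioned uniformization sampling.
#'
#' @param tree A `"phylo"` object.
#' @param y Named tip states.
#' @param Q_discrete `k x k` rate matrix (e.g. from a prior [fit_mk()]).
#' @param n_maps Number of maps to sample.
#' @param seed Optional integer seed.
#' @return List of `"ddpcm_history"` objects.
#' @export
stochastic_map <- function(tree, y, Q_discrete, n_maps = 100,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(Q_discrete)
  levels <- rownames(Q) %||% sort(unique(y))
  k <- nrow(Q)
  pp <- mk_partials(tree, y, Q, levels)
  tr_post <- pp$tree
  ntip <- length(tr_post$tip.label)
  lam <- max(-diag(Q)) * (1 + 1e-10)
  if (lam <= 0) lam <- 1
  # Precompute powers of M = I + Q/lam up to a generous jump-count cap
  M <- diag(k) + Q / lam
  a_max <- lam * max(tr_post$edge.length)
  nmax <- ceiling(a_max + 10 * sqrt(a_max + 1) + 20)
  pow <- vector("list", nmax + 1)
  pow[[1]] <- diag(k)
  for (i in seq_len(nmax)) pow[[i + 1]] <- pow[[i]] %*% M
  edge_dat <- lapply(seq_len(nrow(tr_post$edge)), function(e)
    list(Pt = pp$P[[e]], t = tr_post$edge.length[e]))
  root <- pp$root
  root_post <- pp$L[root, ] / sum(pp$L[root, ])
  preord <- rev(seq_len(nrow(tr_post$edge)))
  out <- vector("list", n_maps)
  # map from postorder-tree edges to cladewise-tree edges for output
  tr_clad <- ape::reorder.phylo(tree, "cladewise")
  clad_idx <- match(paste(tr_post$edge[, 1], tr_post$edge[, 2]),
                    paste(tr_clad$edge[, 1], tr_clad$edge[, 2]))
  for (m in seq_len(n_maps)) {
    node_state <- integer(max(tr_post$edge))
    node_state[root] <- sample.int(k, 1, prob = root_post)
    segs <- vector("list", nrow(tr_clad$edge))
    for (e in preord) {
      par <- tr_post$edge[e, 1]; ch <- tr_post$edge[e, 2]
      w <- pp$P[[e]][node_state[par], ] *
        (if (ch <= ntip) {
          z <- numeric(k); z[match(y[tr_post$tip.label[ch]], levels)] <- 1; z
        } else pp$L[ch, ])
      node_state[ch] <- sample.int(k, 1, prob = w)
      br <- sample_bridge(tr_post$edge.length[e], node_state[par],
                          node_state[ch], M, pow, pp$P[[e]], lam)
      br$state <- levels[br$state]
      segs[[clad_idx[e]]] <- br
    }
    tips <- stats::setNames(levels[node_state[seq_len(ntip)]],
                            tr_post$tip.label)
    out[[m]] <- structure(
      list(edge_segments = segs, tip_states = tips,
           node_states = levels[node_state], levels = levels,
           tree = tr_clad),
      class = "ddpcm_history")
  }
  out
}

# Per-level shared-duration matrices: C_i[u, v] is the time the root paths
# of tips u and v jointly spend in level i.
history_shared_durations <- function(history) {
  tr <- history$tree
  ntip <- length(tr$tip.label)
  lev <- history$levels
  k <- length(lev)
  Cs <- lapply(seq_len(k), function(i) matrix(0, ntip, ntip,
    dimnames = list(tr$tip.label, tr$tip.label)))
  # descendant tips per node
  desc <- vector("list", max(tr$edge))
  po <- ape::reorder.phylo(tr, "postorder")
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  for (e in seq_len(nrow(tr$edge))) {
    tips <- desc[[tr$edge[e, 2]]]
    seg <- history$edge_segments[[e]]
    for (i in seq_len(k)) {
      d <- sum(seg$duration[seg$state == lev[i]])
      if (d > 0) Cs[[i]][tips, tips] <- Cs[[i]][tips, tips] + d
    }
  }
  names(Cs) <- lev
  Cs
}

#' Gaussian state-dependent rate fit for a fixed character history
#'
#' Exact multivariate-normal likelihood whose tip covariance is
#' \eqn{\sum_i \sigma_i^2 C_i} with \eqn{C_i} the shared durations in
#' level i along the history; \eqn{x_0} is profiled by GLS. Levels absent
#' from the history are dropped.
#'
#' @param tree A `"phylo"` object.
#' @param history A `"ddpcm_history"` covering the tree.
#' @param x Named tip values.
#' @return A `"ddpcm_fit"` with per-level `sigma2`.
#' @export
statedep_bm_gaussian_fit <- function(tree, history, x) {
  Cs <- history_shared_durations(history)
  present <- vapply(Cs, function(C) any(diag(C) > 0), TRUE)
  Cs <- Cs[present]
  k <- length(Cs)
  labs <- rownames(Cs[[1]])
  x <- x[labs]
  N <- length(x)
  one <- rep(1, N)
  nll <- function(ls2) {
    s2 <- exp(ls2)
    V <- Reduce(`+`, Map(`*`, Cs, s2))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    x0 <- as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
    r <- x - x0
    0.5 * (N * log(2 * pi) + 2 * sum(log(diag(ch))) +
             as.numeric(r %*% Vi %*% r))
  }
  Tdep <- tree_depth(tree)
  p0 <- rep(log(max(stats::var(x) / Tdep, 1e-6)), k)
  if (k == 1) {
    op <- stats::optimize(nll, p0[1] + c(-10, 10), tol = 1e-8)
    par <- op$minimum; value <- op$objective
  } else {
    o <- .nm_optim(p0, nll, restarts = 1)
    par <- o$par; value <- o$value
  }
  s2 <- stats::setNames(exp(par), paste0("sigma2_", names(Cs)))
  V <- Reduce(`+`, Map(`*`, Cs, exp(par)))
  Vi <- chol2inv(chol(V))
  x0 <- as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
  new_fit("statedep_gaussian", c(as.list(s2), list(x0 = x0)), -value,
          nparam = k + 1, data_id = .data_id(tree, x = x))
}

#' Two-step state-dependent rate estimation
#'
#' The classic workflow: fit an equal-rates Mk model to the discrete tips,
#' sample `n_maps` stochastic character maps under the fitted rates, fit
#' the Gaussian state-dependent model to each map, and average the
#' per-level rate estimates across maps (rates averaged first, ratios
#' taken afterwards).
#'
#' @param tree A `"phylo"` object.
#' @param y Named tip states.
#' @param x Named tip values.
#' @param n_maps Number of stochastic maps (default 100).
#' @param seed Optional integer seed.
#' @return List with averaged `sigma2` (named by level), the Mk `q`
#'   estimate, and the per-map estimate matrix.
#' @export
fit_twostep <- function(tree, y, x, n_maps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- fit_mk(tree, y, "ER")
  maps <- stochastic_map(tree, y, mk$params$Q, n_maps = n_maps)
  levels <- sort(unique(y))
  est <- matrix(NA_real_, n_maps, length(levels),
                dimnames = list(NULL, levels))
  for (m in seq_len(n_maps)) {
    f <- statedep_bm_gaussian_fit(tree, maps[[m]], x)
    s2 <- unlist(f$params[grep("^sigma2_", names(f$params))])
    names(s2) <- sub("^sigma2_", "", names(s2))
    est[m, names(s2)] <- s2
  }
  list(sigma2 = colMeans(est, na.rm = TRUE),
       q = mk$params$rates[[1]], per_map = est, n_maps = n_maps)
}
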