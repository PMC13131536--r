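#' Simulate (possibly trended) Brownian motion on a tree
#'
#' Independent Gaussian increments per edge with mean `mu * t` and
#' variance `sigma2 * t`.
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root value.
#' @param sigma2 Diffusion rate (> 0, or 0 for a degenerate constant
#'   process).
#' @param mu Linear trend per unit time (default 0).
#' @param seed Optional integer seed.
#' @param internal Also return internal-node values?
#' @return Named vector of tip values; with `internal = TRUE`, a vector
#'   over all nodes (attribute `"tips"` gives the tip entries).
#' @export
sim_bm <- function(tree, x0 = 0, sigma2 = 1, mu = 0, seed = NULL,
                   internal = FALSE) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  val <- numeric(nnode)
  root <- tr$edge[1, 1]
  val[root] <- x0
  inc <- stats::rnorm(nrow(tr$edge), mean = mu * tr$edge.length,
                      sd = sqrt(sigma2 * tr$edge.length))
  for (e in seq_len(nrow(tr$edge)))
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + inc[e]
  tips <- val[seq_len(ntip)]
  names(tips) <- tr$tip.label
  if (!internal) return(tips)
  structure(val, tips = tips)
}

#' Simulate Brownian motion with reflective bounds
#'
#' Euler-Maruyama steps along every edge with reflection at `a` and `b`.
#' The default step `dt` divides each edge into 1000 steps.
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root value, strictly inside `(a, b)`.
#' @param sigma2 Diffusion rate (> 0).
#' @param a,b Lower and upper reflective bounds (`a < x0 < b`).
#' @param dt Step size (time units); `NULL` for edge-length/1000.
#' @param seed Optional integer seed.
#' @param nrep Number of independent replicate simulations.
#' @return For `nrep = 1`, a named vector of tip values; otherwise an
#'   `nrep x ntip` matrix with tip-label columns.
#' @export
sim_bounded <- function(tree, x0 = 0, sigma2 = 1, a = -1, b = 1,
                        dt = NULL, seed = NULL, nrep = 1) {
  if (!(a < x0 && x0 < b)) stop("x0 must lie strictly inside (a, b)")
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(dt)) dt <- max(tr$edge.length) / 1000
  if (dt > 0.05 * (b - a)^2 / sigma2)
    warning("dt is coarse relative to (b - a)^2 / sigma2; ",
            "reflection error may be non-negligible")
  out <- cpp_sim_bounded(tr$edge, tr$edge.length,
                         length(tr$tip.label), x0, sigma2, a, b, dt, nrep)
  colnames(out) <- tr$tip.label
  if (nrep == 1) out[1, ] else out
}

#' Simulate the threshold model
#'
#' Liability evolves by Brownian motion ([sim_bm()], same random stream);
#' the observed level of each tip is the index of the threshold interval
#' containing its liability.
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root liability.
#' @param sigma2 Liability diffusion rate (conventionally 1).
#' @param thresholds Strictly increasing threshold values.
#' @param seed Optional integer seed.
#' @param level_names Names for the `length(thresholds) + 1` levels
#'   (default `letters`).
#' @return List with `states` (named character vector) and `liability`
#'   (named numeric vector).
#' @export
sim_threshold <- function(tree, x0 = 0, sigma2 = 1, thresholds = 0,
                          seed = NULL, level_names = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  liab <- sim_bm(tree, x0 = x0, sigma2 = sigma2, seed = seed)
  L <- length(thresholds) + 1
  if (is.null(level_names)) level_names <- letters[seq_len(L)]
  lev <- findInterval(liab, thresholds) + 1L
  states <- stats::setNames(level_names[lev], names(liab))
  list(states = states, liability = liab)
}

#' Simulate the semi-threshold (censored) model
#'
#' Liability evolves by Brownian motion; tips inside the observable window
#' `clamp` report their value, tips outside report only the clamp side.
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root value.
#' @param sigma2 Diffusion rate.
#' @param clamp Length-2 observable window `(low, high)`.
#' @param seed Optional integer seed.
#' @return List with `obs` (data frame `taxon`, `value`, `censored`) and
#'   `liability`.
#' @export
sim_semithreshold <- function(tree, x0 = 0, sigma2 = 1,
                              clamp = c(-1, 1), seed = NULL) {
  if (!(clamp[1] < clamp[2])) stop("clamp low must be < high")
  liab <- sim_bm(tree, x0 = x0, sigma2 = sigma2, seed = seed)
  side <- ifelse(liab <= clamp[1], "low",
                 ifelse(liab >= clamp[2], "high", NA))
  obs <- data.frame(taxon = names(liab),
                    value = ifelse(is.na(side), liab, NA_real_),
                    censored = side, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(obs = obs, liability = liab)
}

#' Simulate a discrete character history (Gillespie)
#'
#' Exponential waiting times along every edge under a k-level rate matrix;
#' returns the full piecewise-constant history, not just tip states.
#'
#' @param tree A `"phylo"` object.
#' @param Q_discrete `k x k` rate matrix (rows sum to zero, or the diagonal
#'   is recomputed), with level names as `rownames` (default letters).
#' @param root_level Starting level (name or index; default the first).
#' @param seed Optional integer seed.
#' @return A `"ddpcm_history"`: list with `edge_segments` (per cladewise
#'   edge, a data frame of `state`, `duration`), `tip_states`,
#'   `node_states`, `levels`, and the reordered `tree`.
#' @export
sim_mk_history <- function(tree, Q_discrete, root_level = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(Q_discrete)
  k <- nrow(Q)
  diag(Q) <- 0
  lev <- rownames(Q) %||% letters[seq_len(k)]
  if (is.character(root_level)) root_level <- match(root_level, lev)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  node_state <- integer(nnode)
  node_state[tr$edge[1, 1]] <- root_level
  segs <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    s <- node_state[tr$edge[e, 1]]
    t_left <- tr$edge.length[e]
    st <- integer(0); du <- numeric(0)
    repeat {
      rate <- sum(Q[s, ])
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (w >= t_left) {
        st <- c(st, s); du <- c(du, t_left)
        break
      }
      st <- c(st, s); du <- c(du, w)
      t_left <- t_left - w
      s <- sample.int(k, 1, prob = Q[s, ])
    }
    segs[[e]] <- data.frame(state = lev[st], duration = du,
                            stringsAsFactors = FALSE)
    node_state[tr$edge[e, 2]] <- s
  }
  tips <- stats::setNames(lev[node_state[seq_len(ntip)]], tr$tip.label)
  structure(list(edge_segments = segs, tip_states = tips,
                 node_states = lev[node_state], levels = lev, tree = tr),
            class = "ddpcm_history")
}

#' @export
print.ddpcm_history <- function(x, ...) {
  nch <- sum(vapply(x$edge_segments, nrow, 1L)) - length(x$edge_segments)
  cat(sprintf("discrete character history: %d tips, %d levels, %d changes\n",
              length(x$tip_states), length(x$levels), nch))
  invisible(x)
}

#' Simulate state-dependent (trended) Brownian motion given a history
#'
#' Per history segment the continuous trait receives a Gaussian increment
#' with mean `mu[level] * duration` and variance `sigma2[level] * duration`.
#'
#' @param tree A `"phylo"` object (must match the history's tree).
#' @param history A `"ddpcm_history"` covering every edge.
#' @param sigma2_by_state Named (or level-ordered) per-level rates.
#' @param mu_by_state Per-level trends (default 0).
#' @param x0 Root value.
#' @param seed Optional integer seed.
#' @return Named vector of tip values.
#' @export
sim_statedep <- function(tree, history, sigma2_by_state,
                         mu_by_state = NULL, x0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- history$tree
  if (!setequal(tr$tip.label, tree$tip.label))
    stop("history does not match the tree")
  k <- length(history$levels)
  if (is.null(mu_by_state)) mu_by_state <- rep(0, k)
  s2 <- if (!is.null(names(sigma2_by_state)))
    sigma2_by_state[history$levels] else sigma2_by_state
  mu <- if (!is.null(names(mu_by_state)))
    mu_by_state[history$levels] else mu_by_state
  if (anyNA(s2) || anyNA(mu))
    stop("sigma2_by_state / mu_by_state do not cover every history level")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  val <- numeric(nnode)
  val[tr$edge[1, 1]] <- x0
  for (e in seq_len(nrow(tr$edge))) {
    seg <- history$edge_segments[[e]]
    li <- match(seg$state, history$levels)
    m <- sum(mu[li] * seg$duration)
    v <- sum(s2[li] * seg$duration)
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + stats::rnorm(1, m, sqrt(v))
  }
  stats::setNames(val[seq_len(ntip)], tr$tip.label)
}

#' Simulate continuous-character dependent discrete evolution
#'
#' Fine-step joint simulation: the continuous trait takes Brownian steps
#' while the binary discrete trait switches with per-step hazard
#' `sigmoid_rate(x) * dt` in the direction given by its current level.
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root continuous value.
#' @param sigma2 Diffusion rate of the continuous trait.
#' @param p_ab,p_ba `"sigmoid_params"` for the a->b and b->a hazards.
#' @param level0 Root level, `"a"` or `"b"`.
#' @param dt Step size; `NULL` for edge-length/1000.
#' @param seed Optional integer seed.
#' @return List with `x` (named tip values) and `states` (named tip
#'   levels, `"a"`/`"b"`).
#' @export
sim_xdep <- function(tree, x0 = 0, sigma2 = 1, p_ab, p_ba,
                     level0 = "a", dt = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(dt)) dt <- max(tr$edge.length) / 1000
  res <- cpp_sim_xdep(tr$edge, tr$edge.length, length(tr$tip.label),
                      x0, match(level0, c("a", "b")) - 1L, sigma2,
                      unlist(p_ab[c("lower", "upper", "midpoint",
                                    "steepness")]),
                      unlist(p_ba[c("lower", "upper", "midpoint",
                                    "steepness")]), dt)
  if (res$max_step_prob > 0.1)
    warning("dt too coarse: per-step switch probability reached ",
            signif(res$max_step_prob, 3))
  ntip <- length(tr$tip.label)
  list(x = stats::setNames(res$x[seq_len(ntip)], tr$tip.label),
       states = stats::setNames(c("a", "b")[res$level[seq_len(ntip)] + 1L],
                                tr$tip.label))
}

#' Write a history as simmap-style annotated Newick
#'
#' Edges are annotated as `{state,duration:state,duration:...}` reading
#' from the rootward end of each edge.
#'
#' @param history A `"ddpcm_history"`.
#' @return A single annotated Newick string.
#' @export
write_simmap <- function(history) {
  tr <- history$tree
  ntip <- length(tr$tip.label)
  edge_of <- integer(max(tr$edge))
  edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  lab <- function(node) {
    ch <- tr$edge[tr$edge[, 1] == node, 2]
    core <- if (length(ch) == 0) tr$tip.label[node]
            else paste0("(", paste(vapply(ch, lab, ""), collapse = ","), ")")
    e <- edge_of[node]
    if (e == 0) return(core)
    seg <- history$edge_segments[[e]]
    ann <- paste(sprintf("%s,%.10g", seg$state, seg$duration),
                 collapse = ":")
    paste0(core, ":{", ann, "}")
  }
  root <- tr$edge[1, 1]
  paste0(lab(root), ";")
}

#' Read a simmap-style annotated Newick string
#'
#' @param text Annotated Newick as written by [write_simmap()] (or
#'   phytools-compatible simmap text).
#' @return A `"ddpcm_history"`.
#' @export
read_simmap <- function(text) {
  # extract the {..} annotations in edge order of the plain topology
  plain <- gsub("\\{[^}]*\\}", "X", text)
  ann <- regmatches(text, gregexpr("\\{[^}]*\\}", text))[[1]]
  # replace each annotation with a placeholder branch length, parse, then
  # match annotations to edges by occurrence order in the string, which is
  # ape's cladewise order for trees written tips-first by write_simmap
  tmp <- text
  lens <- numeric(length(ann))
  segs <- vector("list", length(ann))
  for (i in seq_along(ann)) {
    parts <- strsplit(sub("^\\{", "", sub("\\}$", "", ann[i])), ":")[[1]]
    sd <- do.call(rbind, lapply(parts, function(p) {
      kv <- strsplit(p, ",")[[1]]
      data.frame(state = kv[1], duration = as.numeric(kv[2]),
                 stringsAsFactors = FALSE)
    }))
    segs[[i]] <- sd
    lens[i] <- sum(sd$duration)
  }
  for (i in seq_along(ann))
    tmp <- sub(ann[i], sprintf("%.10g", lens[i]), tmp, fixed = TRUE)
  tree <- ape::reorder.phylo(ape::read.tree(text = tmp), "cladewise")
  # the j-th annotation in the string belongs to the j-th edge whose child
  # subtree closes while reading left to right; re-walk the parsed tree in
  # that order to map annotations onto ape edge indices
  idx <- simmap_edge_order(tree)
  edge_segments <- vector("list", nrow(tree$edge))
  for (j in seq_along(idx)) edge_segments[[idx[j]]] <- segs[[j]]
  lev <- sort(unique(unlist(lapply(segs, function(s) s$state))))
  ntip <- length(tree$tip.label)
  node_states <- character(max(tree$edge))
  for (e in seq_len(nrow(tree$edge)))
    node_states[tree$edge[e, 2]] <-
      edge_segments[[e]]$state[nrow(edge_segments[[e]])]
  node_states[tree$edge[1, 1]] <- edge_segments[[1]]$state[1]
  tips <- stats::setNames(node_states[seq_len(ntip)], tree$tip.label)
  structure(list(edge_segments = edge_segments, tip_states = tips,
                 node_states = node_states, levels = lev, tree = tree),
            class = "ddpcm_history")
}

# Order in which annotated edges appear when a Newick string is read left
# to right: a tip's annotation appears at the tip, an internal node's after
# its subtree closes.  ape preserves child order, so a DFS that records a
# node's edge after recursing into its children reproduces string order.
simmap_edge_order <- function(tree) {
  visit <- integer(0)
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  walk <- function(node) {
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    for (c in ch) walk(c)
    e <- edge_of[node]
    if (e > 0) visit <<- c(visit, e)
  }
  walk(tree$edge[1, 1])
  visit
}
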