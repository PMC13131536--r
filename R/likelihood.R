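#' Tip observation constructors
#'
#' A tip observation is one of: a point-valued continuous measurement, a
#' liability interval, a discrete level (interpreted through thresholds
#' when given, or as a joint-model level otherwise), a joint (level, value)
#' pair, a censored (clamped) measurement, or a fully missing entry.
#'
#' @param x Continuous trait value.
#' @param level Discrete level (1-based index, or a name resolved by the
#'   caller).
#' @param lo,hi Liability interval limits (`lo < hi`).
#' @param side `"low"` or `"high"`: which clamp the value sits at/beyond.
#' @param at The clamp threshold the censored value sits at/beyond.
#' @return A list of class `"tip_obs"`.
#' @export
tip_point <- function(x) {
  stopifnot(is.finite(x))
  structure(list(kind = "point", x = x), class = "tip_obs")
}

#' @rdname tip_point
#' @export
tip_interval <- function(lo, hi) {
  if (!(lo < hi)) stop("interval requires lo < hi")
  structure(list(kind = "interval", lo = lo, hi = hi), class = "tip_obs")
}

#' @rdname tip_point
#' @export
tip_discrete <- function(level) {
  structure(list(kind = "discrete", level = level), class = "tip_obs")
}

#' @rdname tip_point
#' @export
tip_joint <- function(level, x) {
  stopifnot(is.finite(x))
  structure(list(kind = "joint", level = level, x = x), class = "tip_obs")
}

#' @rdname tip_point
#' @export
tip_censored <- function(side = c("low", "high"), at) {
  side <- match.arg(side)
  structure(list(kind = "censored", side = side, at = at),
            class = "tip_obs")
}

#' @rdname tip_point
#' @export
tip_missing <- function() {
  structure(list(kind = "missing"), class = "tip_obs")
}

#' Encode a tip observation as a partial-likelihood vector
#'
#' Point values become an indicator on the containing bin (in joint models,
#' on the (level, bin) state); a discrete level with `thresholds` given
#' becomes ones on all bins between the bracketing thresholds (a bin
#' straddling a threshold gets its overlapped fraction); a discrete level
#' without thresholds (joint model) becomes ones on every bin of that
#' level; censored observations become ones on all bins at/beyond the
#' clamp (fractional at the clamp bin); missing entries are all ones.
#'
#' @param obs A `"tip_obs"`.
#' @param grid A `"trait_grid"`.
#' @param k Number of discrete levels of the generator (default 1).
#' @param thresholds Ordered liability cut-points (for threshold-model
#'   encodings), strictly increasing and inside the grid span.
#' @return Numeric vector of length `k * n` (level-major state order).
#' @export
encode_tip <- function(obs, grid, k = 1L, thresholds = NULL) {
  n <- grid$n
  ctr <- grid$centers
  if (!is.null(thresholds)) {
    if (is.unsorted(thresholds, strictly = TRUE))
      stop("thresholds must be strictly increasing")
    if (any(thresholds <= grid$lo) || any(thresholds >= grid$hi))
      stop("thresholds outside grid span")
  }
  bin_vec <- function() numeric(n)
  # fraction of each bin overlapping [lo, hi): bins wholly inside get 1,
  # bins straddling a cut point get the overlapped fraction, so the
  # encoding is exact to O(delta^2) and continuous in the cut points
  overlap <- function(lo, hi) {
    e_lo <- ctr - grid$delta / 2
    e_hi <- ctr + grid$delta / 2
    pmax(0, (pmin(hi, e_hi) - pmax(lo, e_lo)) / grid$delta)
  }
  v <- switch(obs$kind,
    point = {
      b <- bin_index(grid, obs$x)
      z <- bin_vec(); z[b] <- 1; z
    },
    interval = overlap(obs$lo, obs$hi),
    discrete = {
      if (is.null(thresholds)) {
        rep(1, n)  # level handled below
      } else {
        cuts <- c(-Inf, thresholds, Inf)
        j <- obs$level
        if (j < 1 || j > length(cuts) - 1)
          stop("discrete level outside threshold range")
        overlap(cuts[j], cuts[j + 1])
      }
    },
    joint = {
      b <- bin_index(grid, obs$x)
      z <- bin_vec(); z[b] <- 1; z
    },
    censored = {
      if (obs$side == "low") overlap(-Inf, obs$at)
      else overlap(obs$at, Inf)
    },
    missing = rep(1, n),
    stop("unknown observation kind: ", obs$kind)
  )
  if (sum(v) == 0) stop("observation encodes to an all-zero vector")
  if (k == 1L) return(v)
  out <- numeric(k * n)
  lv <- switch(obs$kind,
               joint = obs$level,
               discrete = if (is.null(thresholds)) obs$level else NULL,
               NULL)
  if (is.null(lv)) {
    for (i in seq_len(k)) out[(i - 1) * n + seq_len(n)] <- v
  } else {
    if (lv < 1 || lv > k) stop("discrete level outside 1..k")
    out[(lv - 1) * n + seq_len(n)] <- v
  }
  out
}

#' Encode a set of tip observations in tree tip order
#'
#' @param obs Named list of `"tip_obs"` (names = taxon labels) covering
#'   every tip of `tree`.
#' @param tree A `"phylo"` object.
#' @inheritParams encode_tip
#' @return Matrix with one row per tip (tree tip order).
#' @export
encode_tips <- function(obs, tree, grid, k = 1L, thresholds = NULL) {
  labs <- tree$tip.label
  if (!all(labs %in% names(obs)))
    stop("missing observations for tips: ",
         paste(setdiff(labs, names(obs)), collapse = ", "))
  t(vapply(labs, function(l) encode_tip(obs[[l]], grid, k, thresholds),
           numeric(k * grid$n)))
}

#' Decompose a generator for repeated edge propagation
#'
#' Symmetric generators get a one-shot eigendecomposition that is reused
#' for every edge (and across optimizer evaluations when the generator is
#' fixed); small non-symmetric chains (up to 12 states) get a general
#' eigendecomposition; large non-symmetric generators are propagated by
#' uniformization and need no precomputation.
#'
#' @param Q A `"ctmc_generator"` (or plain square rate matrix).
#' @return An opaque decomposition object for [prune_loglik()].
#' @export
ctmc_decompose <- function(Q) {
  Qm <- as.matrix(unclass(Q))
  sym <- isSymmetric.matrix(Qm, tol = 1e-9, check.attributes = FALSE)
  k <- attr(Q, "k") %||% 1L
  grid <- attr(Q, "grid")
  if (sym) {
    es <- eigen(Qm, symmetric = TRUE)
    return(structure(list(sym = TRUE, gen = FALSE, V = es$vectors,
                          values = es$values, N = nrow(Qm), k = k,
                          grid = grid),
                     class = "ctmc_decomp"))
  }
  if (nrow(Qm) <= 12) {
    # small discrete chains: a general (possibly complex)
    # eigendecomposition is cheap and, unlike uniformization, costs
    # nothing extra when rates are huge (plateau regions of Mk fits)
    es <- tryCatch(eigen(Qm), error = function(e) NULL)
    Vi <- if (!is.null(es))
      tryCatch(solve(es$vectors), error = function(e) NULL) else NULL
    if (!is.null(Vi) && all(is.finite(Mod(Vi))))
      return(structure(list(sym = FALSE, gen = TRUE, V = es$vectors,
                            values = es$values, Vi = Vi, Q = Qm,
                            N = nrow(Qm), k = k, grid = grid),
                       class = "ctmc_decomp"))
  }
  structure(list(sym = FALSE, gen = FALSE, Q = Qm, N = nrow(Qm),
                 k = k, grid = grid),
            class = "ctmc_decomp")
}

# R-level pruning for small general (non-symmetric) chains using a cached
# eigendecomposition; mirrors the compiled kernels.
r_prune_gen <- function(po, ntip, dec, tipL, root_edge) {
  N <- dec$N
  nnode <- max(po$edge)
  L <- matrix(1, nnode, N)
  L[seq_len(ntip), ] <- tipL
  Pt <- function(t) {
    P <- Re(dec$V %*% (exp(dec$values * t) * dec$Vi))
    P[P < 0] <- 0
    P
  }
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    v <- as.vector(Pt(po$edge.length[e]) %*% L[po$edge[e, 2], ])
    s <- sum(v)
    if (!(s > 0)) return(list(root = numeric(N), log_scale = -Inf))
    logscale <- logscale + log(s)
    L[po$edge[e, 1], ] <- L[po$edge[e, 1], ] * (v / s)
  }
  root <- po$edge[nrow(po$edge), 1]
  rv <- L[root, ]
  if (root_edge > 0) {
    rv <- as.vector(Pt(root_edge) %*% rv)
    s <- sum(rv)
    if (s > 0) { logscale <- logscale + log(s); rv <- rv / s }
  }
  list(root = rv, log_scale = logscale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transition probability matrix over an edge
#'
#' \eqn{P = \exp(Q t)}: rows sum to one, and `P(0)` is the identity.
#'
#' @param Q Generator matrix.
#' @param t Elapsed time (>= 0).
#' @return Transition probability matrix.
#' @export
edge_propagator <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  Qm <- as.matrix(unclass(Q))
  if (t == 0) return(diag(nrow(Qm)))
  if (isSymmetric.matrix(Qm, tol = 1e-9, check.attributes = FALSE)) {
    es <- eigen(Qm, symmetric = TRUE)
    P <- es$vectors %*% (exp(es$values * t) * t(es$vectors))
    P[P < 0] <- 0
    P
  } else if (nrow(Qm) <= 12) {
    dec <- ctmc_decompose(Qm)
    if (isTRUE(dec$gen)) {
      P <- Re(dec$V %*% (exp(dec$values * t) * dec$Vi))
      P[P < 0] <- 0
      P
    } else cpp_expm_unif(Qm, t)
  } else {
    cpp_expm_unif(Qm, t)
  }
}

# Root partial-likelihood vector (normalized) and accumulated log scale.
prune_root <- function(tree, Q, tipL) {
  dec <- if (inherits(Q, "ctmc_decomp")) Q else ctmc_decompose(Q)
  po <- ape::reorder.phylo(tree, "postorder")
  root_edge <- tree$root.edge %||% 0
  ntip <- length(tree$tip.label)
  if (nrow(tipL) != ntip || ncol(tipL) != dec$N)
    stop("tip likelihood matrix has wrong dimensions")
  if (dec$sym)
    res <- cpp_prune_eigen(po$edge, po$edge.length, ntip, dec$V,
                           dec$values, tipL, root_edge)
  else if (isTRUE(dec$gen))
    res <- r_prune_gen(po, ntip, dec, tipL, root_edge)
  else
    res <- cpp_prune_unif(po$edge, po$edge.length, ntip, dec$Q, tipL,
                          root_edge)
  res
}

#' Log-probability of encoded tip data by Felsenstein pruning
#'
#' Postorder recursion with per-node rescaling; the root partial
#' likelihood is combined with a root prior. Priors: `"flat"` (uniform
#' over all generator states), `"ml-bin"` (point mass at the
#' best-supported bin, i.e. the root state profiled out at its maximum
#' likelihood value; for joint generators the prior is flat over discrete
#' levels and the bin is profiled), or an explicit probability vector or
#' single state index.
#'
#' @param tree A `"phylo"` object.
#' @param Q A `"ctmc_generator"` or a `"ctmc_decomp"` from
#'   [ctmc_decompose()].
#' @param tipL Tip partial-likelihood matrix from [encode_tips()].
#' @param root_prior `"flat"`, `"ml-bin"`, a numeric prior vector, or a
#'   single integer state index.
#' @return Log-probability, with attributes `root_bin` and `root_value`
#'   when the root is profiled.
#' @export
prune_loglik <- function(tree, Q, tipL, root_prior = "flat") {
  res <- prune_root(tree, Q, tipL)
  rv <- res$root
  ls <- res$log_scale
  if (!is.finite(ls)) return(-Inf)
  dec_k <- if (inherits(Q, "ctmc_decomp")) Q$k else attr(Q, "k") %||% 1L
  N <- length(rv)
  if (is.numeric(root_prior)) {
    if (length(root_prior) == 1) {
      lp <- log(rv[root_prior]) + ls
    } else {
      if (length(root_prior) != N) stop("root prior has wrong length")
      lp <- log(sum(rv * root_prior)) + ls
    }
    return(lp)
  }
  root_prior <- match.arg(root_prior, c("flat", "ml-bin"))
  if (root_prior == "flat") return(log(mean(rv)) + ls)
  # ml-bin: flat over discrete levels x point mass at the profiled bin
  k <- max(1L, dec_k)
  n <- N %/% k
  per_bin <- rowMeans(matrix(rv, nrow = n, ncol = k))
  b <- which.max(per_bin)
  lp <- log(per_bin[b]) + ls
  attr(lp, "root_bin") <- b
  attr(lp, "root_value") <-
    if (!is.null(attr(Q, "grid")) || inherits(Q, "ctmc_decomp")) {
      g <- if (inherits(Q, "ctmc_decomp")) Q$grid else attr(Q, "grid")
      if (!is.null(g)) g$centers[b] else NA_real_
    } else NA_real_
  lp
}

#' Probability-to-density back-transform
#'
#' Converts the log-probability of discretized data into a log-density:
#' \eqn{\log f = \log p - m \log \delta}, where `m` counts only the tips
#' that contributed a point observation (censored and discrete tips
#' contribute probabilities, not densities).
#'
#' @param log_p Log-probability of the discretized data.
#' @param delta Bin width.
#' @param m Number of point-valued tips (>= 0).
#' @return Log-density.
#' @export
loglik_density <- function(log_p, delta, m) {
  if (m < 0) stop("m must be >= 0")
  as.numeric(log_p) - m * log(delta)
}

#' Read a delimited tip table
#'
#' Columns (any subset): `taxon`, `value`, `state`, `censored`. Missing
#' entries yield fully ambiguous (all-ones) encodings.
#'
#' @param path Path to a tab- or comma-delimited text file with a header.
#' @return A data frame.
#' @export
read_tip_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"taxon" %in% names(df)) stop("tip table needs a 'taxon' column")
  df
}

# Convert a tip-table data frame into a named list of tip_obs.
tip_table_to_obs <- function(df, levels = NULL) {
  out <- vector("list", nrow(df))
  names(out) <- df$taxon
  for (i in seq_len(nrow(df))) {
    cs <- if ("censored" %in% names(df)) df$censored[i] else NA
    val <- if ("value" %in% names(df)) df$value[i] else NA
    st <- if ("state" %in% names(df)) df$state[i] else NA
    out[[i]] <-
      if (!is.na(cs) && nzchar(cs)) tip_censored(cs, at = val)
      else if (!is.na(st) && !is.na(val))
        tip_joint(match(st, levels), val)
      else if (!is.na(st)) tip_discrete(match(st, levels))
      else if (!is.na(val)) tip_point(val)
      else tip_missing()
  }
  out
}
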