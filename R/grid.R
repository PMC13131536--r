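#' Discretize a trait interval into equal-width bins
#'
#' The trait space \eqn{[lo, hi]} is divided into `n` bins of width
#' \eqn{\delta = (hi - lo)/n}; bin centers sit at
#' \eqn{lo + \delta/2, \ldots, hi - \delta/2}. All generators and tip
#' encodings in the package are expressed on such a grid.
#'
#' @param lo,hi Outer edges of the trait interval (`hi > lo`).
#' @param n Number of bins (>= 3).
#' @return An object of class `"trait_grid"`: a list with elements `n`,
#'   `delta`, `centers`, `lo`, `hi`.
#' @export
build_grid <- function(lo, hi, n) {
  if (!(hi > lo)) stop("degenerate interval: hi must exceed lo")
  if (n < 3) stop("n must be >= 3")
  n <- as.integer(n)
  delta <- (hi - lo) / n
  structure(list(n = n, delta = delta,
                 centers = lo + delta * (seq_len(n) - 0.5),
                 lo = lo, hi = hi),
            class = "trait_grid")
}

#' Default padded grid for unbounded-type models
#'
#' Unbounded diffusion is approximated on a finite grid whose edges act as
#' spurious reflecting bounds; the grid therefore extends beyond the
#' observed trait range by `padding` times the observed range on each side.
#' The padding should comfortably exceed \eqn{\sqrt{\sigma^2 T}} for the
#' fitted rate and tree depth; [check_grid_mass()] can be used to verify
#' this after a fit.
#'
#' @param x Observed trait values.
#' @param n Number of bins.
#' @param padding Padding factor relative to the observed range (default
#'   0.5).
#' @param extra Additional absolute padding (trait units) added to each
#'   side, e.g. to guarantee room for diffusion on nearly-invariant data.
#' @return A `"trait_grid"`.
#' @export
default_grid <- function(x, n = 200, padding = 0.5, extra = 0) {
  r <- range(x, finite = TRUE)
  pad <- padding * max(diff(r), .Machine$double.eps) + extra
  build_grid(r[1] - pad, r[2] + pad, n)
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("trait grid: %d bins of width %.6g on [%.6g, %.6g]\n",
              x$n, x$delta, x$lo, x$hi))
  invisible(x)
}

#' Bin index of a trait value
#'
#' Values are assigned to their containing bin; a value exactly at the
#' upper edge belongs to the last bin. Values outside the grid span are an
#' error.
#'
#' @param grid A `"trait_grid"`.
#' @param x Numeric values.
#' @return Integer bin indices in `1:n`.
#' @export
bin_index <- function(grid, x) {
  if (any(x < grid$lo - 1e-12) || any(x > grid$hi + 1e-12))
    stop("trait value outside grid span [", grid$lo, ", ", grid$hi, "]")
  i <- pmin(pmax(floor((x - grid$lo) / grid$delta) + 1L, 1L), grid$n)
  as.integer(i)
}

new_generator <- function(Q, grid, labels, k = 1L) {
  dimnames(Q) <- list(labels, labels)
  structure(Q, class = c("ctmc_generator", "matrix"),
            grid = grid, k = as.integer(k))
}

#' Nearest-neighbor diffusion generator
#'
#' Rate matrix of the continuous-time Markov chain that approximates
#' Brownian motion with rate \eqn{\sigma^2} on a binned trait space: the
#' rate between adjacent bins is \eqn{q_c = \sigma^2 / (2\delta^2)}.
#' Outward transitions at the two edge bins are removed, making the bounds
#' reflective; the removed rate is either reassigned to the transitions
#' between the edge bin and its neighbor (`"reassign"`, both directions
#' doubled to \eqn{2 q_c}, keeping the generator symmetric and its
#' stationary distribution uniform) or simply dropped (`"omit"`). The two
#' conventions converge on each other as \eqn{\delta \to 0}.
#'
#' @param grid A `"trait_grid"`.
#' @param sigma2 Diffusion rate (> 0), trait units squared per time.
#' @param boundary `"reassign"` (default) or `"omit"`.
#' @return An `n x n` `"ctmc_generator"` (rows sum to zero).
#' @export
generator_diffusion <- function(grid, sigma2,
                                boundary = c("reassign", "omit")) {
  boundary <- match.arg(boundary)
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  n <- grid$n
  qc <- sigma2 / (2 * grid$delta^2)
  Q <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  Q[cbind(idx, idx + 1)] <- qc
  Q[cbind(idx + 1, idx)] <- qc
  if (boundary == "reassign") {
    Q[1, 2] <- Q[2, 1] <- 2 * qc
    Q[n, n - 1] <- Q[n - 1, n] <- 2 * qc
  }
  diag(Q) <- -rowSums(Q)
  new_generator(Q, grid, labels = sprintf("bin%d", seq_len(n)))
}

#' Trended (drifted) diffusion generator
#'
#' Upward and downward nearest-neighbor rates
#' \eqn{q_+ = \sigma^2/(2\delta^2) + \mu/(2\delta)} and
#' \eqn{q_- = \sigma^2/(2\delta^2) - \mu/(2\delta)} encode a linear trend
#' \eqn{\mu} on top of diffusion. Non-negativity of both rates requires
#' \eqn{|\mu| \le \sigma^2/\delta}; violating that bound is an error. With
#' `mu = 0` the matrix reduces exactly to [generator_diffusion()].
#'
#' @param grid A `"trait_grid"`.
#' @param sigma2 Diffusion rate (> 0).
#' @param mu Trend, trait units per unit time.
#' @param boundary Boundary convention, as in [generator_diffusion()].
#' @return An `n x n` `"ctmc_generator"`.
#' @export
generator_trend <- function(grid, sigma2, mu,
                            boundary = c("reassign", "omit")) {
  boundary <- match.arg(boundary)
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  d <- grid$delta
  if (abs(mu) > sigma2 / d + 1e-12)
    stop(sprintf(
      "trend constraint violated: |mu| = %.6g exceeds sigma2/delta = %.6g",
      abs(mu), sigma2 / d))
  n <- grid$n
  qc <- sigma2 / (2 * d^2)
  qup <- qc + mu / (2 * d)
  qdn <- qc - mu / (2 * d)
  Q <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  Q[cbind(idx, idx + 1)] <- qup
  Q[cbind(idx + 1, idx)] <- qdn
  if (boundary == "reassign") {
    Q[1, 2] <- 2 * qup
    Q[2, 1] <- 2 * qdn
    Q[n, n - 1] <- 2 * qdn
    Q[n - 1, n] <- 2 * qup
  }
  diag(Q) <- -rowSums(Q)
  new_generator(Q, grid, labels = sprintf("bin%d", seq_len(n)))
}

#' Joint generator for discrete-state dependent diffusion
#'
#' Builds the \eqn{k n \times k n} generator of the joint process (discrete
#' level, binned continuous trait): diagonal \eqn{n \times n} blocks are
#' per-level diffusion (or trend) generators with rates
#' \eqn{q_{c,i} = \sigma_i^2/(2\delta^2)}, and off-diagonal blocks are
#' \eqn{q_{ij} I}, the discrete transition rates acting identically at
#' every bin.
#'
#' @param grid A `"trait_grid"`.
#' @param sigma2_by_state Length-`k` vector of per-level diffusion rates.
#' @param q_discrete `k x k` matrix of discrete transition rates
#'   (off-diagonals >= 0; the diagonal is ignored). A scalar is expanded to
#'   an equal-rates binary matrix when `k = 2`.
#' @param mu_by_state Length-`k` vector of per-level trends (default all
#'   zero).
#' @param boundary Boundary convention for the diffusion blocks.
#' @param level_names Optional names for the discrete levels.
#' @return A `"ctmc_generator"` with attribute `k`.
#' @export
generator_joint <- function(grid, sigma2_by_state, q_discrete,
                            mu_by_state = NULL,
                            boundary = c("reassign", "omit"),
                            level_names = NULL) {
  boundary <- match.arg(boundary)
  k <- length(sigma2_by_state)
  if (is.null(mu_by_state)) mu_by_state <- rep(0, k)
  if (length(mu_by_state) != k)
    stop("sigma2_by_state and mu_by_state must have equal length")
  if (length(q_discrete) == 1 && k == 2)
    q_discrete <- matrix(c(0, q_discrete, q_discrete, 0), 2, 2)
  q_discrete <- as.matrix(q_discrete)
  if (!all(dim(q_discrete) == k))
    stop("q_discrete must be k x k")
  off <- q_discrete[row(q_discrete) != col(q_discrete)]
  if (any(off < 0)) stop("q_discrete off-diagonals must be >= 0")
  if (is.null(level_names))
    level_names <- if (!is.null(rownames(q_discrete)))
      rownames(q_discrete) else letters[seq_len(k)]
  n <- grid$n
  Q <- matrix(0, k * n, k * n)
  for (i in seq_len(k)) {
    blk <- if (mu_by_state[i] == 0)
      generator_diffusion(grid, sigma2_by_state[i], boundary)
    else
      generator_trend(grid, sigma2_by_state[i], mu_by_state[i], boundary)
    ri <- (i - 1) * n + seq_len(n)
    Q[ri, ri] <- unclass(blk)
    for (j in seq_len(k)) {
      if (j == i) next
      rj <- (j - 1) * n + seq_len(n)
      Q[cbind(ri, rj)] <- q_discrete[i, j]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  labels <- as.vector(t(outer(level_names, sprintf("bin%d", seq_len(n)),
                              paste, sep = ":")))
  new_generator(Q, grid, labels = labels, k = k)
}

#' Four-parameter sigmoid transition-rate curve
#'
#' @param lower,upper Lower and upper asymptotes (rates, >= 0).
#' @param midpoint Inflection point (trait units).
#' @param steepness Slope parameter (1/trait units, signed; 0 gives the
#'   constant \eqn{(lower + upper)/2}).
#' @return An object of class `"sigmoid_params"`.
#' @export
make_sigmoid <- function(lower, upper, midpoint, steepness) {
  if (lower < 0 || upper < 0) stop("sigmoid asymptotes must be >= 0")
  structure(list(lower = lower, upper = upper, midpoint = midpoint,
                 steepness = steepness), class = "sigmoid_params")
}

#' Evaluate a sigmoid transition-rate curve
#'
#' \eqn{q(x) = lower + (upper - lower) \cdot
#' \mathrm{logistic}(steepness (x - midpoint))}; always non-negative, and
#' constant (the mean of the asymptotes) when `steepness = 0`.
#'
#' @param x Trait value(s).
#' @param p A `"sigmoid_params"` object.
#' @return Transition rate(s).
#' @export
sigmoid_rate <- function(x, p) {
  p$lower + (p$upper - p$lower) * stats::plogis(p$steepness * (x - p$midpoint))
}

#' Generator for continuous-character dependent discrete evolution
#'
#' A \eqn{2n \times 2n} generator in which both discrete levels share one
#' diffusion rate for the continuous trait and the level-switch rate at bin
#' `i` is the sigmoid curve evaluated at that bin's center, in each
#' direction. With flat sigmoids (`lower == upper`) this reduces exactly to
#' [generator_joint()] with constant rates.
#'
#' @param grid A `"trait_grid"`.
#' @param sigma2 Shared diffusion rate.
#' @param p_ab,p_ba `"sigmoid_params"` for the a->b and b->a switch rates.
#' @param boundary Boundary convention for the diffusion blocks.
#' @return A `"ctmc_generator"` with `k = 2`.
#' @export
generator_xdep <- function(grid, sigma2, p_ab, p_ba,
                           boundary = c("reassign", "omit")) {
  boundary <- match.arg(boundary)
  n <- grid$n
  blk <- unclass(generator_diffusion(grid, sigma2, boundary))
  Q <- matrix(0, 2 * n, 2 * n)
  ia <- seq_len(n); ib <- n + seq_len(n)
  Q[ia, ia] <- blk
  Q[ib, ib] <- blk
  Q[cbind(ia, ib)] <- sigmoid_rate(grid$centers, p_ab)
  Q[cbind(ib, ia)] <- sigmoid_rate(grid$centers, p_ba)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  labels <- as.vector(t(outer(c("a", "b"), sprintf("bin%d", seq_len(n)),
                              paste, sep = ":")))
  new_generator(Q, grid, labels = labels, k = 2L)
}

#' Export a generator as tab-separated text
#'
#' @param Q A `"ctmc_generator"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_tsv <- function(Q, path) {
  utils::write.table(as.matrix(unclass(Q)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
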