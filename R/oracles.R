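#' Brownian-motion covariance structure of a tree
#'
#' \eqn{C[i, j]} is the height above the root of the most recent common
#' ancestor of tips i and j (the shared path length); tip variances sit on
#' the diagonal. The trait covariance is \eqn{\sigma^2 C}.
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Diffusion rate (default 1).
#' @return List with `C` (time units) and `V = sigma2 * C`.
#' @export
bm_cov <- function(tree, sigma2 = 1) {
  C <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    C <- C + tree$root.edge  # stem edge below the root shifts all entries
  list(C = C, V = sigma2 * C)
}

#' Exact multivariate-normal log-density under unbounded Brownian motion
#'
#' @param tree A `"phylo"` object.
#' @param x0 Root value.
#' @param sigma2 Diffusion rate.
#' @param x Named tip values.
#' @return Log-density (a scalar).
#' @export
bm_logdensity <- function(tree, x0, sigma2, x) {
  V <- bm_cov(tree, sigma2)$V
  x <- x[rownames(V)]
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular covariance (duplicate zero-length tips?)"))
  z <- backsolve(ch, x - x0, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Multivariate-normal rectangle probability by nested quadrature
#'
#' \eqn{P(l \le X \le u)} for small dimension (N <= 4), computed by
#' recursive conditioning: adaptive 1-D integration over the first
#' coordinate of its marginal density times the conditional rectangle
#' probability of the rest; the innermost factor is a normal CDF
#' difference. Infinite limits are clipped at 8.5 marginal standard
#' deviations.
#'
#' @param mu Mean vector.
#' @param Sigma Covariance matrix.
#' @param lower,upper Rectangle limits (may be infinite).
#' @param abs_tol Absolute integration tolerance (default 1e-8).
#' @return Probability.
#' @export
mvn_rect_prob <- function(mu, Sigma, lower, upper, abs_tol = 1e-8) {
  d <- length(mu)
  if (d > 4) stop("N too large for reliable nested integration (N <= 4)")
  if (d == 1) {
    s <- sqrt(Sigma[1, 1])
    return(stats::pnorm(upper, mu, s) - stats::pnorm(lower, mu, s))
  }
  s1 <- sqrt(Sigma[1, 1])
  lo <- max(lower[1], mu[1] - 8.5 * s1)
  hi <- min(upper[1], mu[1] + 8.5 * s1)
  if (!(hi > lo)) return(0)
  cond <- function(x1) {
    w <- Sigma[-1, 1] / Sigma[1, 1]
    mu_c <- mu[-1] + w * (x1 - mu[1])
    Sig_c <- Sigma[-1, -1] - outer(w, Sigma[1, -1])
    mvn_rect_prob(mu_c, Sig_c, lower[-1], upper[-1],
                  abs_tol = abs_tol / 10)
  }
  f <- function(x) vapply(x, function(xi)
    stats::dnorm(xi, mu[1], s1) * cond(xi), numeric(1))
  stats::integrate(f, lo, hi, abs.tol = abs_tol,
                   rel.tol = 1e-8, subdivisions = 200L)$value
}

#' Exact threshold-model tip-state probability for small trees
#'
#' Probability that each tip liability falls in its level's threshold
#' interval, under Brownian liability evolution from a known root
#' liability: a multivariate-normal rectangle probability over the product
#' of tip intervals.
#'
#' @param tree A `"phylo"` object with N <= 4 tips.
#' @param thresholds Strictly increasing threshold values.
#' @param tip_levels Named integer vector of tip levels (1-based interval
#'   index).
#' @param root_liability Root liability value.
#' @param sigma2 Liability diffusion rate (default 1).
#' @return Probability.
#' @export
threshold_prob_exact <- function(tree, thresholds, tip_levels,
                                 root_liability = 0, sigma2 = 1) {
  V <- bm_cov(tree, sigma2)$V
  lv <- tip_levels[rownames(V)]
  cuts <- c(-Inf, thresholds, Inf)
  mvn_rect_prob(rep(root_liability, nrow(V)), V,
                cuts[lv], cuts[lv + 1])
}

#' Exact semi-threshold log-density for small trees
#'
#' Point-valued tips contribute the multivariate-normal density at their
#' values; censored tips contribute the conditional probability (given the
#' point tips) of the corresponding semi-infinite interval, computed by
#' nested quadrature.
#'
#' @param tree A `"phylo"` object with N <= 4 tips.
#' @param x0 Root value.
#' @param sigma2 Diffusion rate.
#' @param clamp Observable window `(low, high)`.
#' @param obs Data frame with columns `taxon`, `value`, `censored` (as
#'   produced by [sim_semithreshold()]).
#' @return Log-density (point tips on the density scale, censored tips on
#'   the probability scale).
#' @export
semithreshold_logdensity_exact <- function(tree, x0, sigma2, clamp, obs) {
  V <- bm_cov(tree, sigma2)$V
  obs <- obs[match(rownames(V), obs$taxon), ]
  cen <- !is.na(obs$censored) & nzchar(obs$censored)
  mu <- rep(x0, nrow(V))
  if (!any(cen)) return(bm_logdensity(tree, x0, sigma2,
                                      stats::setNames(obs$value, obs$taxon)))
  lower <- ifelse(obs$censored[cen] == "low", -Inf, clamp[2])
  upper <- ifelse(obs$censored[cen] == "low", clamp[1], Inf)
  if (all(cen))
    return(log(mvn_rect_prob(mu, V, lower, upper)))
  xp <- obs$value[!cen]
  Vpp <- V[!cen, !cen, drop = FALSE]
  ch <- chol(Vpp)
  z <- backsolve(ch, xp - mu[!cen], transpose = TRUE)
  log_dens_p <- -0.5 * (length(xp) * log(2 * pi) +
                          2 * sum(log(diag(ch))) + sum(z^2))
  W <- V[cen, !cen, drop = FALSE] %*% chol2inv(ch)
  mu_c <- mu[cen] + as.vector(W %*% (xp - mu[!cen]))
  Sig_c <- V[cen, cen, drop = FALSE] - W %*% V[!cen, cen, drop = FALSE]
  log_dens_p + log(mvn_rect_prob(mu_c, Sig_c, lower, upper))
}
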