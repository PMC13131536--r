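#' Run one of the package's simulation studies
#'
#' Turnkey replication of the five parameter-recovery experiments at
#' configurable scale: `"bounded"` (bounded vs unbounded Brownian fitting),
#' `"threshold"` (threshold model vs ordered Mk competitors with Akaike
#' weights), `"semithreshold"` (censored vs plain Brownian fitting),
#' `"statedep"` (joint discrete+continuous fitting vs Mk-only and,
#' optionally, the two-step stochastic-mapping workflow), and
#' `"multitrend"` (state-dependent trends on non-ultrametric trees).
#' Generating conditions follow the published designs; tree depth for the
#' bounded and semi-threshold studies (1.0) and the root-state
#' distributions, where unstated, are package choices documented in the
#' methods vignette.
#'
#' @param study Study name (see above).
#' @param n_reps Number of replicates.
#' @param n_taxa Tips per simulated pure-birth tree.
#' @param seed Master seed; every replicate derives its own stream from it.
#' @param n_bins Bins for discretized fits (default per study: 200 for
#'   threshold, 100 for statedep, 160 for multitrend, 100/150 for
#'   bounded/semithreshold).
#' @param include_twostep For `"statedep"`: also run the two-step
#'   stochastic-mapping comparator.
#' @param n_maps Stochastic maps per replicate for the two-step fit.
#' @param verbose Print one progress line per replicate.
#' @return A data frame, one row per replicate, with `gen_*` (generating)
#'   and `est_*` (estimated) columns plus study-specific extras.
#' @export
run_study <- function(study = c("bounded", "threshold", "semithreshold",
                                "statedep", "multitrend"),
                      n_reps = 20, n_taxa = 100, seed = 1,
                      n_bins = NULL, include_twostep = FALSE,
                      n_maps = 100, verbose = FALSE) {
  study <- match.arg(study)
  if (n_reps == 0) return(data.frame())
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rows[[i]] <- tryCatch(
      run_study_rep(study, n_taxa, rep_seeds[i], n_bins,
                    include_twostep, n_maps),
      error = function(e) {
        warning(sprintf("%s rep %d failed: %s", study, i,
                        conditionMessage(e)))
        NULL
      })
    if (verbose && !is.null(rows[[i]]))
      cat(sprintf("[%s] rep %d/%d done (lnL ok)\n", study, i, n_reps))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

run_study_rep <- function(study, n_taxa, seed, n_bins,
                          include_twostep, n_maps) {
  set.seed(seed)
  switch(study,
    bounded = {
      nb <- n_bins %||% 100
      tree <- simulate_pure_birth(n_taxa, depth = 1)
      s2 <- exp(stats::rnorm(1))
      x0 <- stats::runif(1, -0.9, 0.9)
      x <- sim_bounded(tree, x0 = x0, sigma2 = s2, a = -1, b = 1)
      fb <- fit_bounded_bm(tree, x, bounds = c(-1, 1), n_bins = nb)
      fu <- fit_bm_analytic(tree, x)
      data.frame(seed = seed, gen_sigma2 = s2, gen_x0 = x0,
                 est_sigma2_bounded = fb$params$sigma2,
                 est_x0_bounded = fb$params$x0,
                 est_sigma2_bm = fu$params$sigma2,
                 est_x0_bm = fu$params$x0)
    },
    threshold = {
      nb <- n_bins %||% 200
      tree <- simulate_pure_birth(n_taxa, depth = 3)
      x0 <- stats::runif(1, -1, 3)
      sim <- sim_threshold(tree, x0 = x0, sigma2 = 1,
                           thresholds = c(0, 0.8, 1))
      lev <- sort(unique(sim$states))
      if (length(lev) < 2) return(NULL)
      ft <- fit_threshold(tree, sim$states, levels = lev, n_bins = nb)
      fs <- fit_mk(tree, sim$states, "ordered-sym", levels = lev)
      fa <- fit_mk(tree, sim$states, "ordered-asym", levels = lev)
      w <- akaike_weights(list(threshold = ft, mk_sym = fs, mk_asym = fa))
      thr <- ft$params$thresholds
      data.frame(seed = seed, gen_x0 = x0, n_levels = length(lev),
                 w_threshold = w[["threshold"]],
                 w_mk_sym = w[["mk_sym"]], w_mk_asym = w[["mk_asym"]],
                 top_model = names(w)[which.max(w)],
                 gen_thr_bc = 0.8,
                 est_thr_bc = if ("b|c" %in% names(thr)) thr[["b|c"]]
                              else NA_real_,
                 gen_thr_cd = 1,
                 est_thr_cd = if ("c|d" %in% names(thr)) thr[["c|d"]]
                              else NA_real_)
    },
    semithreshold = {
      nb <- n_bins %||% 150
      tree <- simulate_pure_birth(n_taxa, depth = 1)
      s2 <- exp(stats::rnorm(1))
      x0 <- stats::runif(1, -1, 1)
      sim <- sim_semithreshold(tree, x0 = x0, sigma2 = s2,
                               clamp = c(-1, 1))
      cen <- !is.na(sim$obs$censored)
      if (all(cen) && length(unique(sim$obs$censored[cen])) == 1)
        return(NULL)
      fs <- fit_semithreshold(tree, sim$obs, clamp = c(-1, 1),
                              n_bins = nb)
      xfill <- ifelse(cen, ifelse(sim$obs$censored == "low", -1, 1),
                      sim$obs$value)
      names(xfill) <- sim$obs$taxon
      fu <- fit_bm_analytic(tree, xfill)
      data.frame(seed = seed, gen_sigma2 = s2, gen_x0 = x0,
                 frac_censored = mean(cen),
                 est_sigma2_semi = fs$params$sigma2,
                 est_x0_semi = fs$params$x0,
                 est_sigma2_bm = fu$params$sigma2,
                 est_x0_bm = fu$params$x0)
    },
    statedep = {
      nb <- n_bins %||% 100
      tree <- simulate_pure_birth(n_taxa, depth = 1)
      q <- stats::runif(1, 1, 10)
      s2a <- stats::runif(1, 0.5, 2)
      s2b <- stats::runif(1, 5, 20)
      Qd <- matrix(c(-q, q, q, -q), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
      hist <- sim_mk_history(tree, Qd, root_level = sample(2, 1))
      if (length(unique(hist$tip_states)) < 2) return(NULL)
      x <- sim_statedep(tree, hist, c(a = s2a, b = s2b), x0 = 0)
      fj <- fit_statedep_bm(tree, hist$tip_states, x, n_bins = nb)
      fm <- fit_mk(tree, hist$tip_states, "ER")
      row <- data.frame(seed = seed, gen_q = q, gen_sigma2_a = s2a,
                        gen_sigma2_b = s2b,
                        est_q_joint = fj$params$q,
                        est_q_mk = fm$params$rates[[1]],
                        est_sigma2_a = fj$params$sigma2_a,
                        est_sigma2_b = fj$params$sigma2_b,
                        gen_ratio = s2b / s2a,
                        est_ratio_joint =
                          fj$params$sigma2_b / fj$params$sigma2_a)
      if (include_twostep) {
        ts <- fit_twostep(tree, hist$tip_states, x, n_maps = n_maps)
        row$est_ratio_twostep <- ts$sigma2[["b"]] / ts$sigma2[["a"]]
        row$est_sigma2_a_twostep <- ts$sigma2[["a"]]
        row$est_sigma2_b_twostep <- ts$sigma2[["b"]]
      }
      row
    },
    multitrend = {
      nb <- n_bins %||% 160
      tree <- make_nonultrametric(simulate_pure_birth(n_taxa, depth = 10))
      q <- 0.5
      mu_a <- stats::runif(1, 0.2, 1)
      mu_b <- stats::runif(1, -1, -0.2)
      s2a <- stats::runif(1, 0.3, 1)
      s2b <- stats::runif(1, 0.3, 1)
      Qd <- matrix(c(-q, q, q, -q), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
      hist <- sim_mk_history(tree, Qd, root_level = sample(2, 1))
      if (length(unique(hist$tip_states)) < 2) return(NULL)
      x <- sim_statedep(tree, hist, c(a = s2a, b = s2b),
                        mu_by_state = c(a = mu_a, b = mu_b), x0 = 0)
      fj <- fit_multitrend(tree, hist$tip_states, x, n_bins = nb)
      fm <- fit_mk(tree, hist$tip_states, "ER")
      data.frame(seed = seed, gen_q = q, gen_mu_a = mu_a,
                 gen_mu_b = mu_b, gen_sigma2_a = s2a,
                 gen_sigma2_b = s2b,
                 est_q_joint = fj$params$q,
                 est_q_mk = fm$params$rates[[1]],
                 est_mu_a = fj$params$mu_a, est_mu_b = fj$params$mu_b,
                 est_sigma2_a = fj$params$sigma2_a,
                 est_sigma2_b = fj$params$sigma2_b)
    })
}

#' Summarize a study results table
#'
#' For every `est_*` column that pairs with a `gen_*` column (matching
#' suffixes, or the shared generating value for multiple estimators) the
#' summary reports the Pearson correlation, the regression slope of
#' estimates on generating values, the mean bias and the SD of estimates.
#' Constant columns yield `NA` correlations, reported as such. Akaike-
#' weight tallies are added for the threshold study and transition-rate
#' means/SDs for the joint-vs-Mk comparisons.
#'
#' @param df A data frame from [run_study()].
#' @return A list with elements `params` (per-parameter summary data
#'   frame) and, when applicable, `akaike` and `q_comparison`.
#' @export
summarize_study <- function(df) {
  if (!nrow(df)) return(list(params = data.frame()))
  est_cols <- grep("^est_", names(df), value = TRUE)
  gen_cols <- grep("^gen_", names(df), value = TRUE)
  gen_for <- function(ec) {
    suf <- sub("^est_", "", ec)
    hit <- gen_cols[vapply(sub("^gen_", "", gen_cols), function(g)
      startsWith(suf, g), TRUE)]
    if (!length(hit)) return(NA_character_)
    hit[which.max(nchar(hit))]
  }
  rows <- lapply(est_cols, function(ec) {
    gc <- gen_for(ec)
    if (is.na(gc)) return(NULL)
    ok <- stats::complete.cases(df[[ec]], df[[gc]])
    g <- df[[gc]][ok]; e <- df[[ec]][ok]
    const <- stats::var(g) < 1e-12 || stats::var(e) < 1e-12
    data.frame(parameter = ec, generating = gc, n = sum(ok),
               correlation = if (const) NA_real_ else stats::cor(g, e),
               slope = if (stats::var(g) < 1e-12) NA_real_
                       else stats::cov(g, e) / stats::var(g),
               bias = mean(e - g), sd_est = stats::sd(e))
  })
  out <- list(params = do.call(rbind, rows))
  if ("top_model" %in% names(df))
    out$akaike <- list(
      frac_threshold_top = mean(df$top_model == "threshold"),
      frac_weight_ge_0.75 = mean(df$w_threshold >= 0.75))
  if (all(c("est_q_joint", "est_q_mk") %in% names(df)))
    out$q_comparison <- data.frame(
      method = c("joint", "mk"),
      mean = c(mean(df$est_q_joint), mean(df$est_q_mk)),
      sd = c(stats::sd(df$est_q_joint), stats::sd(df$est_q_mk)),
      cor_with_gen = c(
        if (stats::var(df$gen_q) > 1e-12)
          stats::cor(df$gen_q, df$est_q_joint) else NA_real_,
        if (stats::var(df$gen_q) > 1e-12)
          stats::cor(df$gen_q, df$est_q_mk) else NA_real_))
  out
}
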