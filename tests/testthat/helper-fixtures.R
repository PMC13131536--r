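# Small fixture trees used across the suite.

# Two terminal taxa with root-to-tip paths 1.0 and 0.7 whose common
# ancestor sits at height 0.4 (the canonical two-taxon illustration).
fig_tree <- function() {
  tr <- parse_newick("(T1:0.6,T2:0.3);")
  tr$root.edge <- 0.4
  tr
}

# Same tree with the stem represented as an explicit degree-one root, for
# simulators that walk the edge matrix.
fig_tree_stem <- function() {
  ape::read.tree(text = "((T1:0.6,T2:0.3):0.4);")
}

cherry <- function(t1 = 1, t2 = 1) {
  parse_newick(sprintf("(A:%g,B:%g);", t1, t2))
}

star_tree <- function(n = 5, depth = 1) {
  labs <- paste0("t", seq_len(n))
  parse_newick(paste0("(", paste0(labs, ":", depth, collapse = ","), ");"))
}

# ML of a single-sigma2 joint (level, bin) model with constant switch rate,
# used as the nested special case of richer joint models.
fit_joint_single_sigma <- function(tree, y, x, n_bins, padding = 0.5) {
  levels <- sort(unique(y))
  grid <- default_grid(x, n_bins, padding)
  obs <- stats::setNames(lapply(tree$tip.label, function(l)
    tip_joint(match(y[[l]], levels), x[[l]])), tree$tip.label)
  tipL <- encode_tips(obs, tree, grid, k = length(levels))
  obj <- function(par) {
    Q <- generator_joint(grid, rep(exp(par[1]), length(levels)),
                         exp(par[2]), level_names = levels)
    lp <- prune_loglik(tree, Q, tipL, "ml-bin")
    -(as.numeric(lp) - length(x) * log(grid$delta))
  }
  o <- stats::optim(c(log(stats::var(x) / tree_depth(tree)), log(1)), obj,
                    method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-9))
  list(loglik = -o$value, par = exp(o$par))
}
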