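#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees are stored as
#' standard `"phylo"` objects; every downstream function in the package
#' consumes these directly. Branch lengths are required, tip labels must be
#' unique, and non-positive edge lengths are rejected unless explicitly
#' tolerated.
#'
#' @param text Newick string (with branch lengths).
#' @param allow_zero Tolerate zero-length edges? Default `FALSE`.
#' @return An object of class `"phylo"`.
#' @export
parse_newick <- function(text, allow_zero = FALSE) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string")
  if (is.null(tree$edge.length))
    stop("Newick string has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("missing branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels")
  if (any(tree$edge.length < 0) ||
      (!allow_zero && any(tree$edge.length == 0)))
    stop("non-positive edge lengths (set allow_zero = TRUE to tolerate 0)")
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Simulate a pure-birth (Yule) tree rescaled to a fixed depth
#'
#' Grows a constant-rate pure-birth tree to `n_taxa` tips (speciation rate
#' 1, no extinction) and then rescales all branch lengths multiplicatively
#' so that every root-to-tip path equals `depth`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param depth Target tree depth in time units.
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric `"phylo"` object with `n_taxa` tips.
#' @export
simulate_pure_birth <- function(n_taxa, depth = 1, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (depth <= 0) stop("depth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  h <- max(node_heights(tree))
  tree$edge.length <- tree$edge.length * (depth / h)
  tree
}

#' Make an ultrametric tree non-ultrametric by shortening terminal edges
#'
#' Each terminal edge is shortened by a uniform fraction
#' `U(0, max_fraction)` of its own length, except for one randomly chosen
#' tip which is left untouched so that the maximum tip height still equals
#' the original tree depth. This is a stand-in mechanism: how non-ultrametric
#' trees "of total length 10" should be generated is genuinely
#' underdetermined, and the shortening distribution is exposed as a knob.
#'
#' @param tree Ultrametric `"phylo"` object.
#' @param seed Optional integer seed.
#' @param max_fraction Upper limit of the uniform shortening fraction
#'   (default 0.5; must be < 1 so edges stay positive).
#' @return A non-ultrametric `"phylo"` of the same depth.
#' @export
make_nonultrametric <- function(tree, seed = NULL, max_fraction = 0.5) {
  if (!ape::is.ultrametric(tree, tol = 1e-8))
    stop("input tree must be ultrametric")
  if (max_fraction < 0 || max_fraction >= 1)
    stop("max_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  term <- which(tree$edge[, 2] <= ntip)
  frac <- stats::runif(length(term), 0, max_fraction)
  frac[sample(length(term), 1)] <- 0  # keep the original depth attainable
  tree$edge.length[term] <- tree$edge.length[term] * (1 - frac)
  tree
}

#' Node heights above the root
#'
#' Height of every node (cumulative branch length from the root), with the
#' root at height 0. The first `ntip` entries are tip heights, named by tip
#' label.
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of node heights with attribute `"depth"` (the
#'   maximum tip height).
#' @export
node_heights <- function(tree) {
  h <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  names(h) <- c(tree$tip.label, rep("", length(h) - ntip))
  attr(h, "depth") <- max(h[seq_len(ntip)])
  h
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree A `"phylo"` object.
#' @return Numeric scalar.
#' @export
tree_depth <- function(tree) {
  attr(node_heights(tree), "depth")
}
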