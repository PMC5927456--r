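#' Simulate a tree with soft polytomies and correlated Brownian traits
#'
#' Builds a random rooted topology, collapses a requested fraction of its
#' internal edges into soft polytomies, assigns the conventional branch
#' lengths used for contrasts ([assign_convention_lengths()]), and evolves
#' two traits on those lengths: the predictor `x` by Brownian motion with
#' rate `sigma_x^2`, and the response `y = beta * x + e`, where `e` is an
#' independent Brownian noise with rate `sigma_e^2`. Because traits evolve
#' on the same branch lengths the contrasts use, a through-origin
#' regression of the `y` contrasts on the `x` contrasts is centred on
#' `beta`. Deterministic under `seed`.
#'
#' @param n_tips Number of tips, >= 4.
#' @param polytomy_fraction Fraction of collapsible internal edges turned
#'   into polytomies (0 = fully binary).
#' @param beta Generating slope of `y` on `x`.
#' @param sigma_x,sigma_e Brownian rates (SD per unit branch length) of
#'   the predictor and of the independent noise.
#' @param seed Integer seed.
#' @return List with `tree` (a `phylo` with convention branch lengths),
#'   named trait vectors `x` and `y`, and the generating parameters.
#' @export
simulate_bm_tree <- function(n_tips, polytomy_fraction = 0, beta = 1,
                             sigma_x = 1, sigma_e = 1, seed = 1) {
  if (n_tips < 4) stop_input("n_tips must be >= 4")
  if (polytomy_fraction < 0 || polytomy_fraction > 1) {
    stop_input("polytomy_fraction must be in [0, 1]")
  }
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  tree$edge.length <- rep(1, nrow(tree$edge))
  if (polytomy_fraction > 0) {
    internal <- which(tree$edge[, 2] > ape::Ntip(tree))
    n_collapse <- floor(length(internal) * polytomy_fraction)
    if (n_collapse > 0) {
      collapse <- sample(internal, n_collapse)
      tree$edge.length[collapse] <- 0
      tree <- ape::di2multi(tree, tol = 1e-8)
    }
  }
  tree <- assign_convention_lengths(tree)

  # accumulate Brownian increments from the root down
  n_all <- ape::Ntip(tree) + tree$Nnode
  xval <- eval_ <- numeric(n_all)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; child <- edges[k, 2]
    xval[child] <- xval[par] + rnorm(1, 0, sigma_x * sqrt(lens[k]))
    eval_[child] <- eval_[par] + rnorm(1, 0, sigma_e * sqrt(lens[k]))
  }
  tips <- seq_len(ape::Ntip(tree))
  x <- stats::setNames(xval[tips], tree$tip.label)
  y <- stats::setNames(beta * xval[tips] + eval_[tips], tree$tip.label)
  list(tree = tree, x = x, y = y, beta = beta,
       sigma_x = sigma_x, sigma_e = sigma_e, seed = seed)
}
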