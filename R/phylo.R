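#' Read a rooted phylogeny from Newick text or file
#'
#' Thin wrapper over [ape::read.tree()] that validates the properties the
#' contrast machinery needs: unique tip labels, a root with at least two
#' children, and soft polytomies retained exactly as written (never
#' auto-resolved).
#'
#' @param newick A Newick string (contains parentheses and a terminal
#'   semicolon) or a path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylo <- function(newick) {
  tree <- if (length(newick) == 1 && grepl("\\(", newick)) {
    tryCatch(ape::read.tree(text = newick),
             error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(newick), error = function(e) NULL)
  }
  if (is.null(tree)) stop_input("could not parse Newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop_input("duplicate tip labels: %s",
               paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                     collapse = ", "))
  }
  root <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1] == root) < 2) {
    stop_input("root must have at least two children")
  }
  tree
}

#' Write a tree back to Newick text
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Assign the fixed branch-length convention for contrasts at polytomies
#'
#' Replaces all branch lengths with the punctuational convention used for
#' contrasts on composite trees without meaningful lengths: branches whose
#' parent node is a polytomy (more than two daughters) get length
#' `polytomy_internal`, every other branch gets length `other`. Existing
#' lengths are overwritten.
#'
#' @param tree A `phylo` object.
#' @param polytomy_internal Length for daughters of polytomies (default 1).
#' @param other Length for all other branches (default 2).
#' @return The tree with conventional branch lengths.
#' @export
assign_convention_lengths <- function(tree, polytomy_internal = 1,
                                      other = 2) {
  n_children <- table(tree$edge[, 1])
  parent_of_edge <- as.character(tree$edge[, 1])
  poly <- as.vector(n_children[parent_of_edge] > 2)
  tree$edge.length <- ifelse(poly, polytomy_internal, other)
  tree
}

# 1/v-weighted mean and its effective branch length.
weighted_node <- function(vals, v) {
  w <- 1 / v
  list(value = sum(w * vals) / sum(w), length = 1 / sum(w))
}

#' Phylogenetically independent contrasts with single-contrast polytomies
#'
#' Computes standardized contrasts of a predictor `x` and a response `y`
#' over a rooted tree by post-order traversal (the crunch approach).
#' Binary nodes follow the classic recurrence: the raw daughter difference
#' is divided by the square root of the summed (adjusted) daughter branch
#' lengths, the node takes the 1/v-weighted mean of its daughters, and the
#' node's own branch is lengthened by the variance of that mean.
#'
#' A polytomy yields exactly *one* contrast: its daughters are split about
#' the unweighted mean of their predictor values (group A holds values at
#' or below the mean), each group is collapsed to its 1/v-weighted mean
#' with effective length `1/sum(1/v)`, and the two aggregates are
#' contrasted. When all daughter predictor values are equal the split is
#' degenerate and the contrast is flagged invalid (excluded from
#' regression but still reported). The same orientation and divisor are
#' applied to the response, and each contrast is positivized on the
#' predictor with the response sign flipped in tandem.
#'
#' @param tree A `phylo` object with branch lengths assigned (see
#'   [assign_convention_lengths()]).
#' @param x,y Named numeric vectors (names = tip labels): predictor and
#'   response values for every tip.
#' @return Tibble with one row per internal node: `node_id`, `u`
#'   (standardized predictor contrast, >= 0), `w` (standardized response
#'   contrast), `variance` (the squared divisor, i.e. summed adjusted
#'   lengths), `n_daughters`, `valid`, `reason`.
#' @examples
#' tree <- assign_convention_lengths(read_phylo("(A,B,C);"))
#' pic_contrasts(tree, c(A = 1, B = 2, C = 9), c(A = 0, B = 1, C = 5))
#' @export
pic_contrasts <- function(tree, x, y) {
  n_tip <- ape::Ntip(tree)
  if (is.null(tree$edge.length)) {
    stop_input("tree has no branch lengths; assign them first")
  }
  if (any(tree$edge.length <= 0)) {
    stop_input("all branch lengths must be positive")
  }
  missing_x <- setdiff(tree$tip.label, names(x))
  missing_y <- setdiff(tree$tip.label, names(y))
  if (length(missing_x) || length(missing_y)) {
    stop_input("tip(s) without trait values: %s",
               paste(unique(c(missing_x, missing_y)), collapse = ", "))
  }
  n_node <- tree$Nnode
  xv <- yv <- numeric(n_tip + n_node)
  xv[seq_len(n_tip)] <- x[tree$tip.label]
  yv[seq_len(n_tip)] <- y[tree$tip.label]
  # working branch length of the edge above each node (grows as daughter
  # means are substituted); root keeps NA
  vlen <- numeric(n_tip + n_node)
  vlen[tree$edge[, 2]] <- tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(po$edge[, 1])
  children_of <- split(po$edge[, 2], po$edge[, 1])

  rows <- purrr::map(parents, function(node) NULL)
  names(rows) <- parents
  for (node in parents) {
    cs <- children_of[[as.character(node)]]
    vx <- xv[cs]; vy <- yv[cs]; vv <- vlen[cs]
    k <- length(cs)
    if (k == 1) {
      # degree-1 internal node (should not occur on valid trees): pass up
      xv[node] <- vx; yv[node] <- vy
      vlen[node] <- vlen[node] + vv
      next
    }
    if (k == 2) {
      denom <- sqrt(sum(vv))
      u <- (vx[1] - vx[2]) / denom
      w <- (vy[1] - vy[2]) / denom
      valid <- TRUE
      reason <- NA_character_
    } else {
      grp_a <- vx <= mean(vx)
      if (all(grp_a)) {
        u <- NA_real_; w <- NA_real_
        valid <- FALSE
        reason <- "degenerate split: all daughter predictor values equal"
        denom <- NA_real_
      } else {
        a_x <- weighted_node(vx[grp_a], vv[grp_a])
        b_x <- weighted_node(vx[!grp_a], vv[!grp_a])
        a_y <- weighted_node(vy[grp_a], vv[grp_a])
        b_y <- weighted_node(vy[!grp_a], vv[!grp_a])
        denom <- sqrt(a_x$length + b_x$length)
        u <- (a_x$value - b_x$value) / denom
        w <- (a_y$value - b_y$value) / denom
        valid <- TRUE
        reason <- NA_character_
      }
    }
    if (isTRUE(valid) && !is.na(u) && u < 0) {
      u <- -u; w <- -w
    }
    node_x <- weighted_node(vx, vv)
    node_y <- weighted_node(vy, vv)
    xv[node] <- node_x$value
    yv[node] <- node_y$value
    vlen[node] <- vlen[node] + node_x$length
    rows[[as.character(node)]] <- tibble::tibble(
      node_id = node, u = u, w = w,
      variance = if (is.na(denom)) NA_real_ else denom^2,
      n_daughters = k, valid = valid, reason = reason)
  }
  dplyr::bind_rows(rows)
}

#' Regression of response contrasts on predictor contrasts through the origin
#'
#' Standardized contrasts have expectation zero, so the comparative
#' relationship between two traits is estimated by least squares through
#' the origin over the valid contrasts: `slope = sum(u w) / sum(u^2)`,
#' `r = sum(u w) / sqrt(sum(u^2) sum(w^2))`, with a two-sided p-value from
#' the t transform on `n_valid - 1` degrees of freedom.
#'
#' @param contrasts Tibble from [pic_contrasts()].
#' @return An object of class `origin_fit` with components `slope`, `r`,
#'   `p`, `n_valid`, `n_invalid` and the valid `contrasts`; see
#'   [tidy.origin_fit()], [glance.origin_fit()], [autoplot.origin_fit()].
#' @export
origin_regression <- function(contrasts) {
  check_columns(contrasts, c("u", "w", "valid"), "contrasts")
  ok <- dplyr::filter(contrasts, .data$valid, !is.na(.data$u),
                      !is.na(.data$w))
  n <- nrow(ok)
  if (n < 3) stop_degenerate("fewer than 3 valid contrasts")
  suw <- sum(ok$u * ok$w)
  su2 <- sum(ok$u^2)
  sw2 <- sum(ok$w^2)
  if (su2 == 0 || sw2 == 0) {
    stop_degenerate("contrasts have no variation")
  }
  r <- suw / sqrt(su2 * sw2)
  p <- if (abs(r) >= 1) 0 else {
    two_sided_p_from_t(r * sqrt((n - 1) / (1 - r^2)), n - 1)
  }
  structure(list(slope = suw / su2, r = r, p = p, n_valid = n,
                 n_invalid = nrow(contrasts) - n, contrasts = ok),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("Through-origin regression on independent contrasts\n")
  cat(sprintf("  slope = %.4f, r = %.4f, p = %.4g (n_valid = %d, %d invalid)\n",
              x$slope, x$r, x$p, x$n_valid, x$n_invalid))
  invisible(x)
}

#' Tidy a through-origin contrast regression
#'
#' @param x An `origin_fit` from [origin_regression()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `r`, `p.value`, `n_valid`.
#' @method tidy origin_fit
#' @export
tidy.origin_fit <- function(x, ...) {
  tibble::tibble(term = "u", estimate = x$slope, r = x$r, p.value = x$p,
                 n_valid = x$n_valid)
}

#' Glance at a through-origin contrast regression
#'
#' @inheritParams tidy.origin_fit
#' @return One-row tibble: `r`, `p.value`, `n_valid`, `n_invalid`.
#' @method glance origin_fit
#' @export
glance.origin_fit <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p, n_valid = x$n_valid,
                 n_invalid = x$n_invalid)
}
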