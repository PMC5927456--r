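test_that("Newick parsing keeps polytomies and validates structure", {
  two <- read_phylo("(A,B);")
  expect_equal(ape::Ntip(two), 2)
  mixed <- read_phylo("((A,B),(C,D,E));")
  degrees <- table(mixed$edge[, 1])
  expect_setequal(as.integer(degrees), c(2, 2, 3))
  expect_error(read_phylo("((A,B);"), class = "plastinorm_input_error")
  expect_error(read_phylo("(A,A);"), class = "plastinorm_input_error")
})

test_that("parse -> write -> parse round-trips topology on random trees", {
  set.seed(13)
  for (i in 1:10) {
    sim <- simulate_bm_tree(sample(5:20, 1),
                            polytomy_fraction = runif(1, 0, 0.5),
                            seed = i)
    txt <- write_newick(sim$tree)
    back <- read_phylo(txt)
    expect_true(ape::all.equal.phylo(sim$tree, back,
                                     use.edge.length = FALSE))
  }
})

test_that("convention lengths: polytomy daughters 1, all other branches 2", {
  bin <- assign_convention_lengths(read_phylo("((A,B),(C,D));"))
  expect_true(all(bin$edge.length == 2))
  tri <- assign_convention_lengths(read_phylo("(A,B,C);"))
  expect_true(all(tri$edge.length == 1))
  mixed <- assign_convention_lengths(read_phylo("((A,B,C),(D,E));"))
  # hand-annotated: 3 daughters of the polytomy get 1; the two root
  # branches and D,E branches get 2
  parent_deg <- table(mixed$edge[, 1])
  expected <- ifelse(parent_deg[as.character(mixed$edge[, 1])] > 2, 1, 2)
  expect_equal(mixed$edge.length, as.vector(expected))
})

test_that("two- and three-tip contrasts match hand-worked values", {
  tree2 <- read_phylo("(A:2,B:2);")
  c2 <- pic_contrasts(tree2, c(A = 3, B = 1), c(A = 5, B = 1))
  expect_equal(c2$u, 1)
  expect_equal(c2$w, 2)
  expect_equal(c2$variance, 4)

  tree3 <- read_phylo("((A:2,B:2):2,C:2);")
  c3 <- pic_contrasts(tree3, c(A = 4, B = 2, C = 0),
                      c(A = 4, B = 2, C = 0))
  expect_equal(sort(c3$u), sort(c(1, 3 / sqrt(3 + 2))))
  # after the inner node is collapsed its branch is 2 + (2*2/4) = 3
  expect_equal(sort(c3$variance), c(4, 5))
})

test_that("a polytomy emits exactly one contrast via the mean split", {
  tri <- assign_convention_lengths(read_phylo("(A,B,C);"))
  res <- pic_contrasts(tri, c(A = 1, B = 2, C = 9),
                       c(A = 2, B = 4, C = 18))
  expect_equal(nrow(res), 1)
  # groups {1,2} vs {9}: weighted means 1.5 and 9, lengths 1/2 and 1
  expect_equal(res$u, abs(1.5 - 9) / sqrt(0.5 + 1))
  expect_equal(res$w, 2 * res$u)  # y = 2x exactly
  expect_true(res$valid)
  # all daughters equal -> invalid contrast, still reported
  bad <- pic_contrasts(tri, c(A = 5, B = 5, C = 5),
                       c(A = 1, B = 2, C = 3))
  expect_false(bad$valid)
  expect_match(bad$reason, "degenerate")
  expect_error(pic_contrasts(tri, c(A = 1, B = 2), c(A = 1, B = 2, C = 3)),
               "C")
})

test_that("contrast counts: n-1 on binary trees, k-2 fewer per polytomy", {
  set.seed(19)
  for (i in 1:8) {
    n <- sample(4:40, 1)
    sim <- simulate_bm_tree(n, polytomy_fraction = 0, seed = 100 + i)
    expect_equal(nrow(pic_contrasts(sim$tree, sim$x, sim$y)), n - 1)
  }
  poly <- assign_convention_lengths(read_phylo("((A,B,C,D),(E,F));"))
  x <- stats::setNames(rnorm(6), LETTERS[1:6])
  res <- pic_contrasts(poly, x, x)
  # binary would give 5; the 4-way polytomy removes k-2 = 2
  expect_equal(nrow(res), 3)
})

test_that("binary-tree contrasts agree with the classic recurrence in ape", {
  set.seed(29)
  for (i in 1:6) {
    sim <- simulate_bm_tree(12, polytomy_fraction = 0, seed = 200 + i)
    ours <- pic_contrasts(sim$tree, sim$x, sim$y)
    ref_x <- ape::pic(sim$x[sim$tree$tip.label], sim$tree)
    ref_y <- ape::pic(sim$y[sim$tree$tip.label], sim$tree)
    expect_equal(sort(ours$u), unname(sort(abs(ref_x))), tolerance = 1e-10)
    # response contrasts match up to the positivization sign
    expect_equal(sort(abs(ours$w)), unname(sort(abs(ref_y))), tolerance = 1e-10)
    expect_equal(sum(ours$u * ours$w), sum(ref_x * ref_y),
                 tolerance = 1e-10)
  }
})

test_that("daughter relabelling and positivization leave results unchanged", {
  sim <- simulate_bm_tree(10, polytomy_fraction = 0.3, seed = 71)
  ours <- pic_contrasts(sim$tree, sim$x, sim$y)
  rot <- ape::rotateConstr(sim$tree, rev(sim$tree$tip.label))
  rot_res <- pic_contrasts(rot, sim$x, sim$y)
  expect_equal(sort(ours$u), sort(rot_res$u), tolerance = 1e-10)
  expect_equal(sort(ours$w), sort(rot_res$w), tolerance = 1e-10)
  expect_true(all(ours$u[ours$valid] >= 0))
  # |r| of the regression is invariant to flipping contrast signs
  fit <- origin_regression(ours)
  flipped <- dplyr::mutate(ours, u = -u, w = -w)
  expect_equal(abs(origin_regression(flipped)$r), abs(fit$r))
})

test_that("origin regression matches the normal-equation oracle", {
  u <- c(1, 2, 3, 4); w <- 2 * u
  fit <- origin_regression(tibble::tibble(u = u, w = w, valid = TRUE))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)

  w0 <- c(1, -1, 1, -1) * rep(c(2, 1), 2)
  orth <- tibble::tibble(u = c(2, 4, 2, 4), w = w0 - mean(w0 * c(2, 4, 2, 4)) /
                           mean(c(2, 4, 2, 4)^2) * c(2, 4, 2, 4),
                         valid = TRUE)
  expect_equal(origin_regression(orth)$slope, 0, tolerance = 1e-12)

  set.seed(83)
  u <- rnorm(20); w <- 1.3 * u + rnorm(20)
  fit2 <- origin_regression(tibble::tibble(u = u, w = w, valid = TRUE))
  expect_equal(fit2$slope, sum(u * w) / sum(u^2))
  expect_equal(fit2$r, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))
  td <- tidy(fit2); gl <- glance(fit2)
  expect_equal(td$estimate, fit2$slope)
  expect_equal(gl$n_valid, 20)

  expect_error(origin_regression(tibble::tibble(u = 1, w = 1,
                                                valid = TRUE)),
               class = "plastinorm_degenerate_error")
})
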