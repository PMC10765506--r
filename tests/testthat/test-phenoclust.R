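test_that("weighted Euclidean code distances match the formula", {
  codes <- rbind(c(1, 0, 0, 0, 0), c(2, 0, 0, 0, 0), c(1, 3, 0, 2, 0),
                 c(2, 0, 1, 0, 1))
  d <- as.matrix(euclidean_code_dist(codes))
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], 1)
  expect_equal(d[3, 4], sqrt(1 + 9 + 1 + 4 + 1))   # = 4
  dw <- as.matrix(euclidean_code_dist(codes, weights = c(4, 1, 1, 1, 1)))
  expect_equal(dw[1, 2], 2)
  expect_error(euclidean_code_dist(codes[1, , drop = FALSE]),
               class = "oenotype_not_enough_items")
  expect_error(euclidean_code_dist(rbind(c(0, 0, 0, 0, 0))),
               class = "oenotype_bad_input")
})

test_that("Ward linkage merges duplicates first and singletons at their distance", {
  X <- rbind(c(1, 1, 0, 2, 1), c(1, 1, 0, 2, 1), c(2, 3, 1, 0, 0))
  hc <- ward_linkage(dist(X))
  expect_equal(hc$height[1], 0)
  X2 <- rbind(c(1, 0, 0, 0, 0), c(1, 3, 0, 0, 0))
  hc2 <- ward_linkage(dist(X2))
  expect_equal(hc2$height, 3)
})

test_that("Ward linkage equals the exhaustive variance-objective oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    X <- matrix(runif(n * 5, 0, 3), n)
    hc <- ward_linkage(dist(X))
    expect_true(tree_agrees_with_oracle(hc, naive_ward(X)))
  }
})

test_that("the largest-gap rule picks k as specified", {
  expect_identical(as.integer(select_k(c(0.5, 0.7, 0.9, 4.0))), 2L)
  expect_identical(as.integer(select_k(c(1, 1.1, 5, 5.2, 5.4))), 4L)
  # the gap profile is returned for reporting
  gp <- attr(select_k(c(1, 1.1, 5, 5.2, 5.4)), "gaps")
  expect_equal(gp$gap[gp$k == 4], 3.9)
  # k_max restricts the candidates
  expect_identical(as.integer(select_k(c(1, 1.1, 5, 5.3, 5.4), k_max = 3)), 3L)
  # degenerate tree: all heights equal
  expect_warning(k <- select_k(c(1, 1, 1, 1)), "equal")
  expect_identical(as.integer(k), 2L)
})

test_that("cut levels behave at the extremes and nest properly", {
  panel <- gen_isolate_panel(n = 80, flip_prob = 0.05, seed = 9)
  fit <- phenoclust(panel)
  n_ph <- nrow(fit$codes)
  all_single <- cut_phenoclust(fit, n_ph)
  expect_equal(length(unique(all_single$assignment)), n_ph)
  one <- cut_phenoclust(fit, 1)
  expect_equal(unique(one$assignment), 1L)
  # moving k -> k+1 splits exactly one group
  for (k in 2:(min(6, n_ph - 1))) {
    pk <- cutree(fit$tree, k)
    pk1 <- cutree(fit$tree, k + 1)
    split_groups <- unique(pk[ave(pk1, pk, FUN = function(z)
      length(unique(z))) > 1])
    expect_equal(length(split_groups), 1L)
  }
})

test_that("two well-separated planted blobs are recovered at k = 2", {
  blob <- rbind(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0),
                c(2, 3, 1, 2, 1), c(2, 3, 1, 2, 0))
  truth <- c(1, 1, 2, 2)
  fit <- phenoclust(blob[rep(1:4, each = 5), ], k = 2)
  expect_equal(ari(fit$isolate_groups, rep(truth, each = 5)), 1)
})

test_that("the fit is invariant under permutation of isolate order", {
  panel <- gen_isolate_panel(n = 100, seed = 31)
  fit1 <- phenoclust(panel)
  set.seed(1); perm <- sample(nrow(panel))
  fit2 <- phenoclust(panel[perm, ])
  expect_identical(fit1$assignment, fit2$assignment)
  expect_equal(fit1$tree$height, fit2$tree$height)
  expect_identical(unname(fit1$isolate_groups[perm]),
                   unname(fit2$isolate_groups))
})

test_that("group labels order by desirability and profiles describe groups", {
  panel <- gen_isolate_panel(n = 150, flip_prob = 0.02, seed = 5)
  fit <- phenoclust(panel, k = 4)
  # penalties are reported ascending in the group label
  expect_true(all(diff(fit$penalty) >= 0))
  # the killer-sensitive prototype group is described as sensitive
  sens_group <- unique(fit$assignment[substr(names(fit$assignment), 1, 1) == "2"])
  prof <- characterize_groups(fit)
  expect_match(prof$text[sens_group[1]], "sensitive to killer toxin")
  # digit summaries stay within the coding bounds
  expect_true(all(vapply(seq_len(nrow(fit$codes)), function(i)
    all(fit$codes[i, ] >= c(1, 0, 0, 0, 0) & fit$codes[i, ] <= c(2, 3, 1, 2, 1)),
    logical(1))))
})

test_that("a single-member group's profile equals its code", {
  codes <- rbind(c(1, 0, 0, 2, 1), c(1, 0, 1, 2, 1), c(2, 3, 0, 0, 0))
  fit <- phenoclust(codes, k = 2)
  prof <- characterize_groups(fit)
  solo <- fit$assignment["23000"]
  expect_identical(unlist(prof$table[solo, ], use.names = FALSE),
                   c("2", "3", "0", "0", "0"))
})

test_that("species composition is a proper contingency table", {
  panel <- gen_isolate_panel(n = 120, flip_prob = 0, seed = 13)
  panel$species <- paste0("sp", panel$true_group)   # species assigned per group
  fit <- phenoclust(panel, k = 4)
  tab <- species_composition(fit, panel$species)
  expect_equal(sum(tab), 120)
  expect_equal(unname(rowSums(tab)), unname(as.vector(table(fit$isolate_groups))))
  # one species per planted group: exactly one nonzero cell per row
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("trees export as Newick strings ape can parse", {
  panel <- gen_isolate_panel(n = 40, seed = 2)
  fit <- phenoclust(panel)
  nwk <- export_newick(fit$tree)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy), nrow(fit$codes))
})
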