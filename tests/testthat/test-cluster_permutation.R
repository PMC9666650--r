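test_that("adjacency: triangle layouts are fully connected, montage is sane", {
  tri <- new_sensor_layout(c("a", "b", "c"),
                           rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)))
  tri <- build_adjacency(tri)
  expect_true(all(tri$adjacency[upper.tri(tri$adjacency)]))
  expect_false(any(diag(tri$adjacency)))

  # 2-electrode layout falls back to the radius method
  two <- new_sensor_layout(c("a", "b"), rbind(c(0, 0, 1), c(0.1, 0, 1)))
  expect_warning(two <- build_adjacency(two), "degenerate")
  expect_equal(two$adjacency_method$method, "radius")
  expect_true(two$adjacency["a", "b"])

  # shipped 64-channel montage: symmetric, irreflexive, connected,
  # median neighbour count in a physiological range (frozen regression)
  adj <- the_layout$adjacency
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(adjacency_connected(the_layout))
  expect_true(median(neighbour_counts(the_layout)) >= 4 &&
                median(neighbour_counts(the_layout)) <= 8)
})

test_that("electrode-level t statistics match hand values and t.test", {
  d <- cbind(e1 = c(1, 2, 3, 4), e2 = c(0, 0, 0, 0))
  expect_warning(st <- electrode_level_test(d, design = "paired"),
                 "zero-variance")
  expect_equal(st$t[1], sqrt(15))  # mean 2.5, SE sqrt(5/3)/2
  expect_equal(st$t[2], 0)
  expect_equal(st$p[2], 1)
  ref1 <- t.test(d[, 1])
  expect_equal(st$t[1], unname(ref1$statistic))
  expect_equal(st$p[1], ref1$p.value)

  set.seed(7)
  a <- matrix(rnorm(24), 6); b <- matrix(rnorm(32), 8)
  colnames(a) <- colnames(b) <- paste0("e", 1:4)
  st2 <- electrode_level_test(a, b, design = "independent")
  ref <- t.test(a[, 2], b[, 2], var.equal = TRUE)
  expect_equal(st2$t[2], unname(ref$statistic))
  expect_equal(st2$p[2], ref$p.value)

  st3 <- electrode_level_test(a, a, design = "independent")
  expect_equal(st3$t, rep(0, 4))
  expect_equal(st3$p, rep(1, 4))
})

test_that("clusters are maximal connected same-sign components", {
  adj <- matrix(FALSE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj[cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))] <- TRUE  # chain a-b-c, d isolated
  st <- data.frame(electrode = letters[1:4],
                   t = c(3.5, -3.6, -4.0, 5.0),
                   p = c(0.005, 0.004, 0.001, 0.002))
  cl <- form_clusters(st, adj)
  expect_length(cl, 3)
  masses <- vapply(cl, function(x) x$mass, numeric(1))
  expect_equal(sort(masses), sort(c(3.5, -7.6, 5.0)))
  # largest |mass| first: the b-c negative cluster
  expect_equal(cl[[1]]$members, c("b", "c"))
  expect_equal(cl[[1]]$mass, -7.6)
  expect_equal(cl[[1]]$sign, -1)

  # nothing suprathreshold -> empty list
  st0 <- st; st0$p <- 0.5
  expect_length(form_clusters(st0, adj), 0)

  # non-adjacent suprathreshold electrodes stay singleton clusters
  adj2 <- matrix(FALSE, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  st2 <- data.frame(electrode = c("x", "y"), t = c(4, 4.5),
                    p = c(0.001, 0.001))
  expect_length(form_clusters(st2, adj2), 2)
})

test_that("cluster masses are invariant to electrode reordering", {
  set.seed(11)
  n <- 12; E <- ncol(the_layout$adjacency)
  d <- matrix(rnorm(n * E), n, E, dimnames = list(NULL, the_layout$channels))
  d[, planted_electrodes(erp_template_spec(), the_layout, 1)] <-
    d[, planted_electrodes(erp_template_spec(), the_layout, 1)] + 1.5
  res <- permutation_test(d, adjacency = the_layout$adjacency,
                          design = "paired", n_perm = 200, seed = 4)
  perm <- sample(E)
  res_p <- permutation_test(d[, perm], adjacency = the_layout$adjacency[perm, perm],
                            design = "paired", n_perm = 200, seed = 4)
  expect_equal(res_p$max_mass, res$max_mass)
  expect_equal(sort(res_p$largest_cluster$members),
               sort(res$largest_cluster$members))
})

test_that("paired permutation p matches exhaustive sign-flip enumeration", {
  set.seed(3)
  n <- 6
  d <- matrix(rnorm(n * 8, mean = 0.9), n, 8,
              dimnames = list(NULL, paste0("e", 1:8)))
  adj <- matrix(TRUE, 8, 8); diag(adj) <- FALSE
  ex <- permutation_test(d, adjacency = adj, design = "paired",
                         n_perm = "exact", seed = 1)
  expect_equal(ex$n_permutations, 64)
  mc <- permutation_test(d, adjacency = adj, design = "paired",
                         n_perm = 2000, seed = 8, method = "montecarlo")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 2000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1e-3)
})

test_that("null distribution is invariant under global sign flip", {
  set.seed(5)
  d <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("e", 1:6)))
  adj <- matrix(TRUE, 6, 6); diag(adj) <- FALSE
  r1 <- permutation_test(d, adjacency = adj, design = "paired",
                         n_perm = 300, seed = 2)
  r2 <- permutation_test(-d, adjacency = adj, design = "paired",
                         n_perm = 300, seed = 2)
  expect_equal(r2$null_max_mass, r1$null_max_mass)
  expect_equal(r2$max_mass, r1$max_mass)
})

test_that("stronger planted effects never shrink the largest cluster mass", {
  set.seed(13)
  n <- 15
  E <- ncol(the_layout$adjacency)
  noise <- matrix(rnorm(n * E), n, E, dimnames = list(NULL, the_layout$channels))
  w <- rep(0, E)
  pe <- planted_electrodes(erp_template_spec(), the_layout, 1)
  w[match(pe, the_layout$channels)] <- 1
  masses <- vapply(c(0.5, 1, 2, 4), function(es) {
    d <- noise + outer(rep(1, n), w * es)
    permutation_test(d, adjacency = the_layout$adjacency, design = "paired",
                     n_perm = 150, seed = 6)$max_mass
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("independent design recovers group differences and enumerates exactly", {
  set.seed(17)
  E <- 6
  adj <- matrix(TRUE, E, E); diag(adj) <- FALSE
  a <- matrix(rnorm(5 * E), 5, E, dimnames = list(NULL, paste0("e", 1:E)))
  b <- matrix(rnorm(5 * E, mean = 3), 5, E, dimnames = list(NULL, paste0("e", 1:E)))
  d <- rbind(a, b)
  g <- rep(c("left", "right"), each = 5)
  ex <- permutation_test(d, groups = g, adjacency = adj,
                         design = "independent", n_perm = "exact", seed = 1)
  expect_equal(ex$n_permutations, choose(10, 5))
  expect_true(ex$significant)
  expect_lt(ex$electrode_stats$t[1], 0)  # left minus right, left smaller
  mc <- permutation_test(d, groups = g, adjacency = adj,
                         design = "independent", n_perm = 1000, seed = 9)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 1000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2e-3)
})

test_that("too few permutations are refused", {
  d <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("e", 1:4)))
  adj <- matrix(TRUE, 4, 4); diag(adj) <- FALSE
  expect_error(permutation_test(d, adjacency = adj, design = "paired",
                                n_perm = 50),
               class = "vection_validation_error")
})
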