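test_that("spearman matrix reproduces hand cases", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 2, 3, 4))
  sm <- spearman_matrix(m)
  expect_equal(sm$r["a", "a"], 1)
  expect_equal(sm$r["a", "b"], -1)
  expect_equal(sm$r["a", "c"], 1)
  # rank-then-Pearson by hand: d = (0,-1,1,-1,1), sum d^2 = 4,
  # r = 1 - 6*4/(5*24) = 0.8
  m2 <- cbind(x = 1:5, y = c(1, 3, 2, 5, 4))
  expect_equal(spearman_matrix(m2)$r["x", "y"], 0.8)
})

test_that("small-sample p-values match cor.test exactly", {
  set.seed(31)
  for (i in 1:10) {
    m <- cbind(x = rnorm(8), y = rnorm(8))
    sm <- spearman_matrix(m)
    ct <- cor.test(m[, 1], m[, 2], method = "spearman")
    expect_equal(sm$r["x", "y"], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sm$p["x", "y"], ct$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample p-values match the t approximation", {
  set.seed(32)
  n <- 100
  m <- cbind(x = rnorm(n), y = rnorm(n))
  sm <- spearman_matrix(m)
  r <- cor(m[, 1], m[, 2], method = "spearman")
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(sm$p["x", "y"], 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(33)
  m <- cbind(x = rlnorm(40), y = rlnorm(40))
  r0 <- spearman_matrix(m)$r["x", "y"]
  m2 <- cbind(x = log(m[, "x"]), y = m[, "y"]^3)
  expect_equal(spearman_matrix(m2)$r["x", "y"], r0, tolerance = 1e-12)
})

test_that("constant genes are reported as missing, not zero", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  expect_warning(sm <- spearman_matrix(m), "b")
  expect_true(is.na(sm$r["a", "b"]))
  expect_true(is.na(sm$p["a", "b"]))
})

test_that("network edges respect both thresholds", {
  r <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(r) <- 1
  p_all1 <- matrix(1, 3, 3, dimnames = dimnames(r)); diag(p_all1) <- NA
  expect_identical(nrow(build_network(r, p_all1)$edges), 0L)
  p_sig <- matrix(0.01, 3, 3, dimnames = dimnames(r)); diag(p_sig) <- NA
  expect_identical(nrow(build_network(r, p_sig)$edges), 3L)  # K3
  # below edge_min drops out even when significant
  r2 <- r; r2["a", "b"] <- r2["b", "a"] <- 0.1
  expect_identical(nrow(build_network(r2, p_sig, edge_min = 0.2)$edges), 2L)
  expect_error(build_network(r, p_sig, alpha = 1.5), "alpha")
})

test_that("groups are connected components with deterministic labels", {
  genes <- c("a", "b", "c", "d", "e")
  r <- diag(5); dimnames(r) <- list(genes, genes)
  p <- matrix(1, 5, 5, dimnames = dimnames(r))
  # chain a-b, b-c; d,e isolated
  for (pr in list(c("a", "b"), c("b", "c"))) {
    r[pr[1], pr[2]] <- r[pr[2], pr[1]] <- 0.6
    p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- 0.001
  }
  net <- build_network(r, p)
  grp <- identify_groups(net)
  expect_identical(unname(grp[c("a", "b", "c")]), c(1L, 1L, 1L))
  expect_identical(unname(grp["d"]), 2L)  # singleton order follows gene order
  expect_identical(unname(grp["e"]), 3L)
  # empty edge set -> all singletons
  net0 <- build_network(r * 0 + diag(5), p * 0 + 1)
  expect_identical(max(identify_groups(net0)), 5L)
})

test_that("negative edges never join groups", {
  genes <- c("a", "b")
  r <- matrix(c(1, -0.9, -0.9, 1), 2, dimnames = list(genes, genes))
  p <- matrix(c(NA, 1e-5, 1e-5, NA), 2, dimnames = list(genes, genes))
  net <- build_network(r, p)
  expect_identical(nrow(net$edges), 1L)   # edge exists (|r| >= 0.2) ...
  grp <- identify_groups(net)             # ... but is not positive
  expect_identical(max(grp), 2L)
})

test_that("group summary arithmetic is exact", {
  genes <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(genes, genes)
  r["a", "b"] <- r["b", "a"] <- 0.2
  r["a", "c"] <- r["c", "a"] <- 0.4
  r["b", "c"] <- r["c", "b"] <- 0.6
  r["a", "d"] <- r["d", "a"] <- 0.1
  r["b", "d"] <- r["d", "b"] <- 0.1
  r["c", "d"] <- r["d", "c"] <- 0.1
  groups <- setNames(c(1L, 1L, 1L, 2L), genes)
  gs <- group_summary(r, groups)
  g1 <- gs$groups[gs$groups$group == 1, ]
  expect_equal(g1$mean_within, 0.4)              # (0.2+0.4+0.6)/3
  expect_equal(g1$mean_all, mean(c(0.2, 0.4, 0.6, 0.1, 0.1, 0.1)))
  expect_equal(g1$max_any, 0.6)
  g2 <- gs$groups[gs$groups$group == 2, ]
  expect_true(is.na(g2$mean_within))             # singleton
  expect_equal(g2$max_any, 0.1)
  # two genes with r = 0.6 in one group
  gs2 <- group_summary(r[c("b", "c"), c("b", "c")],
                       setNames(c(1L, 1L), c("b", "c")))
  expect_equal(gs2$groups$mean_within, 0.6)
})

test_that("force-directed layout is seeded and edge-contractive", {
  genes <- c("a", "b")
  r <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(genes, genes))
  p <- matrix(c(NA, 1e-9, 1e-9, NA), 2, dimnames = list(genes, genes))
  with_edge <- build_network(r, p)
  no_edge <- build_network(r, matrix(1, 2, 2, dimnames = dimnames(r)))
  xy1 <- layout_fr(with_edge, seed = 7)
  xy2 <- layout_fr(with_edge, seed = 7)
  expect_identical(xy1, xy2)
  d_edge <- sqrt(sum((xy1["a", ] - xy1["b", ])^2))
  d_free <- sqrt(sum((layout_fr(no_edge, seed = 7)["a", ] -
                        layout_fr(no_edge, seed = 7)["b", ])^2))
  expect_lt(d_edge, d_free)
  # single node gets a fixed finite position
  r1 <- matrix(1, 1, 1, dimnames = list("a", "a"))
  p1 <- matrix(NA_real_, 1, 1, dimnames = list("a", "a"))
  xy_one <- layout_fr(build_network(r1, p1), seed = 1)
  expect_true(all(is.finite(xy_one)))
})
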