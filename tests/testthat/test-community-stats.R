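test_that("pcoa reproduces the collinear hand example", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  p <- pcoa(d)
  expect_equal(sum(p$eigenvalues > 1e-10), 1)
  expect_equal(p$eigenvalues[1], 2)
  co <- p$coordinates[, 1]
  if (co[1] < 0) co <- -co                       # defined up to global sign
  expect_equal(unname(co), c(1, 0, -1))
})

test_that("pcoa reconstructs Euclidean distances (classical scaling)", {
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(rnorm(10 * 3), 10)
    d <- as.matrix(dist(x)); rownames(d) <- colnames(d) <- paste0("s", 1:10)
    p <- pcoa(d)
    drec <- as.matrix(dist(p$coordinates))
    expect_lt(max(abs(drec - d)), 1e-9)
  }
})

test_that("pcoa duplicates a duplicated point", {
  x <- c(0, 0, 1, 3)
  p <- pcoa(euclid_dist(x))
  expect_equal(p$coordinates[1, ], p$coordinates[2, ])
})

test_that("permanova matches the exhaustive 4-point worked example", {
  d <- euclid_dist(c(0, 0.5, 1, 1.5))
  md <- data.frame(g = c("A", "A", "B", "B"), row.names = rownames(d))
  out <- permanova_marginal(d, md, ~ g, n_perm = "exhaustive")
  expect_equal(out["Total", "SumOfSqs"], 1.25)
  expect_equal(out["g", "SumOfSqs"], 1.0)
  expect_equal(out["g", "R2"], 0.8)
  expect_equal(out["g", "F"], 8)
  expect_equal(out["g", "Pr(>F)"], 1 / 3)
})

test_that("single-factor permanova equals the pairwise-distance closed form", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(8:16, 1)
    m <- matrix(rpois(n * 6, 12), n)
    rownames(m) <- paste0("s", seq_len(n))
    d <- bray_curtis(hellinger(m))
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(c("A", "B", "C"), n, TRUE)
    md <- data.frame(g = g, row.names = rownames(d))
    out <- permanova_marginal(d, md, ~ g, n_perm = 99, seed = rep)
    oracle <- permanova_oracle(d, g)
    expect_lt(abs(out["Total", "SumOfSqs"] - oracle$ss_total), 1e-9)
    expect_lt(abs(out["g", "SumOfSqs"] - oracle$ss_between), 1e-9)
    expect_lt(abs(out["Residual", "SumOfSqs"] - oracle$ss_within), 1e-9)
    expect_lt(abs(out["g", "F"] - oracle$F), 1e-9)
    # R2 partition sums to one
    expect_equal(out["g", "R2"] + out["Residual", "R2"], 1)
  }
})

test_that("euclidean permanova SS equals linear-model ANOVA SS", {
  set.seed(29)
  x <- rnorm(12)
  g <- factor(rep(c("A", "B", "C"), each = 4))
  d <- euclid_dist(x)
  md <- data.frame(g = g, row.names = rownames(d))
  out <- permanova_marginal(d, md, ~ g, n_perm = 99)
  an <- anova(lm(x ~ g))
  expect_equal(out["g", "SumOfSqs"], an["g", "Sum Sq"])
  expect_equal(out["Residual", "SumOfSqs"], an["Residuals", "Sum Sq"])
  expect_equal(out["g", "F"], an["g", "F value"])
})

test_that("marginal permanova matches vegan adonis2 by margin", {
  skip_if_not_installed("vegan")
  set.seed(42)
  n <- 24
  md <- data.frame(g = sample(c("A", "B", "C"), n, TRUE),
                   s = sample(c("x", "y"), n, TRUE))
  m <- matrix(rpois(n * 10, 20), n); rownames(m) <- paste0("c", 1:n)
  rownames(md) <- rownames(m)
  d <- bray_curtis(hellinger(m))
  mine <- permanova_marginal(d, md, ~ g + s, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g + s, data = md, by = "margin",
                        permutations = 199)
  expect_equal(mine[c("g", "s"), "SumOfSqs"], ref[c("g", "s"), "SumOfSqs"],
               tolerance = 1e-10)
  expect_equal(mine[c("g", "s"), "F"], ref[c("g", "s"), "F"],
               tolerance = 1e-10)
  expect_equal(mine[c("g", "s"), "R2"], ref[c("g", "s"), "R2"],
               tolerance = 1e-10)
  # interaction model
  mine2 <- permanova_marginal(d, md, ~ g * s, n_perm = 199, seed = 1)
  ref2 <- vegan::adonis2(stats::as.dist(d) ~ g * s, data = md, by = "margin",
                         permutations = 199)
  common <- intersect(rownames(mine2), rownames(ref2))
  expect_equal(mine2[common, "SumOfSqs"], ref2[common, "SumOfSqs"],
               tolerance = 1e-10)
})

test_that("identical seeds give identical tables, p honors the lower bound", {
  d <- euclid_dist(rnorm(10))
  md <- data.frame(g = rep(c("A", "B"), 5), row.names = rownames(d))
  a <- permanova_marginal(d, md, ~ g, n_perm = 199, seed = 7)
  b <- permanova_marginal(d, md, ~ g, n_perm = 199, seed = 7)
  expect_identical(a, b)
  expect_gte(a["g", "Pr(>F)"], 1 / 200)
})

test_that("confounded duplicate terms get df 0 and NA F", {
  set.seed(3)
  d <- euclid_dist(rnorm(12))
  md <- data.frame(g = rep(c("A", "B", "C"), 4))
  md$g2 <- md$g
  rownames(md) <- rownames(d)
  out <- permanova_marginal(d, md, ~ g + g2, n_perm = 99)
  expect_equal(out["g2", "Df"], 0)
  expect_true(is.na(out["g2", "F"]))
  expect_true(is.na(out["g2", "Pr(>F)"]))
  expect_error(permanova_marginal(d, data.frame(g = rep("A", 12),
                                                row.names = rownames(d)),
                                  ~ g, n_perm = 99), "single level")
})

test_that("dispersion_test flags planted dispersion differences", {
  # group A: all points identical -> dispersion exactly 0
  x <- c(1, 1, 1, 4, 5, 7)
  g <- c("A", "A", "A", "B", "B", "B")
  res <- dispersion_test(euclid_dist(x), g, n_perm = 199, seed = 1)
  expect_equal(unname(res$group_means["A"]), 0)
  expect_gt(res$group_means["B"], 0)
  # mirrored clouds: dispersions equal by construction -> p not small
  y <- c(0, 1, 2, 10, 11, 12)
  res2 <- dispersion_test(euclid_dist(y), g, n_perm = 199, seed = 2)
  expect_gt(res2$p, 0.05)
  expect_error(dispersion_test(euclid_dist(x), c("A", "B", "C", "A", "B", "C"),
                               n_perm = 99), NA)
})

test_that("colony replicates disperse less than site groups (planted)", {
  w <- sim_world(2, replicate_noise_sd = 0.1)
  tab <- w$com$table
  reps <- table(tab$colony)
  keep <- tab$colony %in% names(reps)[reps == 3]
  t2 <- asv_table(tab$counts[keep, , drop = FALSE], colony = tab$colony[keep])
  h <- hellinger(t2$counts[, colSums(t2$counts) > 0, drop = FALSE])
  d <- bray_curtis(h)
  colony_g <- factor(t2$colony)
  site_g <- w$meta$site[match(rownames(d), w$meta$sample_id)]
  z_col <- dispersion_test(d, colony_g, n_perm = 99, seed = 1)$distances
  z_site <- dispersion_test(d, site_g, n_perm = 99, seed = 1)$distances
  expect_lt(mean(z_col), mean(z_site))
  expect_lt(t.test(z_col, z_site, paired = TRUE,
                   alternative = "less")$p.value, 0.05)
})
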