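test_that("asv_table validates inputs", {
  expect_error(toy_asv(matrix(-1, 1, 1)), "nonnegative")
  expect_error(toy_asv(matrix(1.5, 1, 1)), "nonnegative")
  m <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_error(asv_table(m, colony = c(s1 = "c1")), "without a colony")
})

test_that("aggregate_replicates sums within colonies and conserves reads", {
  t <- toy_asv(rbind(c(3, 0), c(1, 2), c(0, 0), c(5, 5)),
               samples = paste0("s", 1:4),
               colony = c("c1", "c1", "c1", "c2"))
  agg <- aggregate_replicates(t)
  expect_equal(unname(agg$counts["c1", ]), c(4L, 2L))
  expect_equal(unname(agg$counts["c2", ]), c(5L, 5L))
  expect_equal(sum(agg$counts), sum(t$counts))
  # single-sample colonies: identity
  t1 <- toy_asv(rbind(c(1, 2), c(3, 4)), colony = c("c1", "c2"))
  expect_equal(unname(aggregate_replicates(t1)$counts), unname(t1$counts))
})

test_that("group_correlated_asvs merges by presence correlation", {
  # identical presence -> one group; complementary -> separate
  t <- toy_asv(cbind(a = c(5, 3, 0, 0), b = c(1, 9, 0, 0),
                     c = c(0, 0, 2, 7)))
  g <- group_correlated_asvs(t)
  expect_equal(sort(g$groups$group_id[g$groups$asv_id %in% c("a", "b")]),
               c("a", "a"))
  expect_equal(g$groups$group_id[g$groups$asv_id == "c"], "c")
  # grouped counts are member sums, group id is smallest member
  expect_equal(unname(g$table$counts[, "a"]), c(6L, 12L, 0L, 0L))
})

test_that("grouping is transitive through chains of high correlation", {
  # phi(x,y) = 0.816, phi(y,z) = 0.802, phi(x,z) = 0.655 (hand-derived)
  x <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  z <- c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0)
  expect_gt(cor(x, y), 0.8); expect_gt(cor(y, z), 0.8)
  expect_lte(cor(x, z), 0.8)
  t <- toy_asv(cbind(x, y, z), asvs = c("x", "y", "z"))
  g <- group_correlated_asvs(t)
  expect_equal(length(g$members), 1L)
  expect_setequal(g$members[[1]], c("x", "y", "z"))
})

test_that("constant-presence ASVs group only with identical vectors", {
  t <- toy_asv(cbind(all1 = c(1, 2, 3), all1b = c(9, 9, 9),
                     none = c(0, 0, 0), noneb = c(0, 0, 0),
                     mixed = c(1, 0, 1)))
  g <- group_correlated_asvs(t)
  gid <- setNames(g$groups$group_id, g$groups$asv_id)
  expect_equal(unname(gid["all1"]), unname(gid["all1b"]))
  expect_equal(unname(gid["none"]), unname(gid["noneb"]))
  expect_false(gid["all1"] == gid["none"])
  expect_false(gid["mixed"] %in% gid[c("all1", "none")])
})

test_that("filter_asvs honors inclusive prevalence and strict reads", {
  cfg <- filter_config()
  t <- toy_asv(rbind(c(5000, 40, 50, 200),
                     c(5000, 30, 51, 0),
                     c(0,    30, 0,  0),
                     c(0,    1,  0,  0)),
               asvs = c("two_col", "four_col", "low_reads", "one_col"))
  # two_col: 2 colonies < 3 -> dropped despite 10^4 reads
  # four_col: 4 colonies, 101 reads (> 100) -> kept
  # low_reads: 2 colonies and 101... recheck: 50+51 = 101 but 2 colonies -> dropped
  # one_col: dropped
  kept <- colnames(filter_asvs(t, cfg)$counts)
  expect_equal(kept, "four_col")
  # exactly 100 reads in 5 colonies -> dropped (strict > 100)
  t2 <- toy_asv(matrix(20L, 5, 1), asvs = "boundary")
  expect_equal(ncol(filter_asvs(t2, cfg)$counts), 0L)
  # 3 colonies and 101 reads -> kept at the inclusive-3 default
  t3 <- toy_asv(matrix(c(50L, 50L, 1L), 3, 1), asvs = "keepme")
  expect_equal(colnames(filter_asvs(t3, cfg)$counts), "keepme")
})

test_that("filter_colonies applies strict boundaries", {
  cfg <- filter_config()
  t <- toy_asv(rbind(exact1000 = c(250, 250, 250, 250, 0),
                     keep = c(300, 300, 300, 100, 1),
                     few_asvs = c(1500, 1, 1, 0, 0)),
               samples = c("exact1000", "keep", "few_asvs"))
  out <- filter_colonies(t, cfg)
  expect_equal(rownames(out$counts), "keep")   # 1001 reads, 5 nonzero ASVs
  expect_error(filter_colonies(toy_asv(matrix(1L, 1, 1)), cfg),
               "review")
})

test_that("the two filters compose as documented on a toy table", {
  # 5 colonies x 6 ASVs; hand-run: ASVs then colonies, once each
  m <- rbind(c1 = c(600, 500, 40, 2000, 0, 9),
             c2 = c(600, 500, 40, 0,    0, 9),
             c3 = c(600, 500, 40, 0,    0, 9),
             c4 = c(300, 200, 0,  0,    5, 9),
             c5 = c(0,   0,   0,  0,    5, 0))
  colnames(m) <- paste0("A", 1:6)
  t <- toy_asv(m, samples = rownames(m))
  # filter_asvs: A1 (4 col, 2100 reads) keep; A2 (4 col, 1700) keep;
  # A3 (3 col, 120) keep; A4 (1 col) drop; A5 (2 col, 10) drop;
  # A6 (4 col, 36 reads <= 100) drop
  fa <- filter_asvs(t, filter_config())
  expect_equal(colnames(fa$counts), c("A1", "A2", "A3"))
  # filter_colonies on the remainder: read sums c1 = c2 = c3 = 1140 (keep),
  # c4 = 500 and c5 = 0 (drop); richness threshold relaxed to 2 because the
  # surviving toy table has only 3 ASVs
  fc <- filter_colonies(fa, filter_config(min_nonzero_asvs_per_colony = 2))
  expect_equal(rownames(fc$counts), c("c1", "c2", "c3"))
})

test_that("raising any threshold never increases the retained table", {
  set.seed(41)
  m <- matrix(rpois(20 * 15, 30), 20, 15)
  t <- toy_asv(m)
  dims <- sapply(c(0, 50, 200, 400), function(th) {
    f <- filter_asvs(t, filter_config(min_reads_per_asv = th))
    ncol(f$counts)
  })
  expect_true(all(diff(dims) <= 0))
  dims2 <- sapply(c(1, 3, 5, 10), function(th) {
    f <- filter_asvs(t, filter_config(min_colonies_per_asv = th))
    ncol(f$counts)
  })
  expect_true(all(diff(dims2) <= 0))
  dims3 <- sapply(c(0, 300, 450, 600), function(th) {
    tryCatch(
      nrow(filter_colonies(t, filter_config(min_reads_per_colony = th))$counts),
      error = function(e) 0L)  # "all colonies removed" counts as size 0
  })
  expect_true(all(diff(dims3) <= 0))
})

test_that("hellinger gives root proportions with unit sum of squares", {
  t <- toy_asv(rbind(c(1, 1, 2), c(5, 0, 0)))
  h <- hellinger(t)
  expect_equal(unname(h[1, ]), c(0.5, 0.5, sqrt(0.5)))
  expect_equal(unname(h[2, ]), c(1, 0, 0))
  expect_equal(unname(rowSums(h^2)), c(1, 1))
  expect_error(hellinger(rbind(c(0, 0))), "zero-sum")
})

test_that("bray_curtis matches the formula and a brute-force double loop", {
  m <- rbind(a = c(2, 0), b = c(0, 2), c = c(2, 0), d = c(1, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 0)
  expect_equal(bray_curtis(rbind(x = c(1, 1), y = c(1, 3)))["x", "y"], 2 / 6)
  set.seed(7)
  r <- matrix(runif(8 * 5), 8); rownames(r) <- paste0("s", 1:8)
  bd <- bray_curtis(r)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) if (i != j)
    brute[i, j] <- sum(abs(r[i, ] - r[j, ])) / sum(r[i, ] + r[j, ])
  expect_lt(max(abs(bd - brute)), 1e-12)
})

test_that("join_with_genotyped restricts to the intersection", {
  t <- toy_asv(rbind(c(1, 2), c(3, 4), c(5, 6)),
               samples = c("c1", "c2", "c3"))
  expect_error(join_with_genotyped(t, c("x", "y")), "no overlap")
  out <- suppressMessages(join_with_genotyped(t, c("c1", "c3", "zz")))
  expect_equal(rownames(out$counts), c("c1", "c3"))
  # idempotence
  out2 <- suppressMessages(join_with_genotyped(out, c("c1", "c3", "zz")))
  expect_identical(out$counts, out2$counts)
})

test_that("grouping before vs after aggregation keeps variant sets intact", {
  w <- sim_world(33, n_individuals = 15, n_snps = 100, n_asvs = 30)
  t <- w$com$table
  vs <- w$com$truth$variant_sets
  g_before <- group_correlated_asvs(t)
  g_after <- group_correlated_asvs(aggregate_replicates(t))
  for (set in vs) {
    gid1 <- unique(g_before$groups$group_id[g_before$groups$asv_id %in% set])
    gid2 <- unique(g_after$groups$group_id[g_after$groups$asv_id %in% set])
    expect_length(gid1, 1)
    expect_length(gid2, 1)
  }
})

test_that("hellinger and bray_curtis agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(10)
  m <- matrix(rpois(12 * 9, 15), 12, 9)
  rownames(m) <- paste0("s", 1:12); colnames(m) <- paste0("A", 1:9)
  h <- hellinger(m)
  expect_equal(h, as.matrix(vegan::decostand(m, "hellinger")),
               ignore_attr = TRUE)
  expect_equal(bray_curtis(h), as.matrix(vegan::vegdist(h, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("asv tables round-trip through TSV", {
  t <- toy_asv(rbind(c(1, 2), c(3, 4)), colony = c("c1", "c1"))
  f <- tempfile(fileext = ".tsv")
  write_asv_tsv(t, f)
  meta <- data.frame(sample_id = c("s1", "s2"), colony_id = c("c1", "c1"))
  t2 <- read_asv_tsv(f, meta = meta)
  expect_equal(t$counts, t2$counts)
  expect_equal(unname(t$colony), unname(t2$colony))
})
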