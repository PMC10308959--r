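test_that("per-Gbp normalization is elementwise division", {
  expect_equal(ks_per_gbp(c(PUFA = 10), 2), c(PUFA = 5))
  expect_equal(ks_per_gbp(numeric(3), 1.7), numeric(3))
  set.seed(14)
  counts <- rpois(11, 20); size <- runif(1, 0.5, 4)
  expect_equal(ks_per_gbp(counts, size), counts / size)
  expect_error(ks_per_gbp(counts, 0), "positive")
})

test_that("rarefied composition is exact at depth = n, seeded, and hypergeometric in the mean", {
  leaves <- ks_leaf_vocabulary()
  calls <- data.frame(
    metagenome_id = rep("m1", 30),
    leaf_label = rep(c("PUFA", "enediyne", "trans-AT"), each = 10))
  # depth equal to the call count reproduces the empirical counts exactly
  m <- rarefied_composition(calls, depth = 30, permutations = 5, seed = 1)
  expect_equal(unname(m["m1", c("PUFA", "enediyne", "trans-AT")]), c(10, 10, 10))
  expect_equal(sum(m), 30)
  # determinism under a fixed seed
  calls2 <- data.frame(metagenome_id = "m2",
                       leaf_label = sample(c("PUFA", "FAS"), 200, TRUE, c(.5, .5)))
  m1 <- rarefied_composition(calls2, depth = 50, permutations = 200, seed = 9)
  m2 <- rarefied_composition(calls2, depth = 50, permutations = 200, seed = 9)
  expect_identical(m1, m2)
  expect_equal(unname(rowSums(m1)), 50)
  # 50/50 pool of 1000, depth 100: each type's mean within 4 sigma of 50
  calls3 <- data.frame(metagenome_id = "m3",
                       leaf_label = rep(c("PUFA", "FAS"), each = 500))
  m3 <- rarefied_composition(calls3, depth = 100, permutations = 1000, seed = 4)
  sigma <- sqrt(100 * .5 * .5 * (900 / 999)) / sqrt(1000)  # hypergeometric SE of the mean
  expect_lt(abs(m3["m3", "PUFA"] - 50), 4 * sigma)
  # undersized metagenomes are excluded with a warning
  calls4 <- rbind(calls3, data.frame(metagenome_id = "tiny", leaf_label = "PUFA"))
  expect_warning(m4 <- rarefied_composition(calls4, depth = 100,
                                            permutations = 10, seed = 2),
                 "excluding")
  expect_identical(attr(m4, "excluded"), "tiny")
})

test_that("Bray-Curtis follows the formula with its metric properties", {
  m <- rbind(a = c(2, 1), b = c(1, 3), c = c(2, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 3 / 7)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(bray_curtis(rbind(x = c(1, 0), y = c(0, 1)))["x", "y"], 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
  # random matrices: equality with the direct formula
  set.seed(21)
  r <- matrix(rexp(40), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  d2 <- bray_curtis(r)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(d2[i, j], sum(abs(r[i, ] - r[j, ])) / sum(r[i, ] + r[j, ]))
  }
})

test_that("PCoA recovers a planar configuration (Procrustes residual < 1e-8)", {
  set.seed(33)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))   # descending
  expect_lte(sum(fit$proportion_explained), 1 + 1e-9)
  pro <- vegan::procrustes(pts, fit$coordinates[, 1:2], symmetric = FALSE)
  expect_lt(max(abs(stats::residuals(pro))), 1e-8)
  # Euclidean-derived distances give no meaningfully negative eigenvalues
  expect_gte(min(fit$eigenvalues), -1e-9 * max(fit$eigenvalues))
  # 2-point matrix with d = 2 puts the points at +/-1 on axis 1
  two <- pcoa(matrix(c(0, 2, 2, 0), 2, dimnames = list(c("p", "q"), c("p", "q"))))
  expect_equal(unname(sort(two$coordinates[, 1])), c(-1, 1))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA matches the exhaustive-permutation oracle on a hand example", {
  set.seed(61)
  pts <- rbind(matrix(rnorm(6, 0), 3), matrix(rnorm(6, 2), 3))
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(dist(pts))
  labels <- rep(c("g1", "g2"), each = 3)
  fit <- permanova(d, labels, permutations = 999, seed = 5)
  expect_equal(fit$pseudo_F, oracle_pseudo_F(d, labels))
  # exhaustive reference: pseudo-F over all 720 label orderings
  all_perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  Fs <- vapply(all_perm(1:6), function(p) oracle_pseudo_F(d, labels[p]), numeric(1))
  exact_p <- mean(Fs >= fit$pseudo_F - 1e-12)
  # permutation p-value should approximate the exhaustive one
  expect_lt(abs(fit$p_value - exact_p), 0.05)
})

test_that("PERMANOVA gives R2 = 1 on duplicated points and validates groups", {
  pts <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(dist(pts))
  fit <- suppressWarnings(permanova(d, rep(c("a", "b"), each = 3),
                                    permutations = 99, seed = 1))
  expect_equal(fit$R2, 1.0)
  expect_error(permanova(d, c("a", "a", "a", "a", "a", "b")), "fewer than 2")
  expect_error(permanova(d, rep("a", 6)), "two groups")
})

test_that("ANOVA + Tukey HSD matches a hand-computed fixture", {
  # three groups of four; classic textbook layout
  vals <- c(6, 8, 4, 5, 3, 4, 1, 2, 8, 12, 9, 11)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  fit <- anova_tukey(vals, grp, alpha = 0.01)
  # hand calculation: SSW = 8.75 + 5 + 10 = 23.75, SSB = 679/6
  expect_equal(fit$F, (679 / 6 / 2) / (23.75 / 9), tolerance = 1e-10)
  expect_identical(nrow(fit$pairs), 3L)
  # two groups only: Tukey p equals the pooled two-sample comparison (q = |t| sqrt 2)
  v2 <- c(vals[1:8]); g2 <- grp[1:8]
  fit2 <- anova_tukey(v2, g2)
  tt <- stats::t.test(v2 ~ g2, var.equal = TRUE)
  q <- abs(tt$statistic) * sqrt(2)
  p_from_q <- 1 - stats::ptukey(q, nmeans = 2, df = 6)
  expect_equal(fit2$pairs$p_adj, unname(p_from_q), tolerance = 1e-8)
  # degenerate variance errors out
  expect_error(anova_tukey(rep(1, 6), rep(c("a", "b"), 3)), "degenerate")
  # equal group means with iid jitter: nothing flagged at alpha 0.01
  set.seed(3)
  fit3 <- anova_tukey(5 + rnorm(12, 0, 0.01), rep(c("a", "b", "c"), 4))
  expect_false(any(fit3$pairs$flagged))
})

test_that("distinct synthetic biome profiles separate in composition space", {
  db <- ref22
  pufa_heavy <- biome_profile("marine", c(PUFA = 0.8, enediyne = 0.2),
                              identity_target = 0.9)
  cis_heavy <- biome_profile("soil", c(`modular cis-AT` = 0.8,
                                       `hybrid cis-AT` = 0.2),
                             identity_target = 0.9)
  set.seed(17)
  calls <- list()
  for (b in 1:4) {
    for (pf in list(pufa_heavy, cis_heavy)) {
      g <- generate_biome(pf, 40, db, id_prefix = sprintf("%s%d", pf$biome, b))
      # truth labels stand in for classification here: this test isolates
      # the composition statistics from the aligner
      calls[[length(calls) + 1L]] <- data.frame(
        metagenome_id = sprintf("%s%d", pf$biome, b),
        biome = pf$biome, leaf_label = g$truth$leaf_label)
    }
  }
  calls <- do.call(rbind, calls)
  m <- rarefied_composition(calls, depth = 40, permutations = 50, seed = 2)
  d <- bray_curtis(m)
  labels <- sub("[0-9]+$", "", rownames(m))
  fit <- permanova(d, labels, permutations = 999, seed = 11)
  expect_lte(fit$p_value, 0.05)
  expect_gt(fit$R2, 0.5)
})
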