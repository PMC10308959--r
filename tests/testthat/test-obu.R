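test_that("chao1 matches the bias-corrected closed form and vegan", {
  expect_equal(chao1(c(3, 4, 5)), 3.0)
  expect_equal(chao1(c(1, 1, 1, 1, 1, 2, 2, 3, 3, 3)), 10 + 5 * 4 / (2 * 3))
  expect_equal(chao1(1), 1.0)
  expect_error(chao1(numeric(0)), "at least one")
  set.seed(88)
  for (k in 1:10) {
    sizes <- sample(1:6, sample(3:20, 1), replace = TRUE)
    # cross-check against vegan's bias-corrected Chao1 on the abundance vector
    est <- vegan::estimateR(sizes)
    expect_equal(chao1(sizes), unname(est["S.chao1"]))
    expect_gte(chao1(sizes), length(sizes))  # chao1 >= observed richness
  }
})

test_that("greedy clustering honors thresholds on simple constructed cases", {
  s <- rnd_protein(100)
  same <- stats::setNames(rep(s, 4), paste0("a", 1:4))
  for (th in c(0.7, 0.9, 1.0)) {
    tab <- cluster_obus(same, th)
    expect_identical(length(tab$sizes), 1L)
    expect_identical(unname(tab$sizes), 4L)
  }
  # two sequences at 85% identity: together at 0.80, apart at 0.90
  set.seed(55)
  a <- rnd_protein(200)
  b <- mutate_to_identity(a, 0.85, preserve_anchors = FALSE)$sequence
  pair <- c(s1 = a, s2 = b)
  expect_identical(length(cluster_obus(pair, 0.80)$sizes), 1L)
  expect_identical(length(cluster_obus(pair, 0.90)$sizes), 2L)
})

test_that("clustering partitions the input and members reach their centroid", {
  db <- ref22
  set.seed(66)
  seqs <- vapply(sample(nrow(db), 30, replace = TRUE), function(j) {
    mutate_to_identity(db$residues[j], 0.9)$sequence
  }, character(1))
  names(seqs) <- sprintf("m%02d", 1:30)
  tab <- cluster_obus(seqs, 0.8)
  expect_setequal(tab$members$id, names(seqs))          # partition
  expect_identical(sum(tab$sizes), 30L)
  expect_true(all(tab$members$centroid_id %in% tab$members$id))
  for (k in seq_len(nrow(tab$members))) {               # re-align check
    expect_gte(global_identity(seqs[[tab$members$id[k]]],
                               seqs[[tab$members$centroid_id[k]]]), 0.8)
  }
})

test_that("clustering equals the uncached all-pairs greedy oracle", {
  db <- ref22
  set.seed(99)
  seqs <- vapply(sample(nrow(db), 25, replace = TRUE), function(j) {
    mutate_to_identity(db$residues[j], sample(c(0.8, 0.9), 1))$sequence
  }, character(1))
  names(seqs) <- sprintf("s%02d", 1:25)
  for (th in c(0.70, 0.90)) {
    got <- cluster_obus(seqs, th)
    want <- oracle_greedy_cluster(seqs, th, identity_fun = global_identity)
    expect_identical(stats::setNames(got$members$centroid_id, got$members$id),
                     want)
  }
  # the cached-identity path gives the same result
  idm <- identity_matrix(seqs)
  got2 <- cluster_obus(seqs, 0.90, identities = idm)
  expect_identical(cluster_obus(seqs, 0.90)$members, got2$members)
})

test_that("rarefaction is a seeded uniform subsample", {
  seqs <- stats::setNames(rep("MKWVTFISLL", 50), paste0("x", 1:50))
  expect_identical(rarefy_sequences(seqs, 50, seed = 1), seqs)  # depth = n
  r1 <- rarefy_sequences(seqs, 20, seed = 42)
  r2 <- rarefy_sequences(seqs, 20, seed = 42)
  expect_identical(r1, r2)                                       # determinism
  expect_error(rarefy_sequences(seqs, 51), "lower the depth")
  # inclusion frequency approximates depth/n over repeated draws
  counts <- numeric(50)
  for (s in 1:400) {
    counts[match(names(rarefy_sequences(seqs, 20, seed = s)), names(seqs))] <-
      counts[match(names(rarefy_sequences(seqs, 20, seed = s)), names(seqs))] + 1
  }
  p <- 20 / 50
  sigma <- sqrt(400 * p * (1 - p))
  expect_true(all(abs(counts - 400 * p) <= 4 * sigma))
})

test_that("richness estimates behave on degenerate and structured biomes", {
  # a biome of identical sequences has chao1 = 1 with sd 0 at any threshold
  one <- data.frame(id = paste0("i", 1:15), residues = rnd_protein(150),
                    biome = "flat")
  suppressWarnings({
    r <- richness_by_biome(one, thresholds = c(0.7, 0.95), depth = 10,
                           replicates = 3, seed = 1)
  })
  expect_true(all(r$chao1_mean == 1))
  expect_true(all(r$chao1_sd == 0))
  # a biome drawn from 8 lineages outranks one drawn from 2 (seeded)
  db <- ref44
  set.seed(123)
  rich_pool <- which(db$leaf_label %in% c("PUFA", "enediyne"))        # 8 seeds
  poor_pool <- which(db$leaf_label == "PUFA")[1:2]                     # 2 seeds
  mk <- function(pool, biome, n) {
    idx <- sample(pool, n, replace = TRUE)
    data.frame(id = sprintf("%s%03d", biome, 1:n),
               residues = vapply(idx, function(j) {
                 mutate_to_identity(db$residues[j], 0.95)$sequence
               }, character(1)), biome = biome)
  }
  fl <- rbind(mk(rich_pool, "rich", 30), mk(poor_pool, "poor", 30))
  r <- richness_by_biome(fl, thresholds = 0.90, depth = 30, replicates = 5,
                         seed = 7)
  expect_gt(r$chao1_mean[r$biome == "rich"], r$chao1_mean[r$biome == "poor"])
})

test_that("replicates = 1 gives sd 0 and depth auto-lowers with a warning", {
  fl <- data.frame(id = paste0("i", 1:12),
                   residues = replicate(12, rnd_protein(120)),
                   biome = rep(c("a", "b"), each = 6))
  expect_warning(
    r <- richness_by_biome(fl, thresholds = 0.9, depth = 580, replicates = 1,
                           seed = 2),
    "lowered")
  expect_true(all(r$chao1_sd == 0))
  expect_true(all(r$depth == 6))
})

test_that("shared-OBU counts match exhaustive enumeration on a hand-built fixture", {
  set.seed(321)
  base1 <- rnd_protein(120); base2 <- rnd_protein(120); base3 <- rnd_protein(120)
  near <- function(s) mutate_to_identity(s, 0.95, preserve_anchors = FALSE)$sequence
  # three biomes x three sequences; lineage 1 present in A and B, lineage 2
  # in B and C, lineage 3 private to each biome's tail
  fl <- data.frame(
    id = sprintf("q%02d", 1:9),
    residues = c(base1, near(base1), rnd_protein(120),
                 base1, base2, rnd_protein(120),
                 base2, near(base2), rnd_protein(120)),
    biome = rep(c("A", "B", "C"), each = 3))
  sh <- shared_obus(fl, thresholds = 0.9, depth = 3, seed = 1)
  # exhaustive oracle on the same pooled clustering
  seqs <- stats::setNames(fl$residues, fl$id)
  assign <- oracle_greedy_cluster(seqs, 0.9, identity_fun = global_identity)
  biome_of <- stats::setNames(fl$biome, fl$id)
  for (k in seq_len(nrow(sh))) {
    pair <- c(sh$biome_a[k], sh$biome_b[k])
    by_cl <- split(names(assign), assign)
    is_shared <- vapply(by_cl, function(ids) {
      all(pair %in% biome_of[ids])
    }, logical(1))
    expect_identical(sh$shared_obu_count[k], sum(is_shared))
    expect_identical(sh$shared_domain_count[k],
                     sum(vapply(by_cl[is_shared], function(ids) {
                       sum(biome_of[ids] %in% pair)
                     }, integer(1))))
  }
  # symmetry + the >= 2x invariant
  expect_true(all(sh$shared_domain_count >= 2 * sh$shared_obu_count |
                    sh$shared_obu_count == 0))
})

test_that("identical biome sequence sets share every OBU", {
  set.seed(44)
  seqs <- replicate(5, rnd_protein(100))
  fl <- data.frame(id = sprintf("d%02d", 1:10), residues = rep(seqs, 2),
                   biome = rep(c("A", "B"), each = 5))
  sh <- shared_obus(fl, thresholds = 1.0, depth = 5, seed = 3)
  expect_identical(sh$shared_obu_count, 5L)
  expect_identical(sh$shared_domain_count, 10L)  # 2 x depth
})
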