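test_that("leaf-to-group mapping is total, deterministic and matches the scheme", {
  expect_identical(map_leaf("iterative PTM"),
                   list(group_label = "iterative cis-AT", ssn_group = "cis-AT/iterative"))
  expect_identical(map_leaf("PUFA"),
                   list(group_label = "iterative cis-AT", ssn_group = "PUFA"))
  expect_identical(map_leaf("FAS"), list(group_label = "FAS", ssn_group = "FAS"))
  expect_identical(map_leaf("hybrid trans-AT")$ssn_group, "trans-AT")
  expect_identical(map_leaf("hybrid cis-AT")$ssn_group, "hybrid cis-AT")
  cis_it <- c("modular cis-AT", "cis-loading module", "olefin synthase",
              "iterative aromatic", "iterative PTM")
  for (l in cis_it) expect_identical(map_leaf(l)$ssn_group, "cis-AT/iterative")
  for (l in ks_leaf_vocabulary()) expect_no_error(map_leaf(l))
  expect_error(map_leaf("modular"), "unknown")
})

test_that("an exact reference copy yields one perfect call; fragments below the floor do not", {
  db <- ref22
  i_ene <- which(db$leaf_label == "enediyne")[1]
  peps <- c(exact = db$residues[i_ene], frag = substr(db$residues[i_ene], 1, 150))
  calls <- classify_domains(peps, db)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$query_id, "exact")
  expect_identical(calls$leaf_label, "enediyne")
  expect_equal(calls$identity_fraction, 1.0)
  expect_lte(calls$evalue, 1e-30)
  # the 150-aa fragment is recovered once the match-length floor drops
  calls2 <- classify_domains(peps, db, min_match_aa = 100)
  expect_identical(sort(calls2$query_id), c("exact", "frag"))
})

test_that("thresholds act as a maximum E-value and minimum match length (monotonicity)", {
  db <- ref22
  set.seed(11)
  peps <- vapply(c(1, 5, 9), function(j) {
    mutate_to_identity(db$residues[j], 0.8)$sequence
  }, character(1))
  names(peps) <- paste0("q", 1:3)
  strict <- classify_domains(peps, db, min_match_aa = 200, max_evalue = 1e-60)
  loose <- classify_domains(peps, db, min_match_aa = 150, max_evalue = 1e-20)
  # relaxing both thresholds never removes a call
  expect_true(all(paste(strict$query_id, strict$q_start) %in%
                    paste(loose$query_id, loose$q_start)))
  # an impossible E-value ceiling removes everything
  none <- classify_domains(peps, db, max_evalue = 1e-300)
  expect_identical(nrow(none), 0L)
  expect_error(classify_domains(peps, ref22[0, ]), "non-empty")
})

test_that("top hits equal the naive dynamic-programming oracle on a small search", {
  db <- ref22[1:12, ]
  class(db) <- c("ks_refdb", "data.frame")
  set.seed(23)
  peps <- vapply(sample(12, 6), function(j) {
    mutate_to_identity(db$residues[j], 0.85)$sequence
  }, character(1))
  names(peps) <- paste0("q", 1:6)
  calls <- classify_domains(peps, db, min_match_aa = 100, max_evalue = 1)
  for (i in seq_along(peps)) {
    oracle_scores <- vapply(db$residues, function(r) {
      naive_align_score(peps[[i]], r, blosum62, 11, 1, "local")
    }, numeric(1))
    best <- db$id[order(-oracle_scores, db$id)[1]]
    expect_identical(calls$top_ref_id[calls$query_id == names(peps)[i]][1], best)
  }
})

test_that("classification is deterministic and recovers seed leaves at 80% identity", {
  db <- ref22
  set.seed(77)
  idx <- sample(nrow(db), 60, replace = TRUE)
  peps <- vapply(idx, function(j) mutate_to_identity(db$residues[j], 0.8)$sequence,
                 character(1))
  names(peps) <- sprintf("v%02d", seq_along(peps))
  c1 <- classify_domains(peps, db)
  c2 <- classify_domains(peps, db)
  expect_identical(c1, c2)
  hit <- match(names(peps), c1$query_id)
  recovery <- mean(!is.na(hit) & c1$leaf_label[hit] == db$leaf_label[idx])
  expect_gte(recovery, 0.95)
})

test_that("two tandem domains on one peptide give two non-overlapping calls", {
  db <- ref22
  pep <- c(tandem = paste0(db$residues[1], strrep("G", 30), db$residues[9]))
  calls <- classify_domains(pep, db)
  expect_identical(nrow(calls), 2L)
  iv <- calls[order(calls$q_start), c("q_start", "q_end")]
  ov <- min(iv$q_end) - max(iv$q_start) + 1
  shorter <- min(iv$q_end - iv$q_start + 1)
  expect_lt(max(ov, 0) / shorter, 0.5)  # below the 50% overlap rule
  expect_setequal(calls$leaf_label, db$leaf_label[c(1, 9)])
})

test_that("phylum assignment returns the closest labeled match with a tentative flag", {
  db <- ref22
  peps <- c(p1 = db$residues[3])
  calls <- classify_domains(peps, db)
  calls <- assign_phylum(calls, db)
  expect_identical(calls$phylum_call, db$phylum[3])
  expect_equal(calls$phylum_identity, 1.0)
  expect_false(calls$phylum_tentative)
  # a distant variant is flagged tentative (identity < 0.75)
  set.seed(5)
  far <- mutate_to_identity(db$residues[3], 0.6)$sequence
  calls2 <- assign_phylum(classify_domains(c(p2 = far), db, min_match_aa = 100,
                                           max_evalue = 1), db)
  if (nrow(calls2)) expect_true(all(calls2$phylum_tentative))
})

test_that("exact reference ties resolve to the lexicographically first id", {
  base <- ref22$residues[1]
  db <- ks_refdb(id = c("RB", "RA"), residues = c(base, base),
                 leaf_label = c("PUFA", "PUFA"),
                 phylum = c("Cyanobacteria", "Actinobacteria"))
  calls <- classify_domains(c(q = base), db)
  expect_identical(calls$top_ref_id, "RA")
  calls <- assign_phylum(calls, db)
  expect_identical(calls$phylum_ref_id, "RA")
  expect_identical(calls$phylum_call, "Actinobacteria")
})

test_that("precomputed tabular hits substitute for the built-in aligner", {
  db <- ref22
  f <- tempfile()
  writeLines(paste("q1", db$id[1], "95.0", "210", "10", "0", "1", "210", "1",
                   "210", "1e-80", "500", sep = "\t"), f)
  hits <- read_tabular_hits(f)
  calls <- classify_domains(c(q1 = db$residues[1]), db, hits = hits)
  expect_identical(calls$leaf_label, db$leaf_label[1])
  expect_identical(calls$evalue, 1e-80)  # printed E-value trusted verbatim
  # failing the match-length floor drops the call
  calls2 <- classify_domains(c(q1 = db$residues[1]), db, hits = hits,
                             min_match_aa = 300)
  expect_identical(nrow(calls2), 0L)
})
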