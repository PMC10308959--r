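# Independent oracles used to check the package's computational paths.
# These share no code with the implementation: the aligner is a plain
# Gotoh dynamic program, the translator a table lookup, the clusterer an
# uncached all-pairs greedy pass.

# Affine-gap alignment score by direct dynamic programming. Gap of length
# L costs gap_open + L * gap_extend (first gap residue pays both).
naive_align_score <- function(a, b, mat, gap_open = 11, gap_extend = 1,
                              type = c("local", "global")) {
  type <- match.arg(type)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  open <- gap_open + gap_extend
  NEG <- -1e9
  local <- type == "local"
  prevH <- if (local) numeric(m + 1) else c(0, -(gap_open + gap_extend * seq_len(m)))
  prevF <- rep(NEG, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    Frow <- pmax(prevH - open, prevF - gap_extend)
    diag_sc <- prevH[seq_len(m)] + mat[av[i], bv]
    currH <- numeric(m + 1)
    currH[1] <- if (local) 0 else -(gap_open + gap_extend * i)
    E <- NEG
    for (j in seq_len(m)) {
      E <- max(currH[j] - open, E - gap_extend)
      h <- max(diag_sc[j], Frow[j + 1], E)
      if (local) h <- max(h, 0)
      currH[j + 1] <- h
    }
    if (local) best <- max(best, max(currH))
    prevH <- currH
    prevF <- Frow
  }
  if (local) best else prevH[m + 1]
}

# per-frame translation by direct genetic-code lookup (no Biostrings)
STD_CODE <- Biostrings::GENETIC_CODE  # used as a plain named vector table
naive_translate_frame <- function(nt, frame) {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  revcomp <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  s <- if (frame > 0) nt else revcomp(nt)
  f <- abs(frame)
  s <- substr(s, f, nchar(s))
  n_cod <- nchar(s) %/% 3
  if (n_cod == 0) return("")
  cods <- substring(s, 3 * (seq_len(n_cod) - 1) + 1, 3 * seq_len(n_cod))
  aa <- vapply(cods, function(cd) {
    if (grepl("[^ACGT]", cd)) {
      expand <- function(ch) switch(ch, A = "A", C = "C", G = "G", T = "T",
                                    R = c("A", "G"), Y = c("C", "T"),
                                    S = c("C", "G"), W = c("A", "T"),
                                    K = c("G", "T"), M = c("A", "C"),
                                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                                    N = c("A", "C", "G", "T"))
      b <- strsplit(cd, "")[[1]]
      combos <- as.vector(outer(outer(expand(b[1]), expand(b[2]), paste0),
                                expand(b[3]), paste0))
      u <- unique(unname(STD_CODE[combos]))
      if (length(u) == 1) u else "X"
    } else {
      unname(STD_CODE[cd])
    }
  }, character(1))
  paste(aa, collapse = "")
}

# uncached all-pairs greedy centroid clusterer: same contract as
# cluster_obus (visit by decreasing length then id; join first centroid in
# founding order at >= threshold) but every identity is an individual
# pairwise global alignment call
oracle_greedy_cluster <- function(seqs, threshold, identity_fun) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroids <- character(0)
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (cid in centroids) {
      if (identity_fun(seqs[[i]], seqs[[cid]]) >= threshold) {
        assign[i] <- cid; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, names(seqs)[i])
      assign[i] <- names(seqs)[i]
    }
  }
  stats::setNames(assign, names(seqs))
}

# PERMANOVA pseudo-F from the sums-of-squared-distance definition
oracle_pseudo_F <- function(d, labels) {
  d <- as.matrix(d)
  N <- nrow(d)
  g <- length(unique(labels))
  ss_total <- sum(d[upper.tri(d)]^2) / N
  ss_within <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (N - g))
}

# random protein helper
rnd_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})
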