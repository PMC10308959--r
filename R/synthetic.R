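# background amino acid frequencies (approximate database-wide values)
.AA_FREQ <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
              H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
              P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
              W = 1.08, Y = 2.92)

.random_protein <- function(n) {
  paste(sample(names(.AA_FREQ), n, replace = TRUE, prob = .AA_FREQ), collapse = "")
}

#' Generate the synthetic labeled KS reference collection
#'
#' Builds a reference collection with known structure: one well-separated
#' ancestral domain per leaf class (unrelated random sequences, so
#' between-class identity sits at background level) and `n_per_leaf`
#' reference entries per class derived from the ancestor at
#' `within_identity` global identity. Every entry is a full-length domain:
#' it begins with IAIVG and ends with GTNAH, which are preserved exactly
#' during mutation. Each ancestor also carries controlled primer-site
#' residue composition: a forward-primer site at domain positions 61-68
#' and a reverse-primer site at 355-362, with group-dependent residues
#' (cis-AT/iterative classes match the KS2F/KS2R consensus; hybrid and
#' trans-AT classes carry histidine at the KS2F glutamine position and
#' isoleucine at the KS2R 3'-valine; PUFA and enediyne diverge at further
#' positions), so in-silico primer evaluation on generated data reproduces
#' the qualitative coverage differences between KS types. The collection
#' is synthetic — generated, not curated — and its absolute hit counts are
#' not comparable to searches against real curated databases.
#'
#' @param n_per_leaf Entries per leaf class (default 10, giving 110).
#' @param domain_length Domain length in aa (default 420).
#' @param within_identity Identity of each entry to its class ancestor
#'   (default 0.90).
#' @param seed Integer seed; the default fixes the collection shipped with
#'   the package.
#' @return A [ks_refdb()] with attribute `ancestors` (named character
#'   vector of the per-leaf ancestral sequences).
#' @export
synthetic_reference_db <- function(n_per_leaf = 10L, domain_length = 420L,
                                   within_identity = 0.90, seed = 20230605L) {
  stopifnot(domain_length >= 50L)
  set.seed(seed)
  leaves <- ks_leaf_vocabulary()
  phyla <- list(
    "modular cis-AT" = c("Actinobacteria", "Proteobacteria"),
    "cis-loading module" = c("Actinobacteria", "Firmicutes"),
    "olefin synthase" = c("Cyanobacteria", "Proteobacteria"),
    "iterative aromatic" = c("Actinobacteria", "Chloroflexi"),
    "iterative PTM" = c("Proteobacteria", "Verrucomicrobia"),
    "trans-AT" = c("Firmicutes", "Gammaproteobacteria"),
    "hybrid trans-AT" = c("Proteobacteria", "Bacteroidetes"),
    "hybrid cis-AT" = c("Cyanobacteria", "Actinobacteria"),
    "PUFA" = c("Deltaproteobacteria", "Gammaproteobacteria"),
    "enediyne" = c("Actinobacteria", "Deltaproteobacteria"),
    "FAS" = c("Proteobacteria", "Actinobacteria"))
  core_len <- domain_length - nchar(ANCHOR_START) - nchar(ANCHOR_END)
  # planted primer-site residues by KS type (N- to C-terminal site strings)
  fwd_site <- function(l) {
    ssn <- .leaf_ssn(l)
    switch(ssn,
           "PUFA" = ,
           "enediyne" = "AMDPKQGI",      # diverged at the Q and R/S positions
           "hybrid cis-AT" = ,
           "trans-AT" = "AMDPQHRL",      # histidine at the glutamine position
           "AMDPQQRL")                   # cis-AT/iterative + FAS consensus
  }
  rev_site <- function(l) {
    if (.leaf_ssn(l) == "cis-AT/iterative") "VEAHGTCT" else "IEAHGTCT"
  }
  ancestors <- stats::setNames(vapply(leaves, function(l) {
    n_rand <- core_len - 16L
    a <- .random_protein(55L)
    b <- .random_protein(n_rand - 55L - 53L)
    c_ <- .random_protein(53L)
    paste0(ANCHOR_START, a, fwd_site(l), b, rev_site(l), c_, ANCHOR_END)
  }, character(1)), leaves)
  ids <- residues <- leaf <- phy <- character(0)
  for (l in leaves) {
    slug <- gsub("[^A-Za-z]+", "", l)
    for (k in seq_len(n_per_leaf)) {
      mut <- mutate_to_identity(ancestors[[l]], within_identity)
      ids <- c(ids, sprintf("REF_%s_%02d", slug, k))
      residues <- c(residues, mut$sequence)
      leaf <- c(leaf, l)
      phy <- c(phy, phyla[[l]][(k - 1L) %% length(phyla[[l]]) + 1L])
    }
  }
  db <- ks_refdb(ids, residues, leaf, phy)
  attr(db, "ancestors") <- ancestors
  db
}

#' Mutate a sequence to a target global identity
#'
#' Applies amino acid substitutions at distinct positions outside the
#' IAIVG/GTNAH anchor windows (when present and `preserve_anchors` is TRUE)
#' until the Hamming identity reaches the target; substitutions are drawn
#' from a BLOSUM62-weighted proposal (likelier replacements get exchangeable
#' residues), so mutated sequences resemble homologs rather than noise.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param seed_sequence Protein sequence.
#' @param identity_target Target identity in (0.5, 1].
#' @param preserve_anchors Keep terminal anchor windows untouched.
#' @param scoring A [ks_scoring()] providing the substitution matrix.
#' @return List with `sequence` and `realized_identity` (substitution-level
#'   identity, within 0.03 of the target).
#' @export
mutate_to_identity <- function(seed_sequence, identity_target,
                               preserve_anchors = TRUE,
                               scoring = ks_scoring()) {
  if (identity_target <= 0.5 || identity_target > 1) {
    stop("identity_target must lie in (0.5, 1]")
  }
  L <- nchar(seed_sequence)
  chars <- strsplit(seed_sequence, "", fixed = TRUE)[[1]]
  n_sub <- round((1 - identity_target) * L)
  if (n_sub == 0L) {
    return(list(sequence = seed_sequence, realized_identity = 1))
  }
  mutable <- seq_len(L)
  if (preserve_anchors) {
    if (startsWith(seed_sequence, ANCHOR_START)) {
      mutable <- setdiff(mutable, seq_len(nchar(ANCHOR_START)))
    }
    if (endsWith(seed_sequence, ANCHOR_END)) {
      mutable <- setdiff(mutable, seq.int(L - nchar(ANCHOR_END) + 1L, L))
    }
  }
  if (n_sub > length(mutable)) {
    stop("identity target ", identity_target, " unreachable: only ",
         length(mutable), " mutable positions in a ", L, "-aa sequence")
  }
  pos <- mutable[sample.int(length(mutable), n_sub)]
  mat <- scoring$matrix[.PROTEIN_ALPHABET, .PROTEIN_ALPHABET]
  for (p in pos) {
    orig <- chars[p]
    w <- 2^mat[orig, ]
    w[orig] <- 0
    chars[p] <- sample(.PROTEIN_ALPHABET, 1L, prob = w)
  }
  list(sequence = paste(chars, collapse = ""),
       realized_identity = (L - n_sub) / L)
}

#' Define a biome generation profile
#'
#' @param biome Biome name.
#' @param weights Named numeric over (a subset of) the 11 leaf classes;
#'   non-negative, must sum to 1 within 1e-9. Unnamed classes get weight 0.
#' @param lineage_count Seed lineages drawn per leaf class (default 3).
#' @param identity_target Identity of generated sequences to their lineage
#'   seed (default 0.85).
#' @param full_length_fraction Fraction of sequences retaining both
#'   terminal anchors (default 0.7).
#' @return List of class `ks_biome_profile`.
#' @export
biome_profile <- function(biome, weights, lineage_count = 3L,
                          identity_target = 0.85, full_length_fraction = 0.7) {
  leaves <- ks_leaf_vocabulary()
  bad <- setdiff(names(weights), leaves)
  if (length(bad)) stop("unknown leaf label(s) in weights: ", paste(bad, collapse = ", "))
  w <- stats::setNames(numeric(length(leaves)), leaves)
  w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 (got ", sum(w), ")")
  stopifnot(identity_target > 0.5, identity_target <= 1,
            full_length_fraction >= 0, full_length_fraction <= 1)
  structure(list(biome = biome, weights = w, lineage_count = lineage_count,
                 identity_target = identity_target,
                 full_length_fraction = full_length_fraction),
            class = "ks_biome_profile")
}

#' Default biome profiles for the eight surveyed biomes
#'
#' Qualitative KS-type mixtures emulating the survey's biome structure:
#' marine sediments and seawater are enriched in PUFA and enediyne KS
#' domains; forest/agricultural soils and rhizospheres in modular and
#' hybrid cis-AT domains; the remaining biomes are mixed. The exact weights
#' are illustrative choices of this package, not measurements.
#'
#' @param identity_target,full_length_fraction Passed to every profile.
#' @return Named list of [biome_profile()] objects.
#' @export
default_biome_profiles <- function(identity_target = 0.85,
                                   full_length_fraction = 0.7) {
  marine <- c("PUFA" = 0.34, "enediyne" = 0.12, "modular cis-AT" = 0.14,
              "hybrid cis-AT" = 0.08, "trans-AT" = 0.08,
              "hybrid trans-AT" = 0.04, "cis-loading module" = 0.05,
              "olefin synthase" = 0.04, "iterative aromatic" = 0.03,
              "iterative PTM" = 0.03, "FAS" = 0.05)
  seawater <- c("PUFA" = 0.38, "enediyne" = 0.07, "modular cis-AT" = 0.15,
                "hybrid cis-AT" = 0.08, "trans-AT" = 0.08,
                "hybrid trans-AT" = 0.04, "cis-loading module" = 0.05,
                "olefin synthase" = 0.05, "iterative aromatic" = 0.03,
                "iterative PTM" = 0.03, "FAS" = 0.04)
  soil <- c("modular cis-AT" = 0.34, "hybrid cis-AT" = 0.22,
            "cis-loading module" = 0.08, "olefin synthase" = 0.04,
            "iterative aromatic" = 0.06, "iterative PTM" = 0.07,
            "trans-AT" = 0.07, "hybrid trans-AT" = 0.03, "PUFA" = 0.04,
            "enediyne" = 0.02, "FAS" = 0.03)
  rhizo <- c("modular cis-AT" = 0.28, "hybrid cis-AT" = 0.24,
             "cis-loading module" = 0.07, "olefin synthase" = 0.04,
             "iterative aromatic" = 0.06, "iterative PTM" = 0.08,
             "trans-AT" = 0.09, "hybrid trans-AT" = 0.04, "PUFA" = 0.05,
             "enediyne" = 0.02, "FAS" = 0.03)
  peat <- c("modular cis-AT" = 0.26, "hybrid cis-AT" = 0.18,
            "cis-loading module" = 0.07, "olefin synthase" = 0.05,
            "iterative aromatic" = 0.08, "iterative PTM" = 0.08,
            "trans-AT" = 0.10, "hybrid trans-AT" = 0.05, "PUFA" = 0.07,
            "enediyne" = 0.02, "FAS" = 0.04)
  fw_sed <- c("modular cis-AT" = 0.22, "hybrid cis-AT" = 0.14,
              "cis-loading module" = 0.07, "olefin synthase" = 0.05,
              "iterative aromatic" = 0.07, "iterative PTM" = 0.07,
              "trans-AT" = 0.12, "hybrid trans-AT" = 0.05, "PUFA" = 0.12,
              "enediyne" = 0.04, "FAS" = 0.05)
  fw <- c("modular cis-AT" = 0.20, "hybrid cis-AT" = 0.12,
          "cis-loading module" = 0.07, "olefin synthase" = 0.07,
          "iterative aromatic" = 0.07, "iterative PTM" = 0.06,
          "trans-AT" = 0.13, "hybrid trans-AT" = 0.05, "PUFA" = 0.14,
          "enediyne" = 0.03, "FAS" = 0.06)
  host <- c("modular cis-AT" = 0.18, "hybrid cis-AT" = 0.12,
            "cis-loading module" = 0.06, "olefin synthase" = 0.04,
            "iterative aromatic" = 0.08, "iterative PTM" = 0.08,
            "trans-AT" = 0.20, "hybrid trans-AT" = 0.08, "PUFA" = 0.08,
            "enediyne" = 0.02, "FAS" = 0.06)
  mk <- function(b, w) biome_profile(b, w, identity_target = identity_target,
                                     full_length_fraction = full_length_fraction)
  list(
    `marine sediment` = mk("marine sediment", marine),
    seawater = mk("seawater", seawater),
    `forest/agricultural soil` = mk("forest/agricultural soil", soil),
    rhizosphere = mk("rhizosphere", rhizo),
    `peat soil` = mk("peat soil", peat),
    `freshwater sediment` = mk("freshwater sediment", fw_sed),
    freshwater = mk("freshwater", fw),
    `host associated` = mk("host associated", host))
}

#' Generate one biome's worth of synthetic KS domain sequences
#'
#' Leaf labels are drawn from the profile's mixture weights; for each
#' sequence a lineage seed (a reference entry of that leaf class) is chosen
#' and mutated to the profile's identity target with anchors preserved.
#' A `full_length_fraction` subset keeps both terminal anchors; the rest
#' are truncated past one anchor so the full-length extractor rejects them.
#'
#' @param profile A [biome_profile()].
#' @param n_sequences Number of sequences to generate.
#' @param refdb A [ks_refdb()] supplying lineage seeds (the first
#'   `lineage_count` entries per leaf class are used).
#' @param seed Optional integer seed (set once at entry).
#' @param id_prefix Prefix for generated ids (default from the biome name).
#' @return List with `records` (named character vector) and `truth`
#'   (`data.frame`: `id`, `leaf_label`, `lineage_id`, `realized_identity`,
#'   `biome`, `is_full_length`).
#' @export
generate_biome <- function(profile, n_sequences, refdb, seed = NULL,
                           id_prefix = NULL) {
  stopifnot(inherits(profile, "ks_biome_profile"), inherits(refdb, "ks_refdb"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id_prefix)) id_prefix <- gsub("[^A-Za-z]+", "_", profile$biome)
  active <- names(profile$weights)[profile$weights > 0]
  seeds_by_leaf <- lapply(active, function(l) {
    rows <- which(refdb$leaf_label == l)
    if (!length(rows)) {
      stop("configuration error: leaf '", l,
           "' has positive weight but no reference seed")
    }
    rows[seq_len(min(profile$lineage_count, length(rows)))]
  })
  names(seeds_by_leaf) <- active
  labs <- sample(active, n_sequences, replace = TRUE,
                 prob = profile$weights[active])
  records <- character(n_sequences)
  truth <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    rows <- seeds_by_leaf[[labs[i]]]
    j <- rows[sample.int(length(rows), 1L)]
    mut <- mutate_to_identity(refdb$residues[j], profile$identity_target)
    s <- mut$sequence
    is_fl <- stats::runif(1) < profile$full_length_fraction
    if (!is_fl) {
      # truncate past one anchor so the domain no longer spans both motifs
      cut <- 8L + sample.int(20L, 1L)
      s <- if (stats::runif(1) < 0.5) substr(s, cut + 1L, nchar(s)) else
        substr(s, 1L, nchar(s) - cut)
    }
    id <- sprintf("%s_%05d", id_prefix, i)
    records[i] <- s
    truth[[i]] <- data.frame(id = id, leaf_label = labs[i],
                             lineage_id = refdb$id[j],
                             realized_identity = mut$realized_identity,
                             biome = profile$biome, is_full_length = is_fl,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  names(records) <- truth$id
  list(records = records, truth = truth)
}

#' Back-translate a peptide into a nucleotide contig
#'
#' Codons are sampled uniformly among synonyms of each residue and random
#' nucleotide flanks are added on both sides, producing contig-like input
#' for the six-frame translation path. Uses the current RNG state.
#'
#' @param protein_record Named protein sequence (length-1 character).
#' @param flank_nt Flank length added on each side (default 300).
#' @return Named nucleotide sequence; attributes `cds_start` (1-based
#'   forward-strand start of the coding region) and `frame`.
#' @export
back_translate <- function(protein_record, flank_nt = 300L) {
  stopifnot(length(protein_record) == 1L)
  .check_alphabet(protein_record, "protein")
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), gc)
  aa <- strsplit(protein_record[[1]], "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    if (a == "X") {
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    } else {
      s <- syn[[a]]
      s[sample.int(length(s), 1L)]
    }
  }, character(1))
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                    prob = c(.3, .2, .2, .3)), collapse = "")
  nt <- paste0(flank(flank_nt), paste(codons, collapse = ""), flank(flank_nt))
  nm <- names(protein_record) %||% "contig"
  out <- stats::setNames(nt, nm)
  attr(out, "cds_start") <- flank_nt + 1L
  attr(out, "frame") <- (flank_nt %% 3L) + 1L
  out
}
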