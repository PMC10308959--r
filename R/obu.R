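#' Greedy centroid clustering into operational biosynthetic units (OBUs)
#'
#' Sequences are visited in order of decreasing length (ties broken by id)
#' and each joins the first existing centroid, in founding order, whose
#' global amino acid identity to it is at least `threshold`; otherwise it
#' founds a new cluster with itself as centroid. This mirrors the greedy
#' incremental behavior of common centroid clusterers applied to
#' full-length KS domains.
#'
#' @param sequences Named character vector of protein sequences.
#' @param threshold Identity threshold in (0, 1], e.g. 0.70/0.80/0.90/0.95.
#' @param scoring A [ks_scoring()].
#' @param identities Optional precomputed identity matrix from
#'   [identity_matrix()] covering all sequence names; avoids re-aligning
#'   when the same sequences are clustered repeatedly (rarefaction
#'   replicates, multiple thresholds).
#' @return Object of class `obu_table`: list with `threshold`,
#'   `members` (data.frame `id`, `centroid_id`) and `sizes` (named integer
#'   vector per centroid, founding order).
#' @export
cluster_obus <- function(sequences, threshold, scoring = ks_scoring(),
                         identities = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sequences) == 0L) {
    return(structure(list(threshold = threshold,
                          members = data.frame(id = character(0),
                                               centroid_id = character(0),
                                               stringsAsFactors = FALSE),
                          sizes = integer(0)), class = "obu_table"))
  }
  if (is.null(names(sequences))) names(sequences) <- paste0("seq_", seq_along(sequences))
  stopifnot(!anyDuplicated(names(sequences)))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  centroid_seq <- character(0)
  centroid_id <- character(0)
  assign <- character(length(sequences))
  if (!is.null(identities) &&
      !all(names(sequences) %in% rownames(identities))) {
    stop("identity matrix does not cover all sequence names")
  }
  for (i in seq_along(sequences)) {
    if (length(centroid_seq)) {
      ident <- if (is.null(identities)) {
        .global_identity_many(sequences[[i]], centroid_seq, scoring)
      } else {
        identities[names(sequences)[i], centroid_id]
      }
      j <- which(ident >= threshold)
      if (length(j)) {
        assign[i] <- centroid_id[j[1]]  # first centroid in founding order
        next
      }
    }
    centroid_seq <- c(centroid_seq, sequences[[i]])
    centroid_id <- c(centroid_id, names(sequences)[i])
    assign[i] <- names(sequences)[i]
  }
  members <- data.frame(id = names(sequences), centroid_id = assign,
                        stringsAsFactors = FALSE)
  sizes <- vapply(centroid_id, function(cid) sum(assign == cid), integer(1))
  structure(list(threshold = threshold, members = members, sizes = sizes),
            class = "obu_table")
}

#' @export
print.obu_table <- function(x, ...) {
  cat("OBU table at ", sprintf("%.0f%%", 100 * x$threshold), " identity: ",
      length(x$sizes), " OBU(s), ", nrow(x$members), " member(s)\n", sep = "")
  invisible(x)
}

#' All-pairs global identity matrix
#'
#' Pairwise global identities ([global_identity()]) among a set of
#' sequences, computed once and reusable across clustering runs.
#'
#' @param sequences Named character vector of protein sequences.
#' @param scoring A [ks_scoring()].
#' @return Symmetric numeric matrix with unit diagonal and the sequence
#'   names as dimnames.
#' @export
identity_matrix <- function(sequences, scoring = ks_scoring()) {
  if (is.null(names(sequences))) names(sequences) <- paste0("seq_", seq_along(sequences))
  n <- length(sequences)
  m <- diag(1, n)
  dimnames(m) <- list(names(sequences), names(sequences))
  for (i in seq_len(max(n - 1L, 0L))) {
    idx <- seq.int(i + 1L, n)
    v <- .global_identity_many(sequences[[i]], sequences[idx], scoring)
    m[i, idx] <- v
    m[idx, i] <- v
  }
  m
}

#' Rarefy a sequence set to a fixed depth
#'
#' Uniform sample without replacement, seeded for reproducibility.
#'
#' @param sequences Named character vector.
#' @param depth Number of sequences to retain.
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return The sampled subset (named, original names kept).
#' @export
rarefy_sequences <- function(sequences, depth, seed = NULL) {
  if (length(sequences) < depth) {
    stop("cannot rarefy ", length(sequences), " sequences to depth ", depth,
         "; lower the depth")
  }
  if (!is.null(seed)) set.seed(seed)
  sequences[sort(sample.int(length(sequences), depth))]
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` where `F1` and `F2` are the
#' numbers of singleton and doubleton clusters. Always at least `S_obs`.
#'
#' @param obu_sizes Positive integer cluster sizes (or an `obu_table`).
#' @return Chao1 estimate (numeric scalar).
#' @export
chao1 <- function(obu_sizes) {
  if (inherits(obu_sizes, "obu_table")) obu_sizes <- obu_sizes$sizes
  if (length(obu_sizes) == 0L) stop("chao1 requires at least one cluster")
  if (any(obu_sizes < 1)) stop("cluster sizes must be positive")
  f1 <- sum(obu_sizes == 1)
  f2 <- sum(obu_sizes == 2)
  length(obu_sizes) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefied Chao1 OBU richness per biome
#'
#' For each biome and identity threshold, performs `replicates` independent
#' rarefy-cluster-estimate runs: the biome's full-length domains are
#' rarefied to `depth`, clustered into OBUs and summarized with Chao1; the
#' mean and standard deviation over replicates are reported. Biomes with
#' fewer than `depth` sequences are skipped with a warning unless
#' `auto_lower_depth` is set, in which case the depth drops to the smallest
#' biome size.
#'
#' @param full_length Data frame with columns `id`, `residues`, `biome`.
#' @param thresholds Identity thresholds (default `c(0.70, 0.80, 0.90, 0.95)`).
#' @param depth Rarefaction depth (default 580, the survey convention).
#' @param replicates Number of replicate analyses (default 10).
#' @param seed Integer seed; replicate r of biome b uses a deterministic
#'   offset so the whole analysis is reproducible.
#' @param auto_lower_depth Lower `depth` to the minimum biome size when some
#'   biome is smaller (default TRUE, with a warning).
#' @param scoring A [ks_scoring()].
#' @return `data.frame`: `biome`, `threshold`, `chao1_mean`, `chao1_sd`,
#'   `obs_mean`, `replicates`, `depth`.
#' @export
richness_by_biome <- function(full_length, thresholds = c(0.70, 0.80, 0.90, 0.95),
                              depth = 580L, replicates = 10L, seed = 1L,
                              auto_lower_depth = TRUE, scoring = ks_scoring()) {
  stopifnot(all(c("id", "residues", "biome") %in% names(full_length)))
  sizes <- table(full_length$biome)
  if (min(sizes) < depth) {
    if (auto_lower_depth) {
      warning("rarefaction depth lowered from ", depth, " to ", min(sizes),
              " (smallest biome)")
      depth <- as.integer(min(sizes))
    } else {
      skip <- names(sizes)[sizes < depth]
      warning("skipping biome(s) below depth ", depth, ": ",
              paste(skip, collapse = ", "))
      full_length <- full_length[!full_length$biome %in% skip, , drop = FALSE]
    }
  }
  out <- list()
  biomes <- sort(unique(full_length$biome))
  for (bi in seq_along(biomes)) {
    b <- biomes[bi]
    seqs <- stats::setNames(full_length$residues[full_length$biome == b],
                            full_length$id[full_length$biome == b])
    idm <- identity_matrix(seqs, scoring)
    for (ti in seq_along(thresholds)) {
      ch <- ob <- numeric(replicates)
      for (r in seq_len(replicates)) {
        sub <- rarefy_sequences(seqs, depth,
                                seed = seed + 1000L * bi + 100L * ti + r)
        tab <- cluster_obus(sub, thresholds[ti], scoring, identities = idm)
        ch[r] <- chao1(tab$sizes)
        ob[r] <- length(tab$sizes)
      }
      out[[length(out) + 1L]] <- data.frame(
        biome = b, threshold = thresholds[ti],
        chao1_mean = mean(ch),
        chao1_sd = if (replicates > 1L) stats::sd(ch) else 0,
        obs_mean = mean(ob), replicates = replicates, depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Shared OBUs between biome pairs
#'
#' All biomes are rarefied to a common depth, pooled and clustered once per
#' threshold; for each unordered biome pair an OBU counts as shared when it
#' contains at least one member from each biome, and `shared_domain_count`
#' sums the pair's members inside shared OBUs.
#'
#' @param full_length Data frame with `id`, `residues`, `biome`.
#' @param thresholds Identity thresholds.
#' @param depth Common rarefaction depth; `NULL` uses the smallest biome.
#' @param seed Integer seed for the rarefaction draws.
#' @param scoring A [ks_scoring()].
#' @return `data.frame`: `biome_a`, `biome_b`, `threshold`,
#'   `shared_obu_count`, `shared_domain_count`.
#' @export
shared_obus <- function(full_length, thresholds = c(0.70, 0.80, 0.90, 0.95),
                        depth = NULL, seed = 1L, scoring = ks_scoring()) {
  stopifnot(all(c("id", "residues", "biome") %in% names(full_length)))
  biomes <- sort(unique(full_length$biome))
  if (length(biomes) < 2L) stop("shared-OBU analysis needs at least two biomes")
  sizes <- table(full_length$biome)
  if (is.null(depth)) depth <- as.integer(min(sizes))
  if (min(sizes) < depth) stop("some biome has fewer than ", depth, " sequences")
  pooled <- list()
  for (bi in seq_along(biomes)) {
    b <- biomes[bi]
    seqs <- stats::setNames(full_length$residues[full_length$biome == b],
                            full_length$id[full_length$biome == b])
    pooled[[b]] <- rarefy_sequences(seqs, depth, seed = seed + bi)
  }
  seqs <- unlist(unname(pooled))
  biome_of <- rep(biomes, vapply(pooled, length, integer(1)))
  names(biome_of) <- unlist(lapply(pooled, names))
  idm <- identity_matrix(seqs, scoring)
  out <- list()
  for (th in thresholds) {
    tab <- cluster_obus(seqs, th, scoring, identities = idm)
    mem <- tab$members
    mem$biome <- biome_of[mem$id]
    for (i in seq_len(length(biomes) - 1L)) {
      for (j in seq.int(i + 1L, length(biomes))) {
        a <- biomes[i]; b <- biomes[j]
        byc <- split(mem$biome, mem$centroid_id)
        shared <- vapply(byc, function(v) any(v == a) && any(v == b), logical(1))
        n_dom <- sum(vapply(byc[shared], function(v) sum(v %in% c(a, b)), integer(1)))
        out[[length(out) + 1L]] <- data.frame(
          biome_a = a, biome_b = b, threshold = th,
          shared_obu_count = sum(shared), shared_domain_count = n_dom,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
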