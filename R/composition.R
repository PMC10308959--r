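#' KS domain counts per gigabase pair
#'
#' @param counts Non-negative numeric vector (per leaf class).
#' @param size_gbp Metagenome assembly size in Gbp (> 0).
#' @return `counts / size_gbp`.
#' @export
ks_per_gbp <- function(counts, size_gbp) {
  if (!is.numeric(size_gbp) || length(size_gbp) != 1L || !is.finite(size_gbp) ||
      size_gbp <= 0) {
    stop("size_gbp must be a single positive number")
  }
  counts / size_gbp
}

#' Leaf-class count matrix per metagenome
#'
#' @param calls `domain_calls` with a `metagenome_id` column.
#' @return Matrix metagenomes x 11 leaf classes of raw counts.
#' @export
composition_counts <- function(calls) {
  stopifnot("metagenome_id" %in% names(calls))
  leaves <- ks_leaf_vocabulary()
  mg <- sort(unique(calls$metagenome_id))
  m <- matrix(0L, length(mg), length(leaves), dimnames = list(mg, leaves))
  tab <- table(calls$metagenome_id, factor(calls$leaf_label, levels = leaves))
  m[rownames(tab), ] <- as.integer(tab)
  m
}

#' Rarefied KS composition profiles
#'
#' Each metagenome's domain calls are repeatedly subsampled without
#' replacement to `depth` calls and the leaf-class count vectors are
#' averaged over `permutations` draws, yielding fractional mean counts that
#' sum to `depth` per row. Metagenomes with fewer than `depth` calls are
#' excluded with a warning.
#'
#' @param calls `domain_calls` with `metagenome_id` and `leaf_label`.
#' @param depth Rarefaction depth (default 100).
#' @param permutations Number of permutation draws (default 1000).
#' @param seed Integer seed.
#' @return Matrix metagenomes x 11 leaf classes of mean rarefied counts,
#'   with attribute `excluded` naming any dropped metagenomes.
#' @export
rarefied_composition <- function(calls, depth = 100L, permutations = 1000L,
                                 seed = 1L) {
  stopifnot(all(c("metagenome_id", "leaf_label") %in% names(calls)))
  leaves <- ks_leaf_vocabulary()
  by_mg <- split(calls$leaf_label, calls$metagenome_id)
  n_mg <- vapply(by_mg, length, integer(1))
  excluded <- names(by_mg)[n_mg < depth]
  if (length(excluded)) {
    warning("excluding metagenome(s) with fewer than ", depth, " calls: ",
            paste(excluded, collapse = ", "))
    by_mg <- by_mg[n_mg >= depth]
  }
  if (length(by_mg) == 0L) stop("no metagenome reaches the rarefaction depth")
  set.seed(seed)
  m <- matrix(0, length(by_mg), length(leaves),
              dimnames = list(names(by_mg), leaves))
  for (g in names(by_mg)) {
    labs <- factor(by_mg[[g]], levels = leaves)
    n <- length(labs)
    if (n == depth) {
      m[g, ] <- as.numeric(table(labs))  # every draw is the full set
      next
    }
    acc <- numeric(length(leaves))
    for (p in seq_len(permutations)) {
      acc <- acc + tabulate(labs[sample.int(n, depth)], nbins = length(leaves))
    }
    m[g, ] <- acc / permutations
  }
  attr(m, "excluded") <- excluded
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over the composition rows
#' (computed with vegan). Rows must be non-negative with at least one
#' positive entry.
#'
#' @param mat Samples x classes matrix of non-negative abundances.
#' @return Symmetric zero-diagonal matrix of dissimilarities in \[0, 1\],
#'   with the input row names.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative abundances")
  if (any(rowSums(mat) == 0)) stop("all-zero row(s): ",
                                   paste(rownames(mat)[rowSums(mat) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered squared-distance matrix.
#' Coordinates are the eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported as-is and
#' excluded from the proportion-explained denominator; no correction is
#' applied.
#'
#' @param d Symmetric distance matrix (matrix or `dist`).
#' @return List of class `ks_pcoa`: `coordinates` (samples x axes),
#'   `eigenvalues` (descending), `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  k <- nrow(m) - 1L
  # cmdscale warns when the configuration has rank < n - 1; that is the
  # expected case for low-dimensional data, not a problem
  fit <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points
  prop <- eig[pos] / sum(eig[pos])
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop), class = "ks_pcoa")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix, computed with
#' `vegan::adonis2`: pseudo-F from the between/within sums of squared
#' distances and a permutation p-value
#' `(#{permuted F >= observed} + 1) / (permutations + 1)` under free
#' whole-sample label permutation (no strata).
#'
#' @param d Symmetric distance matrix with row names, or `dist`.
#' @param labels Group label per sample (>= 2 groups, each with >= 2
#'   members).
#' @param permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `ks_permanova`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, permutations = 999L, seed = 1L) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2L) stop("PERMANOVA needs at least two groups")
  if (any(tab < 2L)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  dat <- data.frame(grp = labels)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(m) ~ grp, data = dat,
                        permutations = permutations)
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 n_permutations = permutations, seed = seed),
            class = "ks_permanova")
}

#' @export
print.ks_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' One-way ANOVA with Tukey's HSD across biomes
#'
#' Fits `values ~ group` with `aov`, then Tukey-Kramer pairwise comparisons
#' via `TukeyHSD`; pairs significant at `alpha` are flagged.
#'
#' @param values Numeric response (e.g. per-Gbp abundance of one KS class).
#' @param groups Group label per value (>= 2 groups, each >= 2 values).
#' @param alpha Flagging level (default 0.01).
#' @return List of class `ks_tukey`: `F`, `p_value`, `pairs` (data.frame
#'   `pair`, `diff`, `p_adj`, `flagged`), `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.01) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least two groups required")
  if (any(table(groups) < 2L)) stop("each group needs at least two observations")
  if (stats::var(values) == 0) stop("degenerate input: all values equal, F undefined")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      flagged = tk[, "p adj"] < alpha,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                 pairs = pairs, alpha = alpha), class = "ks_tukey")
}
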