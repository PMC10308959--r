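#' Detect and classify KS domains by top-hit homology
#'
#' Each query peptide is searched against the labeled reference collection
#' with affine-gap local alignment. Per candidate region the best reference
#' hit (highest bit score; ties broken by lower E-value, then higher
#' identity, then lexicographic reference id) is retained if and only if the
#' alignment spans at least `min_match_aa` columns and its E-value is at
#' most `max_evalue`; the leaf/group/SSN classification of the winning
#' reference is copied onto the call. Multiple domains per peptide are
#' accepted when their query intervals overlap by less than 50% of the
#' shorter interval (multimodular PKSs carry tandem KS domains); regions are
#' considered greedily in score order.
#'
#' E-values use `m * n * 2^(-bitscore)` with `m` the query length and `n`
#' the total residue count of the reference collection. When a precomputed
#' 12-column hit table is supplied via `hits`, its printed E-values and bit
#' scores are trusted verbatim and no alignment is run.
#'
#' @param peptides Named character vector of protein sequences.
#' @param refdb A [ks_refdb()].
#' @param min_match_aa Minimum alignment length in columns (default 200).
#' @param max_evalue Maximum allowed E-value (default 1e-30).
#' @param scoring A [ks_scoring()].
#' @param max_align_per_query How many prescreen-ranked references are
#'   fully aligned per query (default 8; when the collection has at most
#'   this many entries every reference is aligned and the search is exact).
#'   Candidates are ranked by shared-word (4-mer) counts, the standard
#'   seeding heuristic of word-based protein search tools.
#' @param hits Optional precomputed hit table from [read_tabular_hits()].
#' @return `data.frame` of class `domain_calls`: one row per accepted
#'   domain with query/subject ids, 1-based inclusive query coordinates,
#'   classification labels, alignment statistics and the domain subsequence.
#' @export
classify_domains <- function(peptides, refdb, min_match_aa = 200L,
                             max_evalue = 1e-30, scoring = ks_scoring(),
                             max_align_per_query = 8L, hits = NULL) {
  if (!inherits(refdb, "ks_refdb") || nrow(refdb) == 0L) {
    stop("configuration error: non-empty ks_refdb required")
  }
  if (length(peptides) == 0L) return(.empty_calls())
  if (is.null(names(peptides))) names(peptides) <- paste0("query_", seq_along(peptides))
  .check_alphabet(peptides, "protein")
  if (!is.null(hits)) {
    return(.classify_from_hits(peptides, refdb, hits, min_match_aa, max_evalue))
  }
  n_db <- sum(nchar(refdb$residues))
  cand_by_pep <- .search_candidates(peptides, refdb, scoring, n_db,
                                    max_align_per_query)
  rows <- list()
  for (i in seq_along(peptides)) {
    cand <- cand_by_pep[[i]]
    bit <- vapply(cand, `[[`, numeric(1), "bitscore")
    ev <- vapply(cand, `[[`, numeric(1), "evalue")
    idf <- vapply(cand, `[[`, numeric(1), "identity_fraction")
    ids <- refdb$id[vapply(cand, `[[`, numeric(1), "ref_idx")]
    cand <- cand[order(-bit, ev, -idf, ids)]
    taken <- list()  # considered query intervals
    for (h in cand) {
      iv <- c(h$q_start, h$q_end)
      if (any(vapply(taken, function(t) .overlap_frac(iv, t) >= 0.5, logical(1)))) next
      taken[[length(taken) + 1L]] <- iv
      if (h$aln_columns >= min_match_aa && h$evalue <= max_evalue) {
        j <- h$ref_idx
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(peptides)[i], q_start = h$q_start, q_end = h$q_end,
          top_ref_id = refdb$id[j], leaf_label = refdb$leaf_label[j],
          group_label = refdb$group_label[j], ssn_group = refdb$ssn_group[j],
          identity_fraction = h$identity_fraction, aln_columns = h$aln_columns,
          raw_score = h$raw_score, bitscore = h$bitscore, evalue = h$evalue,
          domain_seq = substr(peptides[[i]], h$q_start, h$q_end),
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  calls <- if (length(rows)) do.call(rbind, rows) else .empty_calls()
  rownames(calls) <- NULL
  class(calls) <- c("domain_calls", "data.frame")
  calls
}

.unique_kmers <- function(s, k = 4L) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, seq_len(L - k + 1L), k:L))
}

# Rank references per peptide by shared-word (4-mer) count, then compute
# full local alignments for the top `max_align` candidates, grouped by
# reference so each reference needs one vectorised alignment call. When the
# collection has <= max_align entries all references are aligned (exact
# search).
.search_candidates <- function(peptides, refdb, scoring, n_db, max_align) {
  n_ref <- nrow(refdb)
  if (n_ref <= max_align) {
    top <- rep(list(seq_len(n_ref)), length(peptides))
  } else {
    ref_km <- lapply(refdb$residues, .unique_kmers)
    km_map <- split(rep(seq_len(n_ref), lengths(ref_km)), unlist(ref_km))
    top <- lapply(peptides, function(p) {
      u <- .unique_kmers(p)
      found <- unlist(km_map[u], use.names = FALSE)
      counts <- tabulate(found, nbins = n_ref)
      order(-counts, refdb$id)[seq_len(max_align)]
    })
  }
  pep_idx <- rep(seq_along(peptides), lengths(top))
  ref_idx <- unlist(top)
  cand <- vector("list", length(pep_idx))
  for (j in unique(ref_idx)) {
    sel <- which(ref_idx == j)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(peptides[pep_idx[sel]])),
      Biostrings::AAString(refdb$residues[j]),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "local")
    st <- .pa_identity_stats(pa, peptides[pep_idx[sel]], refdb$residues[j])
    raw <- Biostrings::score(pa)
    pr <- methods::slot(pa, "pattern")
    sr <- methods::slot(pa, "subject")
    qs <- Biostrings::start(pr); qe <- Biostrings::end(pr)
    ss <- Biostrings::start(sr); se <- Biostrings::end(sr)
    for (t in seq_along(sel)) {
      bit <- .bitscore(raw[t], scoring)
      i <- pep_idx[sel[t]]
      cand[[sel[t]]] <- list(
        raw_score = raw[t], bitscore = bit,
        evalue = .evalue(bit, nchar(peptides[[i]]), n_db),
        identity_fraction = st$matches[t] / st$cols[t],
        aln_columns = st$cols[t],
        q_start = qs[t], q_end = qe[t], s_start = ss[t], s_end = se[t],
        ref_idx = j)
    }
  }
  unname(split(cand, pep_idx))
}

# overlap of [a1,a2] and [b1,b2] as a fraction of the shorter interval
.overlap_frac <- function(a, b) {
  ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1L
  if (ov <= 0L) return(0)
  ov / min(a[2] - a[1] + 1L, b[2] - b[1] + 1L)
}

.empty_calls <- function() {
  calls <- data.frame(query_id = character(0), q_start = integer(0),
                      q_end = integer(0), top_ref_id = character(0),
                      leaf_label = character(0), group_label = character(0),
                      ssn_group = character(0), identity_fraction = numeric(0),
                      aln_columns = integer(0), raw_score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      domain_seq = character(0), stringsAsFactors = FALSE)
  class(calls) <- c("domain_calls", "data.frame")
  calls
}

.classify_from_hits <- function(peptides, refdb, hits, min_match_aa, max_evalue) {
  stopifnot(is.data.frame(hits))
  unknown <- setdiff(unique(hits$subject_id), refdb$id)
  if (length(unknown)) {
    stop("hit table references unknown subject id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  rows <- list()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, -h$pct_identity, h$subject_id), , drop = FALSE]
    taken <- list()
    for (k in seq_len(nrow(h))) {
      iv <- c(h$q_start[k], h$q_end[k])
      if (any(vapply(taken, function(t) .overlap_frac(iv, t) >= 0.5, logical(1)))) next
      taken[[length(taken) + 1L]] <- iv
      if (h$aln_length[k] >= min_match_aa && h$evalue[k] <= max_evalue) {
        j <- match(h$subject_id[k], refdb$id)
        dseq <- if (q %in% names(peptides)) {
          substr(peptides[[q]], h$q_start[k], h$q_end[k])
        } else NA_character_
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, q_start = h$q_start[k], q_end = h$q_end[k],
          top_ref_id = refdb$id[j], leaf_label = refdb$leaf_label[j],
          group_label = refdb$group_label[j], ssn_group = refdb$ssn_group[j],
          identity_fraction = h$pct_identity[k] / 100,
          aln_columns = h$aln_length[k], raw_score = NA_real_,
          bitscore = h$bitscore[k], evalue = h$evalue[k],
          domain_seq = dseq, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else .empty_calls()
  rownames(calls) <- NULL
  class(calls) <- c("domain_calls", "data.frame")
  calls
}

#' Assign a phylum to each domain call by closest labeled match
#'
#' The phylum of the reference with the lowest E-value against the domain
#' subsequence is reported (ties: lowest E-value, then highest identity,
#' then lexicographic reference id), together with the identity to that
#' reference. Matches below 75% identity are flagged tentative.
#'
#' @param calls A `domain_calls` data frame with a `domain_seq` column.
#' @param refdb A [ks_refdb()].
#' @param scoring A [ks_scoring()].
#' @param max_align_per_query Prescreen width, as in [classify_domains()].
#' @return `calls` with added columns `phylum_call`, `phylum_ref_id`,
#'   `phylum_identity`, `phylum_tentative`.
#' @export
assign_phylum <- function(calls, refdb, scoring = ks_scoring(),
                          max_align_per_query = 8L) {
  stopifnot(inherits(refdb, "ks_refdb"))
  if (nrow(calls) == 0L) {
    calls$phylum_call <- character(0); calls$phylum_ref_id <- character(0)
    calls$phylum_identity <- numeric(0); calls$phylum_tentative <- logical(0)
    return(calls)
  }
  n_db <- sum(nchar(refdb$residues))
  cand_by_dom <- .search_candidates(
    stats::setNames(calls$domain_seq, calls$query_id), refdb, scoring,
    n_db, max_align_per_query)
  out <- lapply(cand_by_dom, function(cand) {
    ev <- vapply(cand, `[[`, numeric(1), "evalue")
    idf <- vapply(cand, `[[`, numeric(1), "identity_fraction")
    ids <- refdb$id[vapply(cand, `[[`, numeric(1), "ref_idx")]
    k <- order(ev, -idf, ids)[1]
    win <- cand[[k]]$ref_idx
    data.frame(phylum_call = refdb$phylum[win], phylum_ref_id = refdb$id[win],
               phylum_identity = idf[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  calls$phylum_call <- out$phylum_call
  calls$phylum_ref_id <- out$phylum_ref_id
  calls$phylum_identity <- out$phylum_identity
  calls$phylum_tentative <- out$phylum_identity < 0.75
  calls
}

#' @export
print.domain_calls <- function(x, ...) {
  cat("KS domain calls: ", nrow(x), " domain(s) on ",
      length(unique(x$query_id)), " query peptide(s)\n", sep = "")
  if (nrow(x)) {
    tab <- sort(table(x$leaf_label), decreasing = TRUE)
    cat("  leaf classes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
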