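#' Trim full-length KS domains to amplicon length
#'
#' Reproduces the amplicon-length truncation experiment: each full-length
#' domain is trimmed to `length_aa` residues, either starting at the site
#' located for the forward KS primer (`placement = "primer_site"`, falling
#' back to a centered window when the site is low-confidence) or centered
#' within the domain (`placement = "center"`, window start
#' `floor((L - length_aa) / 2) + 1`). Windows that would overrun the domain
#' end are shifted left to fit.
#'
#' @param full_length Data frame with `id`/`query_id` and `residues`
#'   columns (as from [extract_full_length()]), or a named character
#'   vector.
#' @param length_aa Amplicon length in residues (default 138).
#' @param placement `"primer_site"` or `"center"`.
#' @param pattern Forward-primer pattern used for `primer_site` placement
#'   (default the translated KS2F pattern).
#' @return Named character vector of trimmed sequences (one per input
#'   domain, same ids).
#' @export
trim_to_amplicon <- function(full_length, length_aa = 138L,
                             placement = c("primer_site", "center"),
                             pattern = translate_degenerate(ks2_primers()$KS2F)) {
  placement <- match.arg(placement)
  if (is.data.frame(full_length)) {
    ids <- if ("id" %in% names(full_length)) full_length$id else full_length$query_id
    seqs <- stats::setNames(full_length$residues, ids)
  } else {
    seqs <- full_length
  }
  L <- nchar(seqs)
  if (any(L < length_aa)) {
    stop("domain(s) shorter than the trim length ", length_aa, ": ",
         paste(names(seqs)[L < length_aa], collapse = ", "))
  }
  out <- vapply(seq_along(seqs), function(i) {
    n <- L[i]
    start <- if (placement == "center") {
      (n - length_aa) %/% 2L + 1L
    } else {
      site <- locate_primer_site(pattern, seqs[[i]])
      if (site$low_confidence) (n - length_aa) %/% 2L + 1L else site$pos
    }
    start <- min(start, n - length_aa + 1L)
    substr(seqs[[i]], start, start + length_aa - 1L)
  }, character(1))
  stats::setNames(out, names(seqs))
}

#' Classification concordance between full-length and trimmed domains
#'
#' Pairs full-length and trimmed-domain calls by id and reports, per SSN
#' group and overall, the fraction of pairs whose leaf classification is
#' unchanged after trimming. Trimmed sequences that produced no call count
#' as discordant. Trimmed calls whose id does not occur among the
#' full-length calls are an error.
#'
#' @param full_calls `domain_calls` for the full-length domains; ids taken
#'   from `query_id`.
#' @param trimmed_calls `domain_calls` for the re-classified trimmed
#'   sequences.
#' @return List of class `ks_concordance`: `overall` (fraction), `n`,
#'   `by_group` (data.frame `group`, `n`, `concordant_fraction`).
#' @export
concordance <- function(full_calls, trimmed_calls) {
  if (nrow(full_calls) == 0L) stop("no full-length calls supplied")
  un <- setdiff(trimmed_calls$query_id, full_calls$query_id)
  if (length(un)) {
    stop("trimmed call(s) with no full-length counterpart: ",
         paste(utils::head(un, 5), collapse = ", "))
  }
  i <- match(full_calls$query_id, trimmed_calls$query_id)
  same <- !is.na(i) & trimmed_calls$leaf_label[i] == full_calls$leaf_label
  grp <- full_calls$ssn_group
  by_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               concordant_fraction = mean(same[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(overall = mean(same), n = nrow(full_calls),
                 by_group = by_group), class = "ks_concordance")
}

#' @export
print.ks_concordance <- function(x, ...) {
  cat(sprintf("Trim concordance: %.1f%% of %d domains keep their leaf class\n",
              100 * x$overall, x$n))
  invisible(x)
}

#' Run the truncation-concordance experiment at several trim lengths
#'
#' Classifies the full-length domains, then for each trim length trims,
#' re-classifies with a lowered minimum match length (the full-length
#' 200-aa floor cannot apply to a 138-aa query) and computes concordance.
#'
#' @param full_length Data frame with `id` and `residues` (full-length
#'   domains).
#' @param refdb A [ks_refdb()].
#' @param lengths Trim lengths in aa (default `c(420, 276, 138)`; lengths
#'   at or above a domain's length leave it untrimmed).
#' @param placement Passed to [trim_to_amplicon()].
#' @param min_match_aa_trimmed Match-length floor for trimmed queries
#'   (default 100).
#' @param max_evalue,scoring Passed to [classify_domains()].
#' @return `data.frame`: `length_aa`, `overall_concordance`, `n`.
#' @export
trim_concordance_curve <- function(full_length, refdb,
                                   lengths = c(420L, 276L, 138L),
                                   placement = "center",
                                   min_match_aa_trimmed = 100L,
                                   max_evalue = 1e-30,
                                   scoring = ks_scoring()) {
  seqs <- stats::setNames(full_length$residues, full_length$id)
  full_calls <- classify_domains(seqs, refdb, min_match_aa = 200L,
                                 max_evalue = max_evalue, scoring = scoring)
  # only domains with a full-length classification enter the comparison
  seqs <- seqs[names(seqs) %in% full_calls$query_id]
  out <- list()
  for (len in lengths) {
    eff <- pmin(len, nchar(seqs))
    trimmed <- vapply(seq_along(seqs), function(i) {
      trim_to_amplicon(seqs[i], length_aa = eff[i], placement = placement)
    }, character(1))
    names(trimmed) <- names(seqs)
    mm <- if (len >= 200L) 200L else min_match_aa_trimmed
    tcalls <- classify_domains(trimmed, refdb, min_match_aa = mm,
                               max_evalue = max_evalue, scoring = scoring)
    conc <- concordance(full_calls, tcalls)
    out[[length(out) + 1L]] <- data.frame(length_aa = len,
                                          overall_concordance = conc$overall,
                                          n = conc$n)
  }
  do.call(rbind, out)
}
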