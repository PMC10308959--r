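ANCHOR_START <- "IAIVG"
ANCHOR_END <- "GTNAH"

#' Locate a short anchor motif allowing mismatches
#'
#' Scans every window of the motif's length and returns the best-matching
#' window (fewest mismatches). Ties are broken leftmost for start anchors
#' and rightmost for end anchors. `X` in the sequence never matches.
#'
#' @param residues Protein sequence (character scalar).
#' @param anchor_motif Motif, e.g. `"IAIVG"`.
#' @param max_mismatch Maximum mismatches tolerated (default 1).
#' @param side `"start"` (leftmost tie-break) or `"end"` (rightmost).
#' @return List with `pos` (1-based window start) and `mismatches`, or
#'   `NULL` when no window has at most `max_mismatch` mismatches (including
#'   when the motif is longer than the sequence).
#' @export
find_anchor <- function(residues, anchor_motif, max_mismatch = 1L,
                        side = c("start", "end")) {
  side <- match.arg(side)
  mm <- .anchor_mismatch_counts(residues, anchor_motif)
  if (is.null(mm)) return(NULL)
  best <- min(mm)
  if (best > max_mismatch) return(NULL)
  hits <- which(mm == best)
  pos <- if (side == "start") hits[1] else hits[length(hits)]
  list(pos = pos, mismatches = best)
}

# per-window mismatch counts, NULL if motif longer than sequence
.anchor_mismatch_counts <- function(residues, anchor_motif) {
  k <- nchar(anchor_motif)
  L <- nchar(residues)
  if (k > L) return(NULL)
  sc <- strsplit(residues, "", fixed = TRUE)[[1]]
  mc <- strsplit(anchor_motif, "", fixed = TRUE)[[1]]
  n_win <- L - k + 1L
  mm <- integer(n_win)
  for (j in seq_len(k)) {
    win_res <- sc[seq.int(j, j + n_win - 1L)]
    mm <- mm + as.integer(win_res != mc[j] | win_res == "X")
  }
  mm
}

#' Extract full-length KS domains bounded by terminal anchor motifs
#'
#' A KS domain is categorized as full length when it spans the conserved
#' IAIVG start residues through the GTNAH end residues (some degeneracy
#' tolerated via `max_mismatch`). The sequence is clipped from the first
#' residue of the start anchor through the last residue of the end anchor.
#' When several qualifying anchor windows exist, the longest spanning pair
#' (leftmost qualifying start, rightmost qualifying end) is taken.
#' Non-spanning domains are silently excluded (their count is reported in a
#' `n_excluded` attribute).
#'
#' @param calls A `domain_calls` data frame (needs `domain_seq`), or any
#'   data frame with `query_id`/`domain_seq` columns, or a named character
#'   vector of domain sequences.
#' @param max_mismatch Mismatches tolerated per anchor, 0-2 (default 1).
#' @return `data.frame` with the input rows that passed, their clipped
#'   `residues`, `length_aa`, anchor positions on the original domain
#'   peptide and per-anchor mismatch counts. Attribute `n_excluded` counts
#'   the domains that did not span both anchors.
#' @export
extract_full_length <- function(calls, max_mismatch = 1L) {
  stopifnot(max_mismatch >= 0L, max_mismatch <= 2L)
  if (is.character(calls)) {
    calls <- data.frame(query_id = names(calls) %||% paste0("d", seq_along(calls)),
                        domain_seq = unname(calls), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(calls), "domain_seq" %in% names(calls))
  keep <- logical(nrow(calls))
  a_start <- a_end <- integer(nrow(calls))
  mm_start <- mm_end <- integer(nrow(calls))
  clipped <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$domain_seq[i]
    mm_s <- .anchor_mismatch_counts(s, ANCHOR_START)
    mm_e <- .anchor_mismatch_counts(s, ANCHOR_END)
    if (is.null(mm_s) || is.null(mm_e)) next
    ok_s <- which(mm_s <= max_mismatch)
    ok_e <- which(mm_e <= max_mismatch)
    if (!length(ok_s) || !length(ok_e)) next
    st <- ok_s[1]                       # leftmost qualifying start
    en <- ok_e[length(ok_e)]            # rightmost qualifying end
    # end anchor must begin after the start anchor ends
    if (en <= st + nchar(ANCHOR_START) - 1L) {
      # fall back to any spanning pair
      valid <- expand.grid(st = ok_s, en = ok_e)
      valid <- valid[valid$en > valid$st + nchar(ANCHOR_START) - 1L, , drop = FALSE]
      if (!nrow(valid)) next
      span <- valid$en - valid$st
      pick <- valid[which.max(span), ]
      st <- pick$st; en <- pick$en
    }
    keep[i] <- TRUE
    a_start[i] <- st; a_end[i] <- en
    mm_start[i] <- mm_s[st]; mm_end[i] <- mm_e[en]
    clipped[i] <- substr(s, st, en + nchar(ANCHOR_END) - 1L)
  }
  out <- calls[keep, , drop = FALSE]
  out$residues <- clipped[keep]
  out$length_aa <- nchar(out$residues)
  out$anchor_start_pos <- a_start[keep]
  out$anchor_end_pos <- a_end[keep]
  out$mismatches_start <- mm_start[keep]
  out$mismatches_end <- mm_end[keep]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
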