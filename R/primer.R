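.IUPAC_NT <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

#' Define a degenerate PCR primer
#'
#' @param name Primer name.
#' @param nt_sequence IUPAC nucleotide string, written 5' to 3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return List of class `ks_primer`.
#' @export
degenerate_primer <- function(name, nt_sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  nt_sequence <- toupper(nt_sequence)
  bad <- setdiff(unique(strsplit(nt_sequence, "")[[1]]), names(.IUPAC_NT))
  if (length(bad)) stop("non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, nt_sequence = nt_sequence, orientation = orientation),
            class = "ks_primer")
}

#' The widely used type I KS primer pair
#'
#' The forward primer 5'-GCNATGGAYCCNCARCARMGNVT-3' and reverse primer
#' 5'-GTNCNNGTNCCRTGNSCYTCNAC-3' used to amplify type I KS domains.
#'
#' @return Named list of two [degenerate_primer()] objects, `KS2F` and
#'   `KS2R`.
#' @export
ks2_primers <- function() {
  list(KS2F = degenerate_primer("KS2F", "GCNATGGAYCCNCARCARMGNVT", "forward"),
       KS2R = degenerate_primer("KS2R", "GTNCNNGTNCCRTGNSCYTCNAC", "reverse"))
}

#' Translate a degenerate primer into an amino acid pattern
#'
#' Forward primers are translated directly; reverse primers are
#' reverse-complemented first (so the pattern reads N- to C-terminal along
#' the coding strand). A trailing partial codon is right-padded with `N`.
#' Each degenerate codon expands to the set of amino acids encoded by its
#' concrete expansions, stop codons removed; a codon whose expansions are
#' all stops is an error.
#'
#' @param primer A [degenerate_primer()].
#' @return Object of class `ks_primer_pattern`: list with `name`,
#'   `orientation`, `positions` (list of amino acid character vectors,
#'   alphabetically sorted) and `padded` (was the final codon padded).
#' @export
translate_degenerate <- function(primer) {
  stopifnot(inherits(primer, "ks_primer"))
  nt <- primer$nt_sequence
  if (primer$orientation == "reverse") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  padded <- nchar(nt) %% 3L != 0L
  if (padded) nt <- paste0(nt, strrep("N", 3L - nchar(nt) %% 3L))
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  gc <- Biostrings::GENETIC_CODE
  positions <- lapply(codons, function(cod) {
    b <- strsplit(cod, "")[[1]]
    expansions <- as.vector(outer(outer(.IUPAC_NT[[b[1]]], .IUPAC_NT[[b[2]]], paste0),
                                  .IUPAC_NT[[b[3]]], paste0))
    aa <- unique(gc[expansions])
    aa <- setdiff(aa, "*")
    if (length(aa) == 0L) stop("codon ", cod, " encodes only stop codons")
    sort(aa)
  })
  structure(list(name = primer$name, orientation = primer$orientation,
                 positions = positions, padded = padded),
            class = "ks_primer_pattern")
}

#' Render an amino acid pattern as a compact string
#'
#' Single-residue positions print as the residue; degenerate positions as
#' the set in parentheses. Within parentheses residues follow this
#' package's canonical (alphabetical) order; use [normalize_pattern_string()]
#' to compare renderings that order sets differently.
#'
#' @param x A `ks_primer_pattern`.
#' @return Character scalar, e.g. `"AMDPQQ(RS)(ILMV)"`.
#' @export
format_pattern <- function(x) {
  stopifnot(inherits(x, "ks_primer_pattern"))
  paste(vapply(x$positions, function(p) {
    if (length(p) == 1L) p else paste0("(", paste(sort(p), collapse = ""), ")")
  }, character(1)), collapse = "")
}

#' @export
print.ks_primer_pattern <- function(x, ...) {
  cat(x$name, " (", x$orientation, "): ", format_pattern(x),
      if (x$padded) "  [final codon N-padded]" else "", "\n", sep = "")
  invisible(x)
}

#' Normalize a pattern string for order-insensitive comparison
#'
#' Parses a rendering like `"AMDPQQ(RS)(LIMV)"` into per-position residue
#' sets, sorts each set alphabetically and re-renders, so two renderings
#' that list set members in different orders compare equal.
#'
#' @param s Pattern string.
#' @return Canonicalized pattern string.
#' @export
normalize_pattern_string <- function(s) {
  toks <- regmatches(s, gregexpr("\\([A-Z]+\\)|[A-Z]", s))[[1]]
  paste(vapply(toks, function(t) {
    if (startsWith(t, "(")) {
      inner <- sort(strsplit(gsub("[()]", "", t), "")[[1]])
      paste0("(", paste(inner, collapse = ""), ")")
    } else t
  }, character(1)), collapse = "")
}

#' Locate the primer-encoded site on a KS domain
#'
#' Slides the amino acid pattern along the domain and returns the window
#' maximizing the number of positions whose domain residue belongs to the
#' position's set; ties resolve leftmost. Placements matching fewer than
#' half the positions are flagged low-confidence.
#'
#' @param pattern A `ks_primer_pattern`.
#' @param domain_residues Protein sequence (character scalar).
#' @return List: `pos` (1-based window start), `n_matched`,
#'   `low_confidence`.
#' @export
locate_primer_site <- function(pattern, domain_residues) {
  stopifnot(inherits(pattern, "ks_primer_pattern"))
  k <- length(pattern$positions)
  L <- nchar(domain_residues)
  if (k > L) stop("pattern (", k, " aa) longer than domain (", L, " aa)")
  sc <- strsplit(domain_residues, "", fixed = TRUE)[[1]]
  n_win <- L - k + 1L
  matched <- integer(n_win)
  for (j in seq_len(k)) {
    matched <- matched + as.integer(sc[seq.int(j, j + n_win - 1L)] %in% pattern$positions[[j]])
  }
  best <- which.max(matched)  # leftmost maximum
  list(pos = best, n_matched = matched[best],
       low_confidence = matched[best] < k / 2)
}

#' Per-position primer match profile by KS group
#'
#' For each group of domains, the pattern is placed on every domain with
#' [locate_primer_site()] and the fraction of domains whose residue at each
#' pattern position belongs to that position's amino acid set is reported,
#' together with the fraction matching at all positions simultaneously.
#' Positions are reported both in pattern (N- to C-terminal) order and as
#' offsets from the primer's 3' end: for a forward primer the last pattern
#' position is 3'-proximal, for a reverse primer the first is.
#'
#' @param pattern A `ks_primer_pattern`.
#' @param domains Named character vector of domain sequences.
#' @param groups Group label per domain (e.g. `ssn_group`); groups with no
#'   domains are omitted with a warning.
#' @return List of class `ks_match_profile`: per group, a list with
#'   `n_domains`, `position_fraction` (named by position),
#'   `offset_from_3prime` (integer per position), `full_match_fraction`,
#'   `n_low_confidence`.
#' @export
match_profile <- function(pattern, domains, groups) {
  stopifnot(length(domains) == length(groups))
  k <- length(pattern$positions)
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    seqs <- domains[groups == g]
    if (length(seqs) == 0L) { warning("empty group omitted: ", g); next }
    hit <- matrix(FALSE, length(seqs), k)
    low <- logical(length(seqs))
    for (i in seq_along(seqs)) {
      site <- locate_primer_site(pattern, seqs[[i]])
      res <- strsplit(substr(seqs[[i]], site$pos, site$pos + k - 1L), "")[[1]]
      hit[i, ] <- mapply(function(r, set) r %in% set, res, pattern$positions)
      low[i] <- site$low_confidence
    }
    off <- if (pattern$orientation == "forward") rev(seq_len(k)) else seq_len(k)
    out[[g]] <- list(n_domains = length(seqs),
                     position_fraction = stats::setNames(colMeans(hit), paste0("pos", seq_len(k))),
                     offset_from_3prime = stats::setNames(off, paste0("pos", seq_len(k))),
                     full_match_fraction = mean(rowSums(hit) == k),
                     n_low_confidence = sum(low))
  }
  structure(out, class = "ks_match_profile", pattern = format_pattern(pattern))
}

#' Enlarge amino acid sets of a primer pattern
#'
#' Models primer modifications that broaden codon degeneracy: the given
#' residues are added to the stated pattern positions, and re-running
#' [match_profile()] quantifies the coverage gain.
#'
#' @param pattern A `ks_primer_pattern`.
#' @param modifications Named list: names are pattern positions (integers as
#'   strings or integers via `list()` order), values character vectors of
#'   residues to add. Alternatively a list of `list(position=, add=)` pairs.
#' @return A new `ks_primer_pattern` with enlarged sets.
#' @export
apply_modification <- function(pattern, modifications) {
  stopifnot(inherits(pattern, "ks_primer_pattern"))
  for (m in modifications) {
    pos <- m$position
    add <- toupper(m$add)
    if (!is.numeric(pos) || pos < 1 || pos > length(pattern$positions)) {
      stop("invalid pattern position: ", pos)
    }
    bad <- setdiff(add, .PROTEIN_ALPHABET)
    if (length(bad)) stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
    pattern$positions[[pos]] <- sort(union(pattern$positions[[pos]], add))
  }
  pattern
}
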