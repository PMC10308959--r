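#' Alignment scoring parameters
#'
#' Substitution matrix plus affine gap penalties and the fixed gapped
#' Karlin-Altschul constants used to convert raw scores to bit scores and
#' E-values. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix Substitution matrix name understood by Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open Gap opening penalty (positive cost, default 11).
#' @param gap_extend Gap extension penalty per residue (default 1).
#' @param lambda,K Karlin-Altschul parameters for the gapped BLOSUM62
#'   (11/1) scoring system; bitscore = (lambda * raw - ln K) / ln 2.
#' @return List of class `ks_scoring`.
#' @export
ks_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  mat <- .get_submat(matrix)
  structure(list(matrix_name = matrix, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "ks_scoring")
}

.get_submat <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

.bitscore <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

.evalue <- function(bit, m, n) m * n * 2^(-bit)

# matches / columns with X never counting as a match; gaps count as columns
.identity_from_strings <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  matches <- sum(pc == sc & pc != "-" & pc != "X")
  c(matches = matches, columns = length(pc))
}

# vectorised match/column counts for a PairwiseAlignments object; fast
# nmatch/nchar path, falling back to aligned-string comparison only for
# pairs containing X (nmatch would count X:X columns as matches)
.pa_identity_stats <- function(pa, queries, subject) {
  cols <- Biostrings::nchar(pa)
  matches <- Biostrings::nmatch(pa)
  fix <- grepl("X", queries, fixed = TRUE) | grepl("X", subject, fixed = TRUE)
  if (any(fix)) {
    ap <- as.character(Biostrings::alignedPattern(pa[fix]))
    as_ <- as.character(Biostrings::alignedSubject(pa[fix]))
    matches[fix] <- vapply(seq_along(ap), function(t) {
      unname(.identity_from_strings(ap[t], as_[t])["matches"])
    }, numeric(1))
  }
  list(matches = matches, cols = cols)
}

.align_result <- function(pa, scoring, m, n, query, subject) {
  raw <- Biostrings::score(pa)
  st <- .pa_identity_stats(pa, query, subject)
  bit <- .bitscore(raw, scoring)
  pr <- methods::slot(pa, "pattern")
  sr <- methods::slot(pa, "subject")
  list(raw_score = raw,
       bitscore = bit,
       evalue = .evalue(bit, m, n),
       identity_fraction = st$matches / st$cols,
       aln_columns = st$cols,
       q_start = Biostrings::start(pr), q_end = Biostrings::end(pr),
       s_start = Biostrings::start(sr), s_end = Biostrings::end(sr))
}

.check_protein_pair <- function(query, subject) {
  if (length(query) != 1L || length(subject) != 1L ||
      !nzchar(query) || !nzchar(subject)) {
    stop("alignment requires two non-empty protein sequences")
  }
  .check_alphabet(c(query, subject), "protein")
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Affine-gap local alignment of two protein sequences with statistics:
#' raw score, bit score and E-value under fixed Karlin-Altschul constants,
#' identity fraction (matches / alignment columns, gap columns included,
#' `X` never matching) and 1-based inclusive coordinates on both sequences.
#'
#' @param query,subject Protein sequences (character scalars).
#' @param scoring A [ks_scoring()] object.
#' @param search_space_n Effective database length for the E-value; defaults
#'   to `nchar(subject)` so a single pairwise E-value is self-contained.
#' @return List with `raw_score`, `bitscore`, `evalue`, `identity_fraction`,
#'   `aln_columns`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
align_local <- function(query, subject, scoring = ks_scoring(),
                        search_space_n = nchar(subject)) {
  .check_protein_pair(query, subject)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local")
  .align_result(pa, scoring, m = nchar(query), n = search_space_n,
                query = query, subject = subject)
}

#' Optimal global (Needleman-Wunsch) protein alignment
#'
#' @inheritParams align_local
#' @return Same structure as [align_local()].
#' @export
align_global <- function(query, subject, scoring = ks_scoring(),
                         search_space_n = nchar(subject)) {
  .check_protein_pair(query, subject)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  .align_result(pa, scoring, m = nchar(query), n = search_space_n,
                query = query, subject = subject)
}

#' Global pairwise amino acid identity
#'
#' Identity fraction between two protein sequences under global alignment:
#' matched columns divided by total alignment columns (gap columns count in
#' the denominator; `X` never matches).
#'
#' @inheritParams align_local
#' @return Fraction in \[0, 1\].
#' @export
global_identity <- function(a, b, scoring = ks_scoring()) {
  align_global(a, b, scoring)$identity_fraction
}

# vectorised: global identities of one sequence against many (used by the
# greedy clusterer); returns numeric vector aligned with `pool`
.global_identity_many <- function(seq, pool, scoring = ks_scoring()) {
  if (length(pool) == 0L) return(numeric(0))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(pool)), Biostrings::AAString(seq),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  st <- .pa_identity_stats(pa, pool, seq)
  st$matches / st$cols
}
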