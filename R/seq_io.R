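#' Read a FASTA file into a named character vector
#'
#' Thin validated wrapper around [Biostrings::readBStringSet()]. Record order
#' is preserved; the name of each element is the first whitespace-delimited
#' token of the header and the full header is kept in the `"description"`
#' attribute. Duplicate ids, records with empty sequences and leading
#' non-header content are rejected with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"`, `"protein"` or `"auto"` (default): checked
#'   against the residues actually present.
#' @return Named character vector of residues (upper case), with a
#'   `description` attribute (full headers) and an `alphabet` attribute.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("parse error in ", path, ": no FASTA header found")
  pre <- which(nzchar(trimws(lines[seq_len(hdr[1] - 1)])))
  if (length(pre)) {
    stop("parse error in ", path, " at line ", pre[1],
         ": content before first FASTA header")
  }
  bad_hdr <- hdr[!grepl("^>\\S", lines[hdr])]
  if (length(bad_hdr)) {
    stop("parse error in ", path, " at line ", bad_hdr[1], ": malformed header")
  }
  # empty record = header immediately followed by header/EOF or blank body
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[seq2(hdr[k] + 1L, ends[k])]
    if (sum(nchar(gsub("\\s", "", body))) == 0L) {
      stop("parse error in ", path, " at line ", hdr[k],
           ": record with empty sequence")
    }
  }
  set <- Biostrings::readBStringSet(path)
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  obs <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]))
  is_nt <- all(obs %in% .NT_IUPAC)
  is_aa <- all(obs %in% c(.PROTEIN_ALPHABET, "X", "*"))
  if (alphabet == "auto") {
    alphabet <- if (is_nt) "nucleotide" else if (is_aa) "protein" else
      stop("residues in ", path, " match neither the IUPAC nucleotide nor the protein alphabet")
  } else if (alphabet == "nucleotide" && !is_nt) {
    stop("non-nucleotide residues found in ", path)
  } else if (alphabet == "protein" && !is_aa) {
    stop("non-protein residues found in ", path)
  }
  attr(seqs, "description") <- desc
  attr(seqs, "alphabet") <- alphabet
  seqs
}

# base::seq with from > to yielding integer(0)
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Drop contigs shorter than a nucleotide length floor
#'
#' Mirrors the standard pre-filter applied to assembled metagenomes before
#' domain detection: contigs shorter than `min_nt` nucleotides are excluded.
#' The boundary is inclusive — a contig of exactly `min_nt` is kept.
#'
#' @param records Named character vector of nucleotide sequences.
#' @param min_nt Minimum retained length in nucleotides (default 600).
#' @return The retained records, input order preserved.
#' @export
filter_contigs <- function(records, min_nt = 600L) {
  stopifnot(min_nt >= 0)
  .check_alphabet(records, "nucleotide")
  records[nchar(records) >= min_nt]
}

.check_alphabet <- function(seqs, what = c("nucleotide", "protein")) {
  what <- match.arg(what)
  if (length(seqs) == 0L) return(invisible(TRUE))
  obs <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  ok <- if (what == "nucleotide") obs %in% .NT_IUPAC else obs %in% c(.PROTEIN_ALPHABET, "X", "*")
  if (!all(ok)) {
    stop("expected ", what, " sequences; offending residue(s): ",
         paste(obs[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all six reading frames with the standard genetic code, splits
#' the translations at stop codons, and returns every resulting peptide of
#' length at least `min_peptide_aa`. Ambiguous codons translate to the amino
#' acid shared by all of their expansions, or `X` when the expansions
#' disagree. Peptide ids encode the source id, the frame (`+1..+3`,
#' `-1..-3`) and the 1-based position, on the forward strand, of the first
#' base of the peptide's first codon.
#'
#' @param record Single named nucleotide sequence (named character of
#'   length 1).
#' @param min_peptide_aa Minimum peptide length to report.
#' @return Named character vector of peptides (possibly empty).
#' @export
six_frame_translate <- function(record, min_peptide_aa = 50L) {
  stopifnot(length(record) == 1L)
  .check_alphabet(record, "nucleotide")
  id <- if (!is.null(names(record))) names(record) else "query"
  nt <- chartr("U", "T", toupper(record[[1]]))
  L <- nchar(nt)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  out <- character(0)
  for (strand in c(1L, -1L)) {
    src <- if (strand == 1L) fwd else rev
    for (f in 1:3) {
      n_cod <- (L - f + 1L) %/% 3L
      if (n_cod < 1L) next
      frame_seq <- Biostrings::subseq(src, f, f + 3L * n_cod - 1L)
      aa <- as.character(Biostrings::translate(frame_seq, if.fuzzy.codon = "solve"))
      # split at stops; record 1-based aa offset of each fragment
      frags <- strsplit(aa, "*", fixed = TRUE)[[1]]
      offs <- cumsum(c(1L, nchar(frags[-length(frags)]) + 1L))
      keep <- nchar(frags) >= min_peptide_aa
      for (k in which(keep)) {
        aa_start <- offs[k]                      # within-frame codon index
        cod_pos <- f + 3L * (aa_start - 1L)      # on translated strand
        fwd_pos <- if (strand == 1L) cod_pos else L - cod_pos + 1L
        nm <- sprintf("%s|frame=%+d|start=%d", id, strand * f, fwd_pos)
        out[nm] <- frags[k]
      }
    }
  }
  out
}

#' Read a 12-column tabular homology hit table
#'
#' Parses the conventional 12-column tab-separated search output layout
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, E-value, bit score),
#' allowing externally computed search results to substitute for the
#' built-in aligner.
#'
#' @param path Path to the tab-separated file (no header).
#' @return `data.frame` with typed columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop("parse error in ", path, " at line ", bad, ": expected 12 columns, found ",
         nf[bad])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  num_bad <- which(is.na(hits$evalue) | is.na(hits$bitscore) |
                     is.na(hits$aln_length) | is.na(hits$pct_identity))
  if (length(num_bad)) {
    stop("parse error in ", path, " at line ", num_bad[1],
         ": non-numeric value in a numeric column")
  }
  if (any(hits$evalue < 0)) stop("negative E-value in ", path)
  if (any(hits$aln_length < 1L)) stop("alignment length < 1 in ", path)
  if (any(hits$q_start > hits$q_end)) {
    stop("q_start > q_end in ", path, " (protein query coordinates must be ascending)")
  }
  hits
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a metagenome manifest
#'
#' Tab-separated file with a header row and columns `metagenome_id`, `biome`
#' and `size_gbp` (assembly size in gigabase pairs).
#'
#' @param path Path to the manifest.
#' @return `data.frame` with those three columns.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metagenome_id", "biome", "size_gbp")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$metagenome_id)) stop("duplicate metagenome_id in ", path)
  man$size_gbp <- as.numeric(man$size_gbp)
  if (any(!is.finite(man$size_gbp)) || any(man$size_gbp <= 0)) {
    stop("size_gbp must be positive and numeric in ", path)
  }
  man[need]
}
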