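#' Assemble and validate a labeled KS reference collection
#'
#' The reference collection drives both detection (top-hit classification)
#' and taxonomy (closest-match phylum). Each entry carries a leaf-level KS
#' class from the 11-class vocabulary; the coarser `group_label` and
#' `ssn_group` columns are derived from the leaf and checked for
#' consistency if supplied.
#'
#' @param id,residues,leaf_label,phylum Parallel character vectors.
#' @return `data.frame` of class `ks_refdb` with columns `id`, `residues`,
#'   `leaf_label`, `group_label`, `ssn_group`, `phylum`.
#' @export
ks_refdb <- function(id, residues, leaf_label, phylum) {
  stopifnot(length(id) == length(residues),
            length(id) == length(leaf_label),
            length(id) == length(phylum))
  if (length(id) == 0L) stop("reference collection must be non-empty")
  if (anyDuplicated(id)) stop("duplicate reference ids")
  bad <- setdiff(unique(leaf_label), ks_leaf_vocabulary())
  if (length(bad)) stop("unknown leaf label(s): ", paste(bad, collapse = ", "))
  .check_alphabet(residues, "protein")
  db <- data.frame(id = as.character(id), residues = as.character(residues),
                   leaf_label = as.character(leaf_label),
                   group_label = .leaf_group(leaf_label),
                   ssn_group = .leaf_ssn(leaf_label),
                   phylum = as.character(phylum), stringsAsFactors = FALSE)
  class(db) <- c("ks_refdb", "data.frame")
  db
}

#' Read a reference collection from FASTA + metadata
#'
#' @param fasta_path FASTA of reference KS domain sequences.
#' @param metadata_path Tab-separated metadata with header and columns `id`,
#'   `leaf_label`, `phylum` (extra columns ignored); every FASTA id must be
#'   present.
#' @return A `ks_refdb`.
#' @export
read_reference_db <- function(fasta_path, metadata_path) {
  seqs <- read_fasta(fasta_path, alphabet = "protein")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("id", "leaf_label", "phylum")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("reference metadata lacks column(s): ", paste(miss, collapse = ", "))
  i <- match(names(seqs), meta$id)
  if (anyNA(i)) {
    stop("reference sequence(s) without metadata: ",
         paste(names(seqs)[is.na(i)], collapse = ", "))
  }
  ks_refdb(names(seqs), unname(seqs), meta$leaf_label[i], meta$phylum[i])
}

#' Write a reference collection to FASTA + metadata
#'
#' @param refdb A `ks_refdb`.
#' @param fasta_path,metadata_path Output paths.
#' @export
write_reference_db <- function(refdb, fasta_path, metadata_path) {
  stopifnot(inherits(refdb, "ks_refdb"))
  write_fasta(stats::setNames(refdb$residues, refdb$id), fasta_path)
  utils::write.table(refdb[c("id", "leaf_label", "group_label", "ssn_group", "phylum")],
                     metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(refdb)
}
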