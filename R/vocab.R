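#' Type I KS classification vocabulary
#'
#' The eleven leaf-level KS domain classes used throughout the package,
#' together with their aggregation into coarser groups. `group_label` is the
#' three-group (+ FAS) scheme (cis-AT, trans-AT, iterative cis-AT, FAS);
#' `ssn_group` is the five-cluster scheme seen in sequence similarity
#' networks of full-length type I KS domains (cis-AT/iterative, hybrid
#' cis-AT, trans-AT, PUFA, enediyne) plus FAS.
#'
#' @return Character vector of the 11 leaf labels.
#' @export
ks_leaf_vocabulary <- function() {
  c("modular cis-AT", "cis-loading module", "olefin synthase",
    "iterative aromatic", "iterative PTM", "trans-AT", "hybrid trans-AT",
    "hybrid cis-AT", "PUFA", "enediyne", "FAS")
}

# leaf -> (group_label, ssn_group); total and fixed
.ks_group_table <- data.frame(
  leaf_label = c("modular cis-AT", "cis-loading module", "olefin synthase",
                 "iterative aromatic", "iterative PTM", "trans-AT",
                 "hybrid trans-AT", "hybrid cis-AT", "PUFA", "enediyne",
                 "FAS"),
  group_label = c("cis-AT", "cis-AT", "cis-AT",
                  "iterative cis-AT", "iterative cis-AT", "trans-AT",
                  "trans-AT", "cis-AT", "iterative cis-AT",
                  "iterative cis-AT", "FAS"),
  ssn_group = c("cis-AT/iterative", "cis-AT/iterative", "cis-AT/iterative",
                "cis-AT/iterative", "cis-AT/iterative", "trans-AT",
                "trans-AT", "hybrid cis-AT", "PUFA", "enediyne", "FAS"),
  stringsAsFactors = FALSE
)

#' Map a leaf-level KS class to its group and SSN-cluster labels
#'
#' Deterministic total mapping over the 11-class vocabulary: the modular,
#' loading, olefin synthase, iterative aromatic and iterative PTM classes all
#' fall in the cis-AT/iterative SSN cluster; hybrid trans-AT maps with
#' trans-AT; PUFA, enediyne and hybrid cis-AT form their own clusters; FAS
#' passes through.
#'
#' @param leaf_label One of [ks_leaf_vocabulary()].
#' @return Named list with `group_label` and `ssn_group`.
#' @export
map_leaf <- function(leaf_label) {
  stopifnot(is.character(leaf_label), length(leaf_label) == 1L)
  i <- match(leaf_label, .ks_group_table$leaf_label)
  if (is.na(i)) {
    stop("unknown KS leaf label: '", leaf_label, "' (not in the 11-class vocabulary)")
  }
  list(group_label = .ks_group_table$group_label[i],
       ssn_group = .ks_group_table$ssn_group[i])
}

# vectorised internal versions
.leaf_group <- function(leaf) .ks_group_table$group_label[match(leaf, .ks_group_table$leaf_label)]
.leaf_ssn <- function(leaf) .ks_group_table$ssn_group[match(leaf, .ks_group_table$leaf_label)]

.PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                       "M","N","P","Q","R","S","T","V","W","Y")
.NT_IUPAC <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N")
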