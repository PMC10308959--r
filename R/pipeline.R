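#' Pipeline configuration
#'
#' Collects every numeric parameter of the survey pipeline in one place,
#' with the conventional defaults: 600-nt contig floor, 200-aa minimum
#' match and 1e-30 E-value ceiling for detection, OBU thresholds
#' 0.70/0.80/0.90/0.95, rarefaction depths 100 (composition) and 580
#' (richness), 1000/999 permutations, 10 Chao1 replicates, 138-aa amplicon
#' trim and 1 anchor mismatch.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param min_nt,min_match_aa,max_evalue,obu_thresholds Detection/clustering
#'   parameters.
#' @param composition_depth,composition_permutations Rarefied-composition
#'   parameters.
#' @param richness_depth,chao1_replicates Richness parameters.
#' @param permanova_permutations PERMANOVA permutation count.
#' @param trim_length_aa,trimmed_min_match_aa Amplicon-concordance
#'   parameters.
#' @param anchor_max_mismatch Full-length anchor mismatch tolerance.
#' @param n_metagenomes_per_biome,n_sequences_per_metagenome Synthetic run
#'   sizes used by the `simulate` stage.
#' @param profiles Biome profiles for simulation (default
#'   [default_biome_profiles()]).
#' @param refdb Reference collection (default [synthetic_reference_db()]).
#' @return List of class `ks_pipeline_config`.
#' @export
ks_pipeline_config <- function(out_dir = tempfile("ks_run_"), seed = 1L,
                               min_nt = 600L, min_match_aa = 200L,
                               max_evalue = 1e-30,
                               obu_thresholds = c(0.70, 0.80, 0.90, 0.95),
                               composition_depth = 100L,
                               composition_permutations = 1000L,
                               richness_depth = 580L, chao1_replicates = 10L,
                               permanova_permutations = 999L,
                               trim_length_aa = 138L,
                               trimmed_min_match_aa = 100L,
                               anchor_max_mismatch = 1L,
                               n_metagenomes_per_biome = 2L,
                               n_sequences_per_metagenome = 120L,
                               profiles = NULL, refdb = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), min_nt = min_nt,
              min_match_aa = min_match_aa, max_evalue = max_evalue,
              obu_thresholds = obu_thresholds,
              composition_depth = composition_depth,
              composition_permutations = composition_permutations,
              richness_depth = richness_depth,
              chao1_replicates = chao1_replicates,
              permanova_permutations = permanova_permutations,
              trim_length_aa = trim_length_aa,
              trimmed_min_match_aa = trimmed_min_match_aa,
              anchor_max_mismatch = anchor_max_mismatch,
              n_metagenomes_per_biome = n_metagenomes_per_biome,
              n_sequences_per_metagenome = n_sequences_per_metagenome,
              profiles = profiles, refdb = refdb)
  num <- cfg[c("min_nt", "min_match_aa", "composition_depth",
               "composition_permutations", "richness_depth",
               "chao1_replicates", "permanova_permutations",
               "trim_length_aa", "trimmed_min_match_aa")]
  if (any(unlist(num) <= 0)) stop("all size/threshold parameters must be positive")
  class(cfg) <- "ks_pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the survey pipeline
#'
#' Orchestrates the stages in analysis order on synthetic biome-structured
#' data: `simulate` (generate metagenomes + manifest), `classify` (domain
#' detection/classification + phylum assignment), `fulllength` (anchor
#' extraction), `diversity` (rarefied Chao1 per biome), `shared`
#' (shared-OBU pairwise counts), `composition` (rarefied profiles,
#' Bray-Curtis, PCoA, PERMANOVA), `primer_eval` (KS2F/KS2R match profiles)
#' and `trim_concordance`. `"all"` chains every stage. Each stage writes
#' tab-separated tables (and JSON summaries) under `cfg$out_dir`, plus a
#' `manifest.json` recording all parameter values and the seed, so a run is
#' reproducible end to end.
#'
#' @param cfg A [ks_pipeline_config()].
#' @param stages Character vector of stage names or `"all"`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_ks_pipeline <- function(cfg = ks_pipeline_config(), stages = "all") {
  stopifnot(inherits(cfg, "ks_pipeline_config"))
  all_stages <- c("simulate", "classify", "fulllength", "diversity", "shared",
                  "composition", "primer_eval", "trim_concordance")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  refdb <- cfg$refdb %||% synthetic_reference_db()
  profiles <- cfg$profiles %||% default_biome_profiles()
  res <- list()
  state_file <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, stage) {
    p <- state_file(f)
    if (!file.exists(p)) {
      stop("stage '", stage, "' requires missing artifact: ", p,
           " (run the producing stage first)")
    }
    p
  }

  if ("simulate" %in% stages) {
    set.seed(cfg$seed)
    recs <- character(0); truth <- list(); man <- list()
    k <- 0L
    for (pf in profiles) {
      for (m in seq_len(cfg$n_metagenomes_per_biome)) {
        k <- k + 1L
        mg_id <- sprintf("MG%03d", k)
        g <- generate_biome(pf, cfg$n_sequences_per_metagenome, refdb,
                            id_prefix = mg_id)
        recs <- c(recs, g$records)
        g$truth$metagenome_id <- mg_id
        truth[[k]] <- g$truth
        man[[k]] <- data.frame(metagenome_id = mg_id, biome = pf$biome,
                               size_gbp = round(stats::runif(1, 0.5, 3), 3),
                               stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    manifest <- do.call(rbind, man)
    write_fasta(recs, state_file("simulated_peptides.fasta"))
    .write_tsv(truth, state_file("truth.tsv"))
    .write_tsv(manifest, state_file("sample_manifest.tsv"))
    res$simulate <- list(records = recs, truth = truth, manifest = manifest)
  }

  if ("classify" %in% stages) {
    if (is.null(res$simulate)) {
      recs <- read_fasta(need("simulated_peptides.fasta", "classify"),
                         alphabet = "protein")
      truth <- utils::read.delim(state_file("truth.tsv"), stringsAsFactors = FALSE)
    } else {
      recs <- res$simulate$records; truth <- res$simulate$truth
    }
    calls <- classify_domains(recs, refdb, min_match_aa = cfg$min_match_aa,
                              max_evalue = cfg$max_evalue)
    calls <- assign_phylum(calls, refdb)
    calls$metagenome_id <- truth$metagenome_id[match(calls$query_id, truth$id)]
    calls$biome <- truth$biome[match(calls$query_id, truth$id)]
    .write_tsv(calls, state_file("domain_calls.tsv"))
    res$classify <- calls
  }

  get_calls <- function(stage) {
    if (!is.null(res$classify)) return(res$classify)
    utils::read.delim(need("domain_calls.tsv", stage), stringsAsFactors = FALSE)
  }

  if ("fulllength" %in% stages) {
    calls <- get_calls("fulllength")
    fl <- extract_full_length(calls, max_mismatch = cfg$anchor_max_mismatch)
    fl$id <- fl$query_id
    .write_tsv(fl[c("id", "biome", "leaf_label", "length_aa",
                    "mismatches_start", "mismatches_end", "residues")],
               state_file("full_length_domains.tsv"))
    message(attr(fl, "n_excluded"), " domain(s) did not span both anchors")
    res$fulllength <- fl
  }

  get_fl <- function(stage) {
    if (!is.null(res$fulllength)) return(res$fulllength)
    utils::read.delim(need("full_length_domains.tsv", stage),
                      stringsAsFactors = FALSE)
  }

  if ("diversity" %in% stages) {
    fl <- get_fl("diversity")
    rich <- richness_by_biome(fl, thresholds = cfg$obu_thresholds,
                              depth = cfg$richness_depth,
                              replicates = cfg$chao1_replicates,
                              seed = cfg$seed)
    .write_tsv(rich, state_file("richness.tsv"))
    res$diversity <- rich
  }

  if ("shared" %in% stages) {
    fl <- get_fl("shared")
    sh <- shared_obus(fl, thresholds = cfg$obu_thresholds,
                      depth = min(cfg$richness_depth, min(table(fl$biome))),
                      seed = cfg$seed)
    .write_tsv(sh, state_file("shared_obus.tsv"))
    res$shared <- sh
  }

  if ("composition" %in% stages) {
    calls <- get_calls("composition")
    manifest <- if (!is.null(res$simulate)) res$simulate$manifest else
      read_manifest(need("sample_manifest.tsv", "composition"))
    # per-Gbp abundance of each leaf class, plus ANOVA + Tukey across biomes
    counts <- composition_counts(calls)
    gbp <- manifest$size_gbp[match(rownames(counts), manifest$metagenome_id)]
    per_gbp <- t(vapply(seq_len(nrow(counts)), function(i) {
      ks_per_gbp(counts[i, ], gbp[i])
    }, numeric(ncol(counts))))
    rownames(per_gbp) <- rownames(counts)
    .write_tsv(data.frame(metagenome_id = rownames(per_gbp), per_gbp,
                          check.names = FALSE), state_file("ks_per_gbp.tsv"))
    biome_of_mg <- manifest$biome[match(rownames(per_gbp), manifest$metagenome_id)]
    tukey <- list()
    for (leaf in colnames(per_gbp)) {
      fitw <- tryCatch(anova_tukey(per_gbp[, leaf], biome_of_mg),
                       error = function(e) NULL)
      if (is.null(fitw)) next
      tukey[[length(tukey) + 1L]] <- data.frame(
        leaf_label = leaf, F = fitw$F, p_value = fitw$p_value,
        n_flagged_pairs = sum(fitw$pairs$flagged), stringsAsFactors = FALSE)
    }
    if (length(tukey)) {
      .write_tsv(do.call(rbind, tukey), state_file("abundance_anova.tsv"))
    }
    comp <- rarefied_composition(calls, depth = cfg$composition_depth,
                                 permutations = cfg$composition_permutations,
                                 seed = cfg$seed)
    d <- bray_curtis(comp)
    ord <- pcoa(d)
    biome_of <- calls$biome[match(rownames(comp), calls$metagenome_id)]
    pn <- permanova(d, biome_of, permutations = cfg$permanova_permutations,
                    seed = cfg$seed)
    .write_tsv(data.frame(metagenome_id = rownames(comp), comp,
                          check.names = FALSE), state_file("composition.tsv"))
    .write_tsv(data.frame(id = rownames(d), d, check.names = FALSE),
               state_file("bray_curtis.tsv"))
    coords <- data.frame(metagenome_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE)
    .write_tsv(coords, state_file("pcoa_coordinates.tsv"))
    jsonlite::write_json(list(pseudo_F = pn$pseudo_F, R2 = pn$R2,
                              p_value = pn$p_value,
                              n_permutations = pn$n_permutations),
                         state_file("permanova.json"), auto_unbox = TRUE,
                         digits = NA)
    res$composition <- list(matrix = comp, dist = d, pcoa = ord,
                            permanova = pn, per_gbp = per_gbp)
  }

  if ("primer_eval" %in% stages) {
    calls <- get_calls("primer_eval")
    pats <- lapply(ks2_primers(), translate_degenerate)
    profs <- lapply(pats, function(p) {
      match_profile(p, stats::setNames(calls$domain_seq, calls$query_id),
                    calls$ssn_group)
    })
    tab <- do.call(rbind, lapply(names(profs), function(nm) {
      do.call(rbind, lapply(names(profs[[nm]]), function(g) {
        pr <- profs[[nm]][[g]]
        data.frame(primer = nm, group = g, position = seq_along(pr$position_fraction),
                   offset_from_3prime = unname(pr$offset_from_3prime),
                   match_fraction = unname(pr$position_fraction),
                   full_match_fraction = pr$full_match_fraction,
                   n_domains = pr$n_domains, stringsAsFactors = FALSE)
      }))
    }))
    .write_tsv(tab, state_file("primer_profiles.tsv"))
    res$primer_eval <- profs
  }

  if ("trim_concordance" %in% stages) {
    fl <- get_fl("trim_concordance")
    curve <- trim_concordance_curve(
      fl, refdb, lengths = unique(c(max(fl$length_aa), cfg$trim_length_aa)),
      min_match_aa_trimmed = cfg$trimmed_min_match_aa,
      max_evalue = cfg$max_evalue)
    .write_tsv(curve, state_file("trim_concordance.tsv"))
    res$trim_concordance <- curve
  }

  par <- unclass(cfg)[setdiff(names(cfg), c("profiles", "refdb"))]
  jsonlite::write_json(
    list(package = "pksurvey",
         version = as.character(utils::packageVersion("pksurvey")),
         stages = stages, parameters = par,
         timestamp = format(Sys.time(), tz = "UTC")),
    state_file("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
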