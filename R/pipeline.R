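# One-call orchestration: preprocessing -> alpha diversity -> NTI -> QPE
# (betaNTI + RC-bray) -> NST (+ PANOVA) -> lottery. All stage seeds are
# derived from one global seed via stage_seed(), so outputs are fully
# reproducible and adding a stage never perturbs earlier stages.

#' Run the full community-assembly analysis
#'
#' Inputs may be in-memory objects or file paths (TSV/Newick, read with the
#' package readers). The pipeline validates cross-references, removes
#' contaminant lineages, rarefies to a common depth, then computes rarefied
#' richness and Shannon entropy, NTI, the QPE classification per group, NST
#' (both metrics x both constraints) per `nst_grouping` category with a
#' pooled PANOVA between categories, and the competitive lottery summary per
#' category. Per-stage timings are reported as messages.
#'
#' @param table an `asv_table` or path to an abundance TSV.
#' @param tree an `ape::phylo` or path to a Newick file.
#' @param taxonomy a `taxonomy_map` or path to a taxonomy TSV.
#' @param metadata a metadata `data.frame` or path to a metadata TSV.
#' @param seed integer global seed (required).
#' @param out_dir optional directory for the report bundle (TSVs, JSON
#'   summary, run manifest).
#' @param depth rarefaction depth or `"min"`.
#' @param reps randomisations for NTI/betaNTI/RC (default 999).
#' @param nst_reps null tables for NST (default 1000).
#' @param permutations PANOVA label permutations (default 999).
#' @param grouping metadata columns defining QPE/lottery categories
#'   (default position + nucleic_acid).
#' @param nst_grouping metadata column defining NST categories (default
#'   position).
#' @param bnti_threshold,rc_threshold QPE thresholds (defaults 2, 0.95).
#' @param lottery_rank,lottery_threshold,lottery_min_reads lottery settings
#'   (defaults family, 0.90, 10).
#' @param contaminants lineage labels removed before analysis.
#' @return A list with elements `table` (processed), `alpha`, `nti`,
#'   `qpe_pairs`, `qpe_summary`, `nst`, `panova`, `lottery`,
#'   `winner_changes`, `manifest` (and `paths` when written).
#' @export
run_pipeline <- function(table, tree, taxonomy, metadata, seed,
                         out_dir = NULL, depth = "min",
                         reps = 999L, nst_reps = 1000L, permutations = 999L,
                         grouping = c("position", "nucleic_acid"),
                         nst_grouping = "position",
                         bnti_threshold = 2, rc_threshold = 0.95,
                         lottery_rank = "family", lottery_threshold = 0.90,
                         lottery_min_reads = 10L,
                         contaminants = c("Chloroplast", "Mitochondria")) {
  if (missing(seed) || is.null(seed))
    ma_stop("validation_error", "a global seed is required")
  if (is.character(table)) table <- read_abundance_table(table)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- validate_metadata(metadata)

  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- code
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  validate_crossrefs(table, tree = tree, taxonomy = taxonomy,
                     metadata = metadata)

  table <- stage("preprocess", {
    filtered <- filter_contaminants(table, taxonomy, labels = contaminants)
    rarefy(filtered, depth = depth, seed = stage_seed(seed, "rarefy"))
  })

  alpha <- stage("alpha_diversity", {
    data.frame(sample_id = sample_ids(table),
               richness = vapply(sample_ids(table),
                                 function(s) richness(table, s), integer(1)),
               shannon = vapply(sample_ids(table),
                                function(s) shannon_entropy(table, s),
                                numeric(1)),
               row.names = NULL)
  })

  nti_res <- stage("nti", nti(table, tree, reps = reps,
                              seed = stage_seed(seed, "nti")))

  config <- qpe_config(bnti_threshold = bnti_threshold,
                       rc_threshold = rc_threshold, reps = reps,
                       seed = stage_seed(seed, "qpe"))
  qpe_pairs <- stage("qpe", qpe(table, tree, metadata, grouping = grouping,
                                config = config))
  qpe_sum <- qpe_summary(qpe_pairs)

  nst_groups <- group_assignment(table, metadata, nst_grouping)
  nst_res <- list()
  panova_res <- list()
  stage("nst", {
    for (metric in c("jaccard", "ruzicka")) {
      for (constraint in c("PP", "PF")) {
        for (g in names(nst_groups)) {
          key <- paste(metric, constraint, g, sep = ".")
          nst_res[[key]] <- stochasticity(
            table, metric = metric, constraint = constraint,
            reps = nst_reps, seed = stage_seed(seed, paste0("nst_", key)),
            group = nst_groups[[g]])
        }
        # pooled run across categories for the permutation test
        key <- paste(metric, constraint, sep = ".")
        pooled <- stochasticity(table, metric = metric,
                                constraint = constraint, reps = nst_reps,
                                seed = stage_seed(seed, paste0("nst_pool_", key)))
        glab <- stats::setNames(
          metadata[[nst_grouping]][match(sample_ids(table),
                                         metadata$sample_id)],
          sample_ids(table))
        panova_res[[key]] <- panova(pooled$pairs, glab,
                                     permutations = permutations,
                                     seed = stage_seed(seed, paste0("panova_", key)))
      }
    }
    NULL
  })

  lottery_res <- stage("lottery", {
    clades <- build_clades(taxonomy, rank = lottery_rank)
    cats <- group_assignment(table, metadata, grouping)
    per_cat <- lapply(cats, function(samp)
      detect_winners(subset_table(table, samples = samp), clades,
                     threshold = lottery_threshold,
                     min_clade_reads = lottery_min_reads))
    list(overall = detect_winners(table, clades,
                                  threshold = lottery_threshold,
                                  min_clade_reads = lottery_min_reads),
         per_category = per_cat)
  })
  winner_changes <- winner_status_changes(lottery_res$per_category)

  manifest <- list(
    package = "microassembly",
    version = as.character(utils::packageVersion("microassembly")),
    seed = seed,
    settings = list(depth = depth, reps = reps, nst_reps = nst_reps,
                    permutations = permutations, grouping = grouping,
                    nst_grouping = nst_grouping,
                    bnti_threshold = bnti_threshold,
                    rc_threshold = rc_threshold,
                    lottery_rank = lottery_rank,
                    lottery_threshold = lottery_threshold,
                    lottery_min_reads = lottery_min_reads))

  out <- list(table = table, alpha = alpha, nti = nti_res,
              qpe_pairs = qpe_pairs, qpe_summary = qpe_sum, nst = nst_res,
              panova = panova_res, lottery = lottery_res,
              winner_changes = winner_changes, manifest = manifest)
  if (!is.null(out_dir)) out$paths <- write_report_bundle(out, out_dir)
  out
}

# Write every pipeline product as TSV/JSON under out_dir; returns the paths.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_result_tsv(res$alpha, p("alpha_diversity.tsv"))
  write_result_tsv(res$nti, p("nti.tsv"))
  write_result_tsv(res$qpe_pairs, p("qpe_pairs.tsv"))
  write_result_tsv(res$qpe_summary, p("qpe_summary.tsv"))
  nst_pairs <- do.call(rbind, lapply(names(res$nst), function(k) {
    x <- res$nst[[k]]
    data.frame(run = k, metric = x$metric, constraint = x$constraint,
               x$pairs, row.names = NULL)
  }))
  write_result_tsv(nst_pairs, p("nst_pairs.tsv"))
  nst_sum <- data.frame(
    run = names(res$nst),
    nst_mean = vapply(res$nst, function(x) x$group_nst, numeric(1)),
    n_pairs = vapply(res$nst, function(x) nrow(x$pairs), integer(1)),
    row.names = NULL)
  write_result_tsv(nst_sum, p("nst_summary.tsv"))
  panova_tab <- data.frame(
    run = names(res$panova),
    statistic = vapply(res$panova, function(x) x$statistic, numeric(1)),
    p_value = vapply(res$panova, function(x) x$p_value, numeric(1)),
    row.names = NULL)
  write_result_tsv(panova_tab, p("panova.tsv"))
  write_result_tsv(res$lottery$overall$calls, p("lottery_calls.tsv"))
  write_result_tsv(lottery_summary(res$lottery$overall), p("lottery_summary.tsv"))
  write_result_tsv(res$winner_changes, p("lottery_winner_changes.tsv"))
  summary_json <- list(
    n_taxa = length(taxon_ids(res$table)),
    n_samples = length(sample_ids(res$table)),
    depth = unname(sample_totals(res$table)[1L]),
    nti_mean = mean(res$nti$nti, na.rm = TRUE),
    qpe = split(res$qpe_summary$fraction, res$qpe_summary$group),
    nst_mean = stats::setNames(nst_sum$nst_mean, nst_sum$run),
    panova_p = stats::setNames(panova_tab$p_value, panova_tab$run))
  jsonlite::write_json(summary_json, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list.files(out_dir, full.names = TRUE)
}
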