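# Competitive lottery model. Phylogenetically related taxa (clades binned
# at a taxonomic rank, by default family) are assumed to compete for the
# same niche; a clade shows lottery behaviour in a sample when a single ASV
# captures more than 90% of the clade's reads there ("winner"). Winner
# prevalence (how often the clade has a winner) and winner diversity (how
# evenly different ASVs take the win) summarise the behaviour across
# samples.

#' Bin taxa into clades by a taxonomic rank
#'
#' @param taxonomy a `taxonomy_map`.
#' @param rank one of domain, phylum, class, order, family (default), genus,
#'   species.
#' @return A `clade_map`: named list of taxon-id vectors; attribute
#'   `n_unassigned` counts taxa with an empty rank value (excluded).
#' @export
build_clades <- function(taxonomy, rank = "family") {
  if (!rank %in% TAX_RANKS)
    ma_stop("validation_error", "unknown rank '%s'", rank)
  vals <- taxonomy$lineage[, rank]
  keep <- !is.na(vals) & vals != ""
  if (!any(keep)) {
    warning(sprintf("no taxon has a %s assignment; empty clade map", rank))
    clades <- list()
  } else {
    clades <- split(taxonomy$taxon_id[keep], vals[keep])
  }
  structure(clades, class = "clade_map", rank = rank,
            n_unassigned = sum(!keep))
}

#' @export
print.clade_map <- function(x, ...) {
  cat(sprintf("Clade map at rank '%s': %d clades, %d unassigned taxa\n",
              attr(x, "rank"), length(x), attr(x, "n_unassigned")))
  invisible(x)
}

#' Detect lottery winners per clade and sample
#'
#' In every sample where a clade carries at least `min_clade_reads` reads,
#' its most abundant member is called the winner iff its share of the
#' clade's reads strictly exceeds `threshold`.
#'
#' @param table an `asv_table`.
#' @param clades a [build_clades()] result.
#' @param threshold winner share threshold in (0.5, 1], strict (default 0.90).
#' @param min_clade_reads eligibility floor on clade reads per sample
#'   (default 10); keeps 1-read clades from producing trivial winners.
#' @return A `lottery_result`: list with `calls` (`sample_id`, `clade`,
#'   `eligible`, `winner` or `NA`, `share`) and the settings.
#' @export
detect_winners <- function(table, clades, threshold = 0.90,
                           min_clade_reads = 10L) {
  if (threshold <= 0.5 || threshold > 1)
    ma_stop("validation_error", "threshold must lie in (0.5, 1]")
  m <- counts(table)
  rows <- list()
  for (cl in names(clades)) {
    taxa <- intersect(clades[[cl]], rownames(m))
    if (!length(taxa)) next
    sub <- m[taxa, , drop = FALSE]
    tot <- colSums(sub)
    for (j in seq_len(ncol(sub))) {
      eligible <- tot[j] >= min_clade_reads
      winner <- NA_character_
      share <- NA_real_
      if (eligible) {
        top <- which.max(sub[, j])
        share <- sub[top, j] / tot[j]
        if (share > threshold) winner <- taxa[top]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = colnames(sub)[j], clade = cl, eligible = eligible,
        winner = winner, share = share, row.names = NULL)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows)
           else data.frame(sample_id = character(), clade = character(),
                           eligible = logical(), winner = character(),
                           share = numeric())
  structure(list(calls = calls, threshold = threshold,
                 min_clade_reads = min_clade_reads,
                 rank = attr(clades, "rank")),
            class = "lottery_result")
}

clade_calls <- function(result, clade) {
  calls <- result$calls[result$calls$clade == clade, , drop = FALSE]
  if (!any(calls$eligible))
    ma_stop("validation_error", "clade '%s' never eligible", clade)
  calls
}

#' Winner prevalence of a clade
#'
#' Fraction of eligible samples (clade present at or above the read floor)
#' in which a winner was called.
#'
#' @param result a [detect_winners()] result.
#' @param clade clade label.
#' @return Numeric in `[0, 1]`.
#' @export
winner_prevalence <- function(result, clade) {
  calls <- clade_calls(result, clade)
  sum(!is.na(calls$winner)) / sum(calls$eligible)
}

#' Winner diversity of a clade
#'
#' Normalised Shannon entropy of winner identities over the `S_w` samples
#' with a winner: `H(p) / log(S_w)`, where `p` are the frequencies of
#' distinct winner ASVs. Zero when a single ASV always wins (or only one
#' winning sample exists); 1 when every winning sample has a different
#' winner.
#'
#' @inheritParams winner_prevalence
#' @return Numeric in `[0, 1]`, or `NA` when the clade has no winner.
#' @export
winner_diversity <- function(result, clade) {
  calls <- clade_calls(result, clade)
  winners <- calls$winner[!is.na(calls$winner)]
  sw <- length(winners)
  if (sw == 0L) return(NA_real_)
  if (sw == 1L || length(unique(winners)) == 1L) return(0)
  p <- as.numeric(table(winners)) / sw
  -sum(p * log(p)) / log(sw)
}

#' Per-clade lottery summary
#'
#' @param result a [detect_winners()] result.
#' @return `data.frame`: `clade`, `n_eligible`, `n_winners`, `prevalence`,
#'   `diversity`.
#' @export
lottery_summary <- function(result) {
  clades <- unique(result$calls$clade[result$calls$eligible])
  do.call(rbind, lapply(clades, function(cl) {
    calls <- clade_calls(result, cl)
    data.frame(clade = cl, n_eligible = sum(calls$eligible),
               n_winners = sum(!is.na(calls$winner)),
               prevalence = winner_prevalence(result, cl),
               diversity = winner_diversity(result, cl), row.names = NULL)
  }))
}

#' Compare winner status of clades between sample categories
#'
#' Given one [detect_winners()] result per category (all computed on a
#' shared clade map), labels each clade as winning in all categories,
#' winning in a subset (listing which), or showing no lottery behaviour.
#'
#' @param results named list of `lottery_result`s, one per category.
#' @return `data.frame`: `clade`, `categories_won` (comma-separated),
#'   `status` in `{"winner in all", "winner in subset", "no lottery behaviour"}`.
#' @export
winner_status_changes <- function(results) {
  if (length(results) < 2L)
    ma_stop("validation_error", "need >= 2 categories")
  if (is.null(names(results)) || any(names(results) == ""))
    ma_stop("validation_error", "results must be a named list")
  for (nm in names(results)) {
    if (!nrow(results[[nm]]$calls))
      ma_stop("validation_error", "category '%s' has no samples", nm)
  }
  clades <- sort(unique(unlist(lapply(results, function(r) r$calls$clade))))
  won_in <- lapply(clades, function(cl) {
    names(results)[vapply(results, function(r) {
      calls <- r$calls[r$calls$clade == cl, , drop = FALSE]
      any(!is.na(calls$winner))
    }, logical(1))]
  })
  status <- vapply(won_in, function(w) {
    if (length(w) == 0L) "no lottery behaviour"
    else if (length(w) == length(results)) "winner in all"
    else "winner in subset"
  }, character(1))
  data.frame(clade = clades,
             categories_won = vapply(won_in, paste, character(1), collapse = ","),
             status = status, row.names = NULL)
}

#' Scatter plot of winner prevalence against winner diversity
#'
#' @param summary a [lottery_summary()] data.frame.
#' @return A `ggplot` object.
#' @export
plot_lottery <- function(summary) {
  dat <- summary[!is.na(summary$diversity), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$prevalence, y = .data$diversity)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$clade), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "winner prevalence", y = "winner diversity") +
    ggplot2::theme_minimal()
}
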