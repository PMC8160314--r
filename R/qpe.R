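# Quantitative process estimates (QPE). Each sample pair is first tested
# for selection with betaNTI; phylogenetically unremarkable pairs are then
# passed to an abundance-based Raup-Crick null on Bray-Curtis (RC-bray)
# that separates dispersal limitation (+drift), homogenizing dispersal and
# undominated turnover.

PROCESSES <- c("variable_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal", "undominated")

#' QPE configuration
#'
#' @param bnti_threshold selection threshold on |betaNTI| (default 2).
#' @param rc_threshold dispersal threshold on |RC-bray| (default 0.95).
#' @param reps randomisations per null model (default 999).
#' @param seed integer seed, or `NULL`.
#' @return A `qpe_config` list.
#' @export
qpe_config <- function(bnti_threshold = 2, rc_threshold = 0.95,
                       reps = 999L, seed = NULL) {
  stopifnot(bnti_threshold > 0, rc_threshold > 0)
  structure(list(bnti_threshold = bnti_threshold, rc_threshold = rc_threshold,
                 reps = as.integer(reps), seed = seed), class = "qpe_config")
}

# One null community: rich taxa drawn without replacement with probability
# proportional to occupancy, then the remaining reads allocated by a
# multinomial proportional to pool-wide relative abundance over the drawn
# taxa, after every drawn taxon receives one read (so realised richness
# equals drawn richness).
rc_null_draw <- function(rich, total, occ_w, ab_w) {
  idx <- sample.int(length(occ_w), rich, replace = FALSE, prob = occ_w)
  x <- integer(length(occ_w))
  x[idx] <- 1L
  extra <- total - rich
  if (extra > 0L) {
    p <- ab_w[idx]
    if (sum(p) <= 0) p <- rep(1, length(idx))
    x[idx] <- x[idx] + as.integer(stats::rmultinom(1L, extra, p))
  }
  x
}

#' Abundance-based Raup-Crick with Bray-Curtis for one sample pair
#'
#' The observed Bray-Curtis dissimilarity is located within a null
#' distribution in which each of the two communities is reassembled
#' independently: membership is drawn by occupancy (fraction of pool
#' samples containing the taxon) at the sample's observed richness, and the
#' sample's observed read total is allocated among the drawn taxa in
#' proportion to their pool-wide relative abundance, each drawn taxon
#' keeping at least one read. `RC = 2 * (#null < obs + 0.5 * #null = obs) /
#' reps - 1`, bounded in `[-1, 1]`; ties get half weight so discrete
#' Bray-Curtis values do not bias the score.
#'
#' @param table an `asv_table` (typically rarefied).
#' @param pair character vector of two sample ids.
#' @param reps randomisations (default 999).
#' @param seed integer seed.
#' @param pool character vector of sample ids defining the regional pool for
#'   occupancy and abundance weights; must contain the pair. Default: all
#'   samples of `table`.
#' @return Numeric RC value in `[-1, 1]`.
#' @export
rc_bray <- function(table, pair, reps = 999L, seed = NULL, pool = NULL) {
  stopifnot(length(pair) == 2L)
  ids <- sample_ids(table)
  if (is.null(pool)) pool <- ids
  if (!all(pair %in% pool))
    ma_stop("validation_error", "pool must contain both samples of the pair")
  sub <- drop_empty_taxa(subset_table(table, samples = pool))
  m <- counts(sub)
  occ_w <- rowMeans(m > 0L)
  ab_w <- rowSums(m) / sum(m)
  x <- m[, pair[1L]]
  y <- m[, pair[2L]]
  if (sum(x) == 0L || sum(y) == 0L)
    ma_stop("validation_error", "empty sample in pair")
  rich <- c(sum(x > 0L), sum(y > 0L))
  tot <- c(sum(x), sum(y))
  if (any(rich > nrow(m)))
    ma_stop("validation_error", "sample richness exceeds pool taxon count")
  obs <- bray_curtis(x, y)
  with_seed(seed, {
    null_bc <- vapply(seq_len(reps), function(r) {
      nx <- rc_null_draw(rich[1L], tot[1L], occ_w, ab_w)
      ny <- rc_null_draw(rich[2L], tot[2L], occ_w, ab_w)
      sum(abs(nx - ny)) / sum(nx + ny)
    }, numeric(1))
    eps <- 1e-12
    below <- sum(null_bc < obs - eps)
    ties <- sum(abs(null_bc - obs) <= eps)
    2 * (below + 0.5 * ties) / reps - 1
  })
}

#' Classify a sample pair into an assembly process
#'
#' The five-way rule, with strict inequalities throughout (boundary values
#' fall through to the weaker category): `betaNTI > +t` variable selection;
#' `betaNTI < -t` homogeneous selection; otherwise `RC > +r` dispersal
#' limitation, `RC < -r` homogenizing dispersal, else undominated. An `NA`
#' betaNTI yields `"undefined"`.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC-bray values; may be `NA` where
#'   `|bnti|` exceeds the threshold (RC is not needed there).
#' @param config a [qpe_config()].
#' @return Character vector of process labels.
#' @export
classify_pair <- function(bnti, rc = NA_real_, config = qpe_config()) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  t <- config$bnti_threshold
  r <- config$rc_threshold
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(bnti[i])) {
      out[i] <- "undefined"
    } else if (bnti[i] > t) {
      out[i] <- "variable_selection"
    } else if (bnti[i] < -t) {
      out[i] <- "homogeneous_selection"
    } else if (is.na(rc[i])) {
      ma_stop("validation_error",
              "RC-bray required when |betaNTI| <= %g (pair %d)", t, i)
    } else if (rc[i] > r) {
      out[i] <- "dispersal_limitation"
    } else if (rc[i] < -r) {
      out[i] <- "homogenizing_dispersal"
    } else {
      out[i] <- "undominated"
    }
  }
  out
}

#' Quantitative process estimates for grouped samples
#'
#' For each group, betaNTI is computed over all within-group pairs; RC-bray
#' is computed only for pairs whose |betaNTI| does not exceed the selection
#' threshold, using the group's samples as the regional pool; each pair is
#' then classified with [classify_pair()].
#'
#' @param table an `asv_table` (rarefied).
#' @param tree an `ape::phylo` covering the table's taxa.
#' @param metadata metadata `data.frame` with `sample_id`; required when
#'   `grouping` is given.
#' @param grouping character vector of metadata column names to group by,
#'   or `NULL` for a single all-samples group.
#' @param config a [qpe_config()].
#' @param pool_all use the whole table (not the group) as the RC regional
#'   pool.
#' @return Long `data.frame`: `sample_a`, `sample_b`, `group`, `bnti`,
#'   `rc_bray`, `process`.
#' @export
qpe <- function(table, tree, metadata = NULL, grouping = NULL,
                config = qpe_config(), pool_all = FALSE) {
  groups <- group_assignment(table, metadata, grouping)
  out <- list()
  for (g in names(groups)) {
    samp <- groups[[g]]
    if (length(samp) < 2L) {
      warning(sprintf("group '%s' has < 2 samples; skipped", g))
      next
    }
    sub <- drop_empty_taxa(subset_table(table, samples = samp))
    bn <- beta_nti(sub, tree, reps = config$reps,
                   seed = if (is.null(config$seed)) NULL
                          else stage_seed(config$seed, paste0("bnti_", g)))
    rc_pool <- if (pool_all) sample_ids(table) else samp
    rc_seed <- if (is.null(config$seed)) NULL
               else stage_seed(config$seed, paste0("rc_", g))
    rc <- rep(NA_real_, nrow(bn))
    need_rc <- !bn$undefined & abs(bn$bnti) <= config$bnti_threshold
    with_seed(rc_seed, {
      for (k in which(need_rc)) {
        rc[k] <- rc_bray(table, c(bn$sample_a[k], bn$sample_b[k]),
                         reps = config$reps, seed = NULL, pool = rc_pool)
      }
    })
    proc <- classify_pair(bn$bnti, rc, config)
    out[[g]] <- data.frame(sample_a = bn$sample_a, sample_b = bn$sample_b,
                           group = g, bnti = bn$bnti, rc_bray = rc,
                           process = proc, row.names = NULL)
  }
  if (!length(out)) ma_stop("validation_error", "no group with >= 2 samples")
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "config") <- config
  res
}

# sample-id sets per group label; grouping = NULL gives one group "all"
group_assignment <- function(table, metadata, grouping) {
  ids <- sample_ids(table)
  if (is.null(grouping)) return(list(all = ids))
  if (is.null(metadata))
    ma_stop("validation_error", "metadata required for grouped analysis")
  validate_crossrefs(table, metadata = metadata)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  missing <- setdiff(grouping, names(md))
  if (length(missing))
    ma_stop("validation_error", "unknown grouping column(s): %s",
            paste(missing, collapse = ", "))
  key <- do.call(paste, c(md[grouping], sep = "."))
  split(ids, key)
}

#' Summarise QPE pair classifications into per-group process fractions
#'
#' @param pairs the pairwise `data.frame` from [qpe()], or an `asv_table`
#'   (in which case the remaining arguments are forwarded to [qpe()] first).
#' @param ... forwarded to [qpe()] when `pairs` is a table.
#' @return `data.frame` with `group`, `process`, `fraction`, `n_pairs`;
#'   fractions are over defined pairs and sum to 1 per group. Attribute
#'   `excluded` counts undefined pairs per group.
#' @export
qpe_summary <- function(pairs, ...) {
  if (inherits(pairs, "asv_table")) pairs <- qpe(pairs, ...)
  out <- list()
  excluded <- integer()
  for (g in unique(pairs$group)) {
    p <- pairs$process[pairs$group == g]
    def <- p[p != "undefined"]
    excluded[g] <- sum(p == "undefined")
    tab <- table(factor(def, levels = PROCESSES))
    out[[g]] <- data.frame(group = g, process = PROCESSES,
                           fraction = if (length(def)) as.numeric(tab) / length(def)
                                      else rep(NA_real_, length(PROCESSES)),
                           n_pairs = as.integer(tab), row.names = NULL)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "excluded") <- excluded
  res
}

#' Stacked-bar plot of assembly process fractions per group
#'
#' @param summary result of [qpe_summary()].
#' @return A `ggplot` object.
#' @export
plot_qpe_fractions <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$process)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs",
                  fill = "assembly process") +
    ggplot2::theme_minimal()
}
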