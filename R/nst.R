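# Normalised stochasticity ratio (NST). Observed pairwise dissimilarity D
# is compared with the expectation E of a taxa-shuffling null; the
# stochasticity ratio ST is 1 when D sits at its null expectation and the
# normalised form NST runs from 0 (fully deterministic: D is at its
# attainable extreme) to 1 (fully stochastic). Group means are the
# statistic of interest; a permutation test ("PANOVA") compares groups.

#' One randomised community table under a taxa-richness constraint
#'
#' Taxa constraint "proportional": membership drawn with probability
#' proportional to occurrence frequency across the samples. Richness
#' constraint "fixed" (PF): each null sample keeps its observed richness.
#' Richness "proportional" (PP): each null sample's richness is a binomial
#' draw over the taxa pool with expectation equal to the observed richness.
#' Abundances (for the Ruzicka metric) are allocated to the drawn taxa in
#' proportion to pool-wide relative abundance, each drawn taxon keeping at
#' least one read; sample totals are preserved.
#'
#' @param table an `asv_table` with >= 2 samples.
#' @param constraint `"PP"` (proportional-proportional) or `"PF"`
#'   (proportional-fixed).
#' @param seed integer seed, or `NULL`.
#' @return A randomised `asv_table` with the same taxa and sample ids.
#' @export
nst_null_table <- function(table, constraint = c("PF", "PP"), seed = NULL) {
  constraint <- match.arg(constraint)
  m <- counts(table)
  if (ncol(m) < 2L) ma_stop("validation_error", "need >= 2 samples")
  S <- nrow(m)
  occ_w <- rowMeans(m > 0L)
  ab_w <- rowSums(m) / sum(m)
  rich <- colSums(m > 0L)
  tot <- colSums(m)
  with_seed(seed, {
    out <- matrix(0L, S, ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      r <- if (constraint == "PF") rich[j]
           else stats::rbinom(1L, S, rich[j] / S)
      r <- max(min(r, S), 1L)
      out[, j] <- rc_null_draw(r, max(tot[j], r), occ_w, ab_w)
    }
    res <- table
    res$counts <- out
    res
  })
}

# The ST/NST normalisation, isolated so it can be swapped against other
# conventions. Branch-symmetric in D around E; NST = 1 at D = E, 0 when D
# reaches the boundary away from E.
nst_pair_values <- function(D, E) {
  if (abs(D - E) < 1e-12) return(c(st = 1, nst = 1))
  if (E <= 0 || E >= 1) return(c(st = NA_real_, nst = 0))
  if (D >= E) {
    st <- E / D
    nst <- (st - E) / (1 - E)
  } else {
    st <- (1 - E) / (1 - D)
    nst <- (st - (1 - E)) / E
  }
  c(st = st, nst = nst)
}

#' Normalised stochasticity ratio for one sample group
#'
#' For every within-group pair, the observed dissimilarity `D_ij` is
#' compared to the mean dissimilarity `E_ij` of `reps` null tables drawn
#' under the chosen taxa-richness constraint; the pair's NST is 1 when
#' observed turnover equals the null expectation and approaches 0 as it
#' departs towards either boundary. The group NST is the mean over pairs.
#'
#' @param table an `asv_table`.
#' @param metric `"jaccard"` (incidence) or `"ruzicka"` (abundance).
#' @param constraint `"PF"` or `"PP"`, see [nst_null_table()].
#' @param reps null tables to average over (default 1000).
#' @param seed integer seed.
#' @param group character vector of sample ids to analyse (default: all).
#' @return An `nst_result`: list with `pairs` (`sample_a`, `sample_b`, `D`,
#'   `E`, `ST`, `NST`), `group_nst` (mean NST), and the run settings.
#' @export
stochasticity <- function(table, metric = c("jaccard", "ruzicka"),
                          constraint = c("PF", "PP"), reps = 1000L,
                          seed = NULL, group = NULL) {
  metric <- match.arg(metric)
  constraint <- match.arg(constraint)
  if (!is.null(group)) table <- subset_table(table, samples = group)
  table <- drop_empty_taxa(table)
  ids <- sample_ids(table)
  if (length(ids) < 2L) ma_stop("validation_error", "group needs >= 2 samples")
  fn <- switch(metric, jaccard = jaccard, ruzicka = ruzicka)
  obs <- dissimilarity_from_matrix(counts(table), fn, metric)
  n <- length(ids)
  with_seed(seed, {
    esum <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      nulltab <- nst_null_table(table, constraint = constraint, seed = NULL)
      esum <- esum + dissimilarity_from_matrix(counts(nulltab), fn, metric)
    }
    E <- esum / reps
    pairs <- sample_pairs(ids)
    k <- cbind(match(pairs[, 1L], ids), match(pairs[, 2L], ids))
    vals <- t(apply(cbind(obs[k], E[k]), 1L,
                    function(de) nst_pair_values(de[1L], de[2L])))
    res <- list(pairs = data.frame(sample_a = pairs[, 1L],
                                   sample_b = pairs[, 2L],
                                   D = obs[k], E = E[k],
                                   ST = vals[, "st"], NST = vals[, "nst"],
                                   row.names = NULL),
                group_nst = mean(vals[, "nst"]),
                metric = metric, constraint = constraint,
                reps = reps, seed = seed)
    class(res) <- "nst_result"
    res
  })
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("NST (%s, %s, %d reps): group mean %.1f%% over %d pairs\n",
              x$metric, x$constraint, x$reps, 100 * x$group_nst,
              nrow(x$pairs)))
  invisible(x)
}

#' Permutation test for NST differences between groups ("PANOVA")
#'
#' The statistic is the absolute difference of within-group mean pairwise
#' NST between two groups (for more groups, the pair-count-weighted sum of
#' squared deviations of group means from the grand mean). Sample-to-group
#' labels are permuted and within-group means recomputed from the
#' precomputed pairwise NST matrix; `p = (1 + #null >= obs) / (1 + permutations)`.
#'
#' @param nst_pairs `data.frame` with `sample_a`, `sample_b`, `NST` pooling
#'   the pairwise NST values of all samples (e.g. `rbind` of the `pairs`
#'   elements of per-group [stochasticity()] runs, or one run over all
#'   samples).
#' @param groups named character vector: sample id -> group label, for >= 2
#'   groups of >= 3 samples.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return A `panova_result` list: `statistic`, `p_value`, `permutations`,
#'   `groups`.
#' @export
panova <- function(nst_pairs, groups, permutations = 999L, seed = NULL) {
  ids <- unique(c(nst_pairs$sample_a, nst_pairs$sample_b))
  if (!all(ids %in% names(groups)))
    ma_stop("validation_error", "every sample needs a group label")
  glab <- groups[ids]
  if (length(unique(glab)) < 2L)
    ma_stop("validation_error", "need >= 2 groups")
  if (any(table(glab) < 3L))
    ma_stop("validation_error", "each group needs >= 3 samples")
  n <- length(ids)
  nstm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ia <- match(nst_pairs$sample_a, ids)
  ib <- match(nst_pairs$sample_b, ids)
  nstm[cbind(ia, ib)] <- nst_pairs$NST
  nstm[cbind(ib, ia)] <- nst_pairs$NST
  stat_for <- function(lab) {
    means <- counts <- numeric(0)
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) < 2L) return(NA_real_)
      vals <- nstm[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
      if (anyNA(vals)) return(NA_real_)
      means <- c(means, mean(vals))
      counts <- c(counts, length(vals))
    }
    if (length(means) == 2L) abs(means[1L] - means[2L])
    else sum(counts * (means - sum(counts * means) / sum(counts))^2)
  }
  obs <- stat_for(glab)
  if (is.na(obs))
    ma_stop("validation_error",
            "pairwise NST must cover all within-group pairs for every group")
  with_seed(seed, {
    null_stats <- vapply(seq_len(permutations),
                         function(p) stat_for(sample(glab)), numeric(1))
    if (anyNA(null_stats))
      ma_stop("validation_error",
              "pairwise NST must cover all sample pairs (including between-group pairs) for the permutation null")
    p_value <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + permutations)
    structure(list(statistic = obs, p_value = p_value,
                   permutations = permutations,
                   groups = sort(unique(glab))),
              class = "panova_result")
  })
}

#' @export
print.panova_result <- function(x, ...) {
  cat(sprintf("PANOVA (%s): statistic %.4f, p = %.4f (%d permutations)\n",
              paste(x$groups, collapse = " vs "), x$statistic, x$p_value,
              x$permutations))
  invisible(x)
}
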