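# Phylogenetic null models. The alpha side (MNTD against a richness null,
# reported as the nearest taxon index NTI) screens for environmental
# filtering: NTI > +2 means taxa are more locally clustered on the tree than
# chance, NTI < -2 means overdispersion. The beta side (betaMNTD against a
# tip-shuffling null, reported as betaNTI) drives the selection branch of
# the quantitative process estimates.

#' Tip-to-tip patristic distance matrix
#'
#' Distances are sums of branch lengths along the unique tip-to-tip path.
#'
#' @param tree an `ape::phylo` with >= 2 tips and branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L)
    ma_stop("validation_error", "tree needs >= 2 tips")
  as.matrix(stats::cophenetic(tree))
}

#' Mean nearest taxon distance of one community
#'
#' Unweighted: mean over present taxa of the distance to their nearest
#' present relative. Weighted: the same minima averaged with relative
#' abundance weights.
#'
#' @param comm named abundance (or incidence) vector; names are taxon ids.
#' @param dist patristic distance matrix from [cophenetic_distances()].
#' @param abundance_weighted weight nearest-taxon distances by relative
#'   abundance.
#' @return Non-negative numeric.
#' @export
mntd <- function(comm, dist, abundance_weighted = FALSE) {
  present <- names(comm)[comm > 0]
  if (length(present) < 2L)
    ma_stop("validation_error", "MNTD undefined for < 2 present taxa")
  missing <- setdiff(present, rownames(dist))
  if (length(missing))
    ma_stop("crossref_error", "taxa absent from distance matrix: %s",
            paste(missing, collapse = ", "))
  d <- dist[present, present, drop = FALSE]
  diag(d) <- Inf
  nearest <- row_mins(d)
  if (abundance_weighted) {
    f <- comm[present] / sum(comm[present])
    sum(f * nearest)
  } else {
    mean(nearest)
  }
}

# Unweighted MNTD of a tip index set against a full distance matrix;
# internal fast path used by the richness null.
mntd_idx <- function(idx, dmat) {
  d <- dmat[idx, idx, drop = FALSE]
  diag(d) <- Inf
  mean(row_mins(d))
}

#' Nearest taxon index per sample (richness null)
#'
#' Observed unweighted MNTD is compared to a null that redraws each sample's
#' membership: `reps` times, the sample's observed richness tips are drawn
#' uniformly without replacement from the taxa pool (taxa present in at
#' least one sample of the table), ignoring abundances. NTI is the negative
#' z-score, so positive values mean phylogenetic clustering.
#'
#' @param table an `asv_table`; every taxon must be a tree tip.
#' @param tree an `ape::phylo`.
#' @param reps number of randomisations (default 999).
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `richness`, `mntd_obs`,
#'   `null_mean`, `null_sd`, `nti` (`NA` where the null sd is zero, flagged
#'   in `undefined`), plus attributes `reps` and `seed`.
#' @export
nti <- function(table, tree, reps = 999L, seed = NULL) {
  table <- drop_empty_taxa(table)
  validate_crossrefs(table, tree = tree)
  dmat <- cophenetic_distances(tree)[taxon_ids(table), taxon_ids(table)]
  m <- counts(table)
  pool <- seq_len(nrow(m)) # taxa observed in >= 1 sample
  rich <- colSums(m > 0L)
  if (any(rich < 2L))
    ma_stop("validation_error", "sample(s) with < 2 taxa: %s",
            paste(colnames(m)[rich < 2L], collapse = ", "))
  obs <- vapply(seq_len(ncol(m)), function(j) mntd_idx(which(m[, j] > 0L), dmat),
                numeric(1))
  with_seed(seed, {
    null_mean <- null_sd <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
      draws <- vapply(seq_len(reps),
                      function(r) mntd_idx(sample(pool, rich[j]), dmat),
                      numeric(1))
      null_mean[j] <- mean(draws)
      null_sd[j] <- stats::sd(draws)
    }
    res <- data.frame(sample_id = colnames(m), richness = as.integer(rich),
                      mntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
                      nti = ifelse(null_sd > 0, -(obs - null_mean) / null_sd, NA_real_),
                      undefined = !(null_sd > 0), row.names = NULL)
    attr(res, "reps") <- reps
    attr(res, "seed") <- seed
    attr(res, "null_model") <- "richness"
    res
  })
}

#' Between-community mean nearest taxon distance
#'
#' `betaMNTD = 0.5 * (sum_k f_xk min_{l in y} d_kl + sum_k f_yk min_{l in x}
#' d_kl)`; a taxon present in both communities finds itself in the other
#' community and contributes zero.
#'
#' @param x,y named abundance vectors over the same taxon set.
#' @param dist patristic distance matrix.
#' @param abundance_weighted use relative abundance weights (default TRUE);
#'   unweighted gives each present taxon equal weight.
#' @return Non-negative numeric; zero iff the two memberships coincide.
#' @export
beta_mntd <- function(x, y, dist, abundance_weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  if (!length(px) || !length(py))
    ma_stop("validation_error", "betaMNTD undefined for an empty sample")
  miss <- setdiff(c(px, py), rownames(dist))
  if (length(miss))
    ma_stop("crossref_error", "taxa absent from distance matrix: %s",
            paste(miss, collapse = ", "))
  near_xy <- row_mins(dist[px, py, drop = FALSE])
  near_yx <- row_mins(dist[py, px, drop = FALSE])
  wx <- if (abundance_weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  wy <- if (abundance_weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  0.5 * (sum(wx * near_xy) + sum(wy * near_yx))
}

# All-pairs betaMNTD from a weight matrix (taxa x samples, columns summing
# to 1 over present taxa) and a presence matrix. M[k, j] = distance from
# taxon k to its nearest taxon present in sample j.
beta_mntd_all <- function(w, pres, dmat) {
  n <- ncol(w)
  M <- matrix(0, nrow(w), n)
  for (j in seq_len(n)) {
    M[, j] <- row_mins(dmat[, pres[, j], drop = FALSE])
  }
  a <- crossprod(w, M) # a[i, j] = sum_k w_ki * M[k, j]
  b <- 0.5 * (a + t(a))
  dimnames(b) <- list(colnames(w), colnames(w))
  b
}

#' Pairwise beta nearest taxon index (tip-shuffling null)
#'
#' Observed betaMNTD for every sample pair is compared to a null in which
#' taxon labels are permuted across the tips of the phylogeny; one
#' permutation per randomisation is applied to all pairs, the standard
#' practice for across-matrix turnover nulls. `betaNTI = (obs - null mean) /
#' null sd`; values above +2 indicate variable selection, below -2
#' homogeneous selection.
#'
#' @inheritParams nti
#' @param abundance_weighted weight by relative abundances (default TRUE).
#' @return Long `data.frame`: `sample_a`, `sample_b`, `bmntd_obs`,
#'   `null_mean`, `null_sd`, `bnti` (`NA` where the null sd is zero, e.g.
#'   identical memberships), `undefined`; attributes `reps`, `seed`.
#' @export
beta_nti <- function(table, tree, reps = 999L, seed = NULL,
                     abundance_weighted = TRUE) {
  table <- drop_empty_taxa(table)
  validate_crossrefs(table, tree = tree)
  ids <- sample_ids(table)
  if (length(ids) < 2L) ma_stop("validation_error", "need >= 2 samples")
  dmat_full <- cophenetic_distances(tree)
  obs_idx <- match(taxon_ids(table), rownames(dmat_full))
  dmat <- dmat_full[obs_idx, obs_idx]
  m <- counts(table)
  pres <- m > 0L
  w <- if (abundance_weighted) {
    relative_abundance(table)
  } else {
    sweep(pres * 1, 2L, pmax(colSums(pres), 1L), "/")
  }
  obs <- beta_mntd_all(w, pres, dmat)
  S <- nrow(m)
  n_tips <- nrow(dmat_full)
  with_seed(seed, {
    sum1 <- sum2 <- matrix(0, length(ids), length(ids))
    for (r in seq_len(reps)) {
      # shuffle taxa across ALL tips of the phylogeny: each observed taxon
      # is reassigned a random tip position, so a community confined to one
      # clade is compared against placements over the whole tree
      p <- sample.int(n_tips, S)
      b <- beta_mntd_all(w, pres, dmat_full[p, p, drop = FALSE])
      sum1 <- sum1 + b
      sum2 <- sum2 + b * b
    }
    null_mean <- sum1 / reps
    null_var <- pmax((sum2 - sum1^2 / reps) / (reps - 1), 0)
    null_sd <- sqrt(null_var)
    pairs <- sample_pairs(ids)
    i <- match(pairs[, 1L], ids)
    j <- match(pairs[, 2L], ids)
    k <- cbind(i, j)
    sd_k <- null_sd[k]
    res <- data.frame(sample_a = pairs[, 1L], sample_b = pairs[, 2L],
                      bmntd_obs = obs[k], null_mean = null_mean[k],
                      null_sd = sd_k,
                      bnti = ifelse(sd_k > 1e-12, (obs[k] - null_mean[k]) / sd_k,
                                    NA_real_),
                      undefined = !(sd_k > 1e-12), row.names = NULL)
    attr(res, "reps") <- reps
    attr(res, "seed") <- seed
    attr(res, "abundance_weighted") <- abundance_weighted
    res
  })
}

#' Write NTI / betaNTI result tables as TSV
#'
#' @param result data.frame from [nti()] or [beta_nti()].
#' @param path output path.
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
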