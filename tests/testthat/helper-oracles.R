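# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the implementation:
# distances come from explicit root-path enumeration, MNTD statistics from
# plain double loops.

tiny_table <- function(m, taxa = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- taxa %||% sprintf("T%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  asv_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tree_from_text <- function(text) ape::read.tree(text = text)

# Patristic distances by explicit path enumeration: distance = sum of the
# two root-paths minus twice the shared prefix.
brute_cophenetic <- function(tree) {
  tips <- tree$tip.label
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root_path <- function(node) {
    path <- node
    while (parent[node] != 0) {
      node <- parent[node]
      path <- c(path, node)
    }
    path
  }
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n - 1)) {
    pi <- root_path(i)
    for (j in seq.int(i + 1, n)) {
      pj <- root_path(j)
      shared <- intersect(pi, pj)
      path_edges <- c(setdiff(pi, shared), setdiff(pj, shared))
      d[i, j] <- d[j, i] <- sum(elen[path_edges])
    }
  }
  d
}

# Unweighted/weighted MNTD by a double loop over present taxa.
brute_mntd <- function(comm, d, weighted = FALSE) {
  present <- names(comm)[comm > 0]
  nearest <- vapply(present, function(k) {
    min(vapply(setdiff(present, k), function(l) d[k, l], numeric(1)))
  }, numeric(1))
  if (weighted) {
    f <- comm[present] / sum(comm[present])
    sum(f * nearest)
  } else mean(nearest)
}

# betaMNTD by a double loop, taxa shared by both samples matching themselves.
brute_beta_mntd <- function(x, y, d, weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  near <- function(from, to_set) {
    vapply(from, function(k) min(d[k, to_set]), numeric(1))
  }
  wx <- if (weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  wy <- if (weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  0.5 * (sum(wx * near(px, py)) + sum(wy * near(py, px)))
}

# Independent betaNTI: identical null definition (one whole-tree tip draw
# per rep, shared by all pairs, same RNG consumption) but every betaMNTD is
# computed with the brute-force pair loop instead of matrix algebra.
brute_beta_nti <- function(table, tree, reps, seed) {
  dmat_full <- as.matrix(ape::cophenetic.phylo(tree))
  m <- counts(table)
  ids <- colnames(m)
  taxa <- rownames(m)
  n_tips <- nrow(dmat_full)
  bm_for <- function(d) {
    pr <- list()
    for (i in seq_len(ncol(m) - 1)) for (j in seq.int(i + 1, ncol(m))) {
      x <- m[, i]; y <- m[, j]
      names(x) <- names(y) <- rownames(d)
      pr[[paste(ids[i], ids[j])]] <- brute_beta_mntd(x, y, d)
    }
    unlist(pr)
  }
  obs <- bm_for(structure(dmat_full[match(taxa, rownames(dmat_full)),
                                    match(taxa, rownames(dmat_full))],
                          dimnames = list(taxa, taxa)))
  set.seed(seed)
  draws <- matrix(NA_real_, reps, length(obs))
  for (r in seq_len(reps)) {
    p <- sample.int(n_tips, nrow(m))
    d <- dmat_full[p, p]
    dimnames(d) <- list(taxa, taxa)
    draws[r, ] <- bm_for(d)
  }
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, sd)
  (obs - mu) / sdv
}

# Hand-built 4-sample, 2-clade lottery toy covering the winner (0.95),
# strict-boundary (0.90), non-winner (0.80) and ineligible (< 10 reads)
# cases.
lottery_fixture <- function() {
  m <- matrix(0L, 5, 4,
              dimnames = list(c("A1", "A2", "B1", "B2", "B3"),
                              c("S1", "S2", "S3", "S4")))
  m["A1", ] <- c(19L, 9L, 8L, 3L)
  m["A2", ] <- c(1L, 1L, 2L, 1L)
  m["B1", ] <- c(95L, 2L, 0L, 50L)
  m["B2", ] <- c(5L, 96L, 1L, 0L)
  m["B3", ] <- c(0L, 2L, 9L, 1L)
  tax <- taxonomy_map(rownames(m), c(rep("d__B;p__;c__;o__;f__FamA", 2),
                                     rep("d__B;p__;c__;o__;f__FamB", 3)))
  list(table = asv_table(m), clades = build_clades(tax))
}

# Five-way QPE rule written as literal nested conditionals (truth table).
truth_table_process <- function(bnti, rc) {
  if (bnti > 2) return("variable_selection")
  if (bnti < -2) return("homogeneous_selection")
  if (rc > 0.95) return("dispersal_limitation")
  if (rc < -0.95) return("homogenizing_dispersal")
  "undominated"
}
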