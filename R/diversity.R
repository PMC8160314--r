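# Alpha diversity and pairwise dissimilarity metrics. These are the raw
# materials of the null models: Bray-Curtis feeds RC-bray, Jaccard and
# Ruzicka feed the stochasticity ratio.

#' Rarefied richness of one sample
#'
#' @param table an `asv_table`.
#' @param sample sample id.
#' @return Integer count of taxa with count > 0.
#' @export
richness <- function(table, sample) {
  v <- sample_vector(table, sample)
  sum(v > 0L)
}

#' Shannon entropy of one sample (nats)
#'
#' `H = -sum f log f` over taxa with relative abundance f > 0; natural log.
#'
#' @inheritParams richness
#' @return Non-negative numeric.
#' @export
shannon_entropy <- function(table, sample) {
  v <- sample_vector(table, sample)
  if (sum(v) == 0L) ma_stop("validation_error", "sample '%s' has no reads", sample)
  f <- v[v > 0L] / sum(v)
  -sum(f * log(f))
}

sample_vector <- function(table, sample) {
  if (!sample %in% sample_ids(table))
    ma_stop("crossref_error", "unknown sample id '%s'", sample)
  counts(table)[, sample]
}

check_pair_vectors <- function(x, y) {
  if (length(x) != length(y))
    ma_stop("validation_error", "vectors differ in length")
  if (any(x < 0) || any(y < 0))
    ma_stop("validation_error", "negative abundances")
  if (sum(x) == 0 && sum(y) == 0)
    ma_stop("validation_error", "dissimilarity undefined for two empty samples")
}

#' Pairwise community dissimilarity metrics
#'
#' `bray_curtis`: sum |x - y| / sum (x + y). `jaccard`: 1 - shared / union on
#' presence/absence. `ruzicka`: 1 - sum min(x, y) / sum max(x, y), the
#' abundance-based generalisation of Jaccard (identical to it on 0/1 data).
#'
#' @param x,y equal-length non-negative abundance vectors, not both all-zero.
#' @return Numeric in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair_vectors(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' @rdname bray_curtis
#' @export
jaccard <- function(x, y) {
  check_pair_vectors(x, y)
  px <- x > 0
  py <- y > 0
  1 - sum(px & py) / sum(px | py)
}

#' @rdname bray_curtis
#' @export
ruzicka <- function(x, y) {
  check_pair_vectors(x, y)
  1 - sum(pmin(x, y)) / sum(pmax(x, y))
}

#' All-pairs dissimilarity matrix
#'
#' @param table an `asv_table` with >= 2 samples.
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"ruzicka"`.
#' @param relative compute on relative abundances instead of counts; only
#'   useful for tables not equalised by rarefaction.
#' @return A symmetric numeric matrix with sample ids as dimnames and
#'   attribute `metric`.
#' @export
pairwise_matrix <- function(table, metric = c("bray_curtis", "jaccard", "ruzicka"),
                            relative = FALSE) {
  metric <- match.arg(metric)
  fn <- switch(metric, bray_curtis = bray_curtis, jaccard = jaccard,
               ruzicka = ruzicka)
  m <- if (relative) relative_abundance(table) else counts(table)
  dissimilarity_from_matrix(m, fn, metric)
}

# m: taxa x samples numeric matrix
dissimilarity_from_matrix <- function(m, fn, metric) {
  ids <- colnames(m)
  n <- ncol(m)
  if (n < 2L) ma_stop("validation_error", "need >= 2 samples")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- fn(m[, i], m[, j])
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Write a square dissimilarity matrix as TSV
#'
#' @param d symmetric matrix with sample-id dimnames.
#' @param path output path.
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
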