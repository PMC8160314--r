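# ASV abundance table: integer counts, taxa in rows, samples in columns.
# The class is a thin wrapper around a named integer matrix; all downstream
# statistics consume it through the accessors so orientation is an
# implementation detail.

#' Construct an ASV abundance table
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   row names (taxon ids) and unique column names (sample ids).
#' @return An object of class `asv_table`.
#' @export
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, dimnames = list(c("ASV1", "ASV2"),
#'                                                   c("S1", "S2")))
#' asv_table(m)
asv_table <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L)
    ma_stop("format_error", "abundance table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ma_stop("format_error", "counts must carry taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    ma_stop("format_error", "duplicated taxon ids: %s",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    ma_stop("format_error", "duplicated sample ids: %s",
            paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    ma_stop("format_error", "counts must be numeric and non-missing")
  if (any(counts < 0))
    ma_stop("format_error", "negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-9))
    ma_stop("format_error", "counts must be integral")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV abundance table: %d taxa x %d samples, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Accessors for `asv_table`
#'
#' @param table an `asv_table`.
#' @return `taxon_ids()`/`sample_ids()` return character vectors;
#'   `counts()` the integer taxa-by-samples matrix; `sample_totals()` the
#'   per-sample read totals; `relative_abundance()` the column-normalised
#'   matrix f_ik (columns with zero total stay zero).
#' @export
taxon_ids <- function(table) rownames(table$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' @rdname taxon_ids
#' @export
counts <- function(table) table$counts

#' @rdname taxon_ids
#' @export
sample_totals <- function(table) colSums(table$counts)

#' @rdname taxon_ids
#' @export
relative_abundance <- function(table) {
  tot <- colSums(table$counts)
  f <- sweep(table$counts, 2L, pmax(tot, 1L), "/")
  f[, tot == 0L] <- 0
  f
}

#' Read a taxa-by-samples abundance table from TSV
#'
#' Accepts the QIIME-style export whose header line begins with `#OTU ID`
#' (other leading `#` comment lines are skipped). The first column holds
#' taxon ids, remaining columns integer counts.
#'
#' @param path path to a tab-separated file.
#' @return An [asv_table].
#' @export
read_abundance_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # drop comment lines (BIOM exports carry "# Constructed from ...") but keep
  # the "#OTU ID" header itself
  lines <- lines[!(grepl("^#", lines) & !grepl("^#OTU", lines))]
  if (length(lines) < 2L) ma_stop("format_error", "abundance table has no data rows")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr))
    ma_stop("format_error", "duplicated sample ids in header: %s",
            paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) ma_stop("format_error", "abundance table needs >=1 sample column")
  taxa <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) ma_stop("format_error", "non-numeric count cells in %s", path)
  rownames(m) <- taxa
  asv_table(m)
}

#' Write an abundance table to TSV
#'
#' Emits a tab-delimited, newline-terminated UTF-8 file with an `#OTU ID`
#' header, the format [read_abundance_table()] reads back exactly.
#'
#' @param table an `asv_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", sample_ids(table)), collapse = "\t"), con)
  m <- counts(table)
  body <- paste(rownames(m), apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Remove contaminant lineages (chloroplast, mitochondria)
#'
#' Drops every taxon whose lineage contains any of `labels` at any rank,
#' matched case-insensitively as a substring: SILVA places "Chloroplast" at
#' order level and "Mitochondria" at family level, so rank-agnostic matching
#' is the robust rule.
#'
#' @param table an `asv_table`.
#' @param taxonomy a [taxonomy_map].
#' @param labels character vector of contaminant names.
#' @return Filtered `asv_table`; the sample set is unchanged. Filtering every
#'   taxon away yields an empty-taxa table with a warning.
#' @export
filter_contaminants <- function(table, taxonomy,
                                labels = c("Chloroplast", "Mitochondria")) {
  stopifnot(inherits(table, "asv_table"), inherits(taxonomy, "taxonomy_map"))
  lin <- taxonomy$lineage[match(taxon_ids(table), taxonomy$taxon_id), , drop = FALSE]
  lin[is.na(lin)] <- ""
  hit <- rep(FALSE, nrow(lin))
  for (lab in labels) {
    hit <- hit | apply(lin, 1L, function(r)
      any(grepl(lab, r, ignore.case = TRUE, fixed = FALSE)))
  }
  if (all(hit)) {
    warning("all taxa matched the contaminant labels; returning empty-taxa table")
    out <- table
    out$counts <- table$counts[FALSE, , drop = FALSE]
    return(out)
  }
  out <- table
  out$counts <- table$counts[!hit, , drop = FALSE]
  out
}

#' Drop taxa never observed in any sample
#'
#' Zero-abundance rows are unobserved taxa; they break occupancy-weighted
#' null models and are removed before downstream analysis.
#'
#' @param table an `asv_table`.
#' @return `asv_table` without all-zero rows.
#' @export
drop_empty_taxa <- function(table) {
  keep <- rowSums(table$counts) > 0L
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  out
}

#' Rarefy every sample to a common read depth
#'
#' Uniform subsampling WITHOUT replacement (multivariate hypergeometric),
#' the QIIME convention: each sample's reads are treated as distinguishable
#' items and `depth` of them are kept.
#'
#' @param table an `asv_table`.
#' @param depth positive integer target depth, or `"min"` for the minimum
#'   sample total.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @param drop_empty drop taxa with all-zero counts afterwards (default TRUE).
#' @return Rarefied `asv_table`; every column sums exactly to `depth` and no
#'   cell exceeds its original count.
#' @export
rarefy <- function(table, depth = "min", seed = NULL, drop_empty = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  tot <- sample_totals(table)
  if (identical(depth, "min")) depth <- min(tot)
  depth <- as.integer(depth)
  if (depth < 1L) ma_stop("validation_error", "rarefaction depth must be positive")
  if (any(tot < depth)) {
    ma_stop("validation_error",
            "rarefaction depth %d exceeds totals of sample(s): %s",
            depth, paste(names(tot)[tot < depth], collapse = ", "))
  }
  m <- counts(table)
  with_seed(seed, {
    out <- m
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      reads <- rep.int(seq_along(col), col)
      kept <- sample(reads, depth, replace = FALSE)
      out[, j] <- tabulate(kept, nbins = length(col))
    }
    res <- table
    res$counts <- out
    if (drop_empty) res <- drop_empty_taxa(res)
    res
  })
}

#' Subset an abundance table
#'
#' @param table an `asv_table`.
#' @param taxa,samples character vectors of ids to keep (`NULL` keeps all).
#' @return Subset `asv_table`.
#' @export
subset_table <- function(table, taxa = NULL, samples = NULL) {
  m <- counts(table)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(m))
    if (length(missing))
      ma_stop("crossref_error", "unknown taxa: %s", paste(missing, collapse = ", "))
    m <- m[taxa, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      ma_stop("crossref_error", "unknown samples: %s", paste(missing, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  out <- table
  out$counts <- m
  out
}
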