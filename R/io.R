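# Readers and writers for the remaining input formats: Newick trees (via
# ape), SILVA-style taxonomy TSV, and sample metadata TSV.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Read a rooted phylogenetic tree from Newick
#'
#' @param path path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) ma_stop("format_error",
                                               "unparseable Newick: %s", conditionMessage(e)))
  if (is.null(tree)) ma_stop("format_error", "unparseable Newick file %s", path)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Shared tree invariants: unique tips, branch lengths present and >= 0.
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    ma_stop("format_error", "duplicate tip labels: %s",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    ma_stop("format_error", "tree has no branch lengths")
  if (any(tree$edge.length < 0))
    ma_stop("format_error", "negative branch lengths")
  tree
}

#' Parse a semicolon-delimited lineage string
#'
#' Splits into the seven positional ranks (domain ... species), stripping
#' SILVA/QIIME rank prefixes such as `d__` or `f__`. Absent trailing ranks
#' become empty strings, never dropped.
#'
#' @param lineage character vector of lineage strings.
#' @param strip_prefix remove `x__`-style rank prefixes (default TRUE).
#' @return Character matrix with one row per input and the seven rank columns.
#' @export
parse_lineage <- function(lineage, strip_prefix = TRUE) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    if (strip_prefix) p <- sub("^[a-zA-Z]__", "", p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7L)))
  colnames(m) <- TAX_RANKS
  m
}

#' Read a taxonomy map (taxon id to lineage) from TSV
#'
#' Expects a header line and two columns: taxon id and semicolon-delimited
#' lineage.
#'
#' @param path path to a tab-separated file.
#' @param strip_prefix passed to [parse_lineage()].
#' @return A `taxonomy_map`: list with `taxon_id` and the 7-column `lineage`
#'   matrix.
#' @export
read_taxonomy <- function(path, strip_prefix = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) ma_stop("format_error", "taxonomy TSV needs id + lineage columns")
  taxonomy_map(df[[1L]], df[[2L]], strip_prefix = strip_prefix)
}

#' @rdname read_taxonomy
#' @param taxon_id character vector of taxon ids.
#' @param lineage character vector of lineage strings, parallel to `taxon_id`.
#' @export
taxonomy_map <- function(taxon_id, lineage, strip_prefix = TRUE) {
  taxon_id <- as.character(taxon_id)
  if (anyDuplicated(taxon_id))
    ma_stop("format_error", "duplicate taxon ids in taxonomy")
  structure(list(taxon_id = taxon_id,
                 lineage = parse_lineage(lineage, strip_prefix = strip_prefix)),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("Taxonomy map: %d taxa, ranks %s\n", length(x$taxon_id),
              paste(TAX_RANKS, collapse = "/")))
  invisible(x)
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_map`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lin <- apply(taxonomy$lineage, 1L, paste, collapse = ";")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("taxon_id\tlineage", paste(taxonomy$taxon_id, lin, sep = "\t")), con)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `position` (floating/settled),
#' `nucleic_acid` (DNA/cDNA) and `reactor`.
#'
#' @param path path to a tab-separated file.
#' @return A `data.frame` of validated metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          stringsAsFactors = FALSE, quote = "")
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata a metadata `data.frame`.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "position", "nucleic_acid", "reactor")
  missing <- setdiff(need, names(metadata))
  if (length(missing))
    ma_stop("format_error", "metadata lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    ma_stop("format_error", "duplicate sample ids in metadata")
  bad_pos <- setdiff(unique(metadata$position), c("floating", "settled"))
  if (length(bad_pos))
    ma_stop("validation_error", "unknown position label(s): %s",
            paste(bad_pos, collapse = ", "))
  bad_na <- setdiff(unique(metadata$nucleic_acid), c("DNA", "cDNA"))
  if (length(bad_na))
    ma_stop("validation_error", "unknown nucleic_acid label(s): %s",
            paste(bad_na, collapse = ", "))
  metadata
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that table, tree, taxonomy and metadata cross-reference cleanly
#'
#' Every table taxon must be a tree tip and a taxonomy entry; every table
#' sample must have a metadata row. Aborts with the complete offender list.
#'
#' @param table an `asv_table`.
#' @param tree an `ape::phylo` (optional).
#' @param taxonomy a `taxonomy_map` (optional).
#' @param metadata a metadata `data.frame` (optional).
#' @return `TRUE` invisibly, or a classed `crossref_error`.
#' @export
validate_crossrefs <- function(table, tree = NULL, taxonomy = NULL,
                               metadata = NULL) {
  problems <- character()
  if (!is.null(tree)) {
    miss <- setdiff(taxon_ids(table), tree$tip.label)
    if (length(miss))
      problems <- c(problems, sprintf("taxa absent from tree: %s",
                                      paste(miss, collapse = ", ")))
  }
  if (!is.null(taxonomy)) {
    miss <- setdiff(taxon_ids(table), taxonomy$taxon_id)
    if (length(miss))
      problems <- c(problems, sprintf("taxa absent from taxonomy: %s",
                                      paste(miss, collapse = ", ")))
  }
  if (!is.null(metadata)) {
    miss <- setdiff(sample_ids(table), metadata$sample_id)
    if (length(miss))
      problems <- c(problems, sprintf("samples absent from metadata: %s",
                                      paste(miss, collapse = ", ")))
  }
  if (length(problems))
    ma_stop("crossref_error", "cross-reference failures:\n%s",
            paste(problems, collapse = "\n"))
  invisible(TRUE)
}
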