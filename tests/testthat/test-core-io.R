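# Readers, validation, contaminant filtering and rarefaction.

test_that("abundance table parsing enforces the format contract", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS2", "ASV1\t3\t0", "ASV2\t1\t2"), tsv)
  tab <- read_abundance_table(tsv)
  expect_equal(taxon_ids(tab), c("ASV1", "ASV2"))
  expect_equal(unname(sample_totals(tab)), c(4L, 2L))

  writeLines(c("#OTU ID\tS1\tS2", "ASV1\t-1\t0", "ASV2\t1\t2"), tsv)
  expect_error(read_abundance_table(tsv), class = "format_error")

  writeLines(c("#OTU ID\tS1\tS1", "ASV1\t1\t0"), tsv)
  expect_error(read_abundance_table(tsv), class = "format_error")

  writeLines(c("#OTU ID\tS1\tS2", "ASV1\t1\t0", "ASV1\t1\t2"), tsv)
  expect_error(read_abundance_table(tsv), class = "format_error")

  writeLines("#OTU ID\tS1", tsv)
  expect_error(read_abundance_table(tsv), class = "format_error")

  expect_error(asv_table(matrix(1.5, 1, 1, dimnames = list("A", "S"))),
               class = "format_error")
})

test_that("abundance table round-trips through TSV exactly", {
  tab <- tiny_table(matrix(c(3L, 0L, 1L, 2L, 5L, 7L), 3))
  tsv <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, tsv)
  back <- read_abundance_table(tsv)
  expect_identical(counts(back), counts(tab))
})

test_that("relative abundances sum to one for non-empty samples", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rpois(30, 4), 6)
    m[, 1] <- m[, 1] + 1L # guarantee one positive column
    tab <- tiny_table(m)
    f <- relative_abundance(tab)
    pos <- sample_totals(tab) > 0
    expect_true(all(abs(colSums(f[, pos, drop = FALSE]) - 1) < 1e-12))
  }
})

test_that("newick reading preserves tips and branch lengths", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:0.5,C:0.5):0.5);", nwk)
  tree <- read_newick(nwk)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  expect_equal(sum(tree$edge.length), 2.5)

  writeLines("(A:1,A:1);", nwk)
  expect_error(read_newick(nwk), class = "format_error")

  tr2 <- tree_from_text("(A:1,B:1);")
  out <- tempfile(fileext = ".nwk")
  write_newick(tr2, out)
  back <- read_newick(out)
  expect_setequal(back$tip.label, tr2$tip.label)
  expect_equal(sort(back$edge.length), sort(tr2$edge.length))
})

test_that("taxonomy lineages split into seven positional ranks", {
  lin <- parse_lineage(paste0("d__Bacteria;p__Firmicutes;c__Bacilli;",
                              "o__Lactobacillales;f__Streptococcaceae;",
                              "g__Lactococcus;"))
  expect_equal(unname(lin[1, "family"]), "Streptococcaceae")
  expect_equal(unname(lin[1, "genus"]), "Lactococcus")
  expect_equal(unname(lin[1, "species"]), "")

  short <- parse_lineage("d__Bacteria;p__Firmicutes;c__Bacilli")
  expect_equal(unname(short[1, "family"]), "")

  tax <- taxonomy_map(c("A", "B"), c("d__X;p__Y", "d__X"))
  tsv <- tempfile(fileext = ".tsv")
  write_taxonomy(tax, tsv)
  back <- read_taxonomy(tsv)
  expect_identical(back$lineage, tax$lineage)
})

test_that("metadata validation rejects unknown category labels", {
  md <- data.frame(sample_id = c("S1", "S2"),
                   position = c("floating", "settled"),
                   nucleic_acid = c("DNA", "cDNA"), reactor = "R1")
  expect_silent(validate_metadata(md))
  md_bad <- md
  md_bad$position[1] <- "sideways"
  expect_error(validate_metadata(md_bad), class = "validation_error")
  md_bad2 <- md
  md_bad2$nucleic_acid[2] <- "RNAish"
  expect_error(validate_metadata(md_bad2), class = "validation_error")
  tsv <- tempfile(fileext = ".tsv")
  write_metadata(md, tsv)
  expect_identical(read_metadata(tsv), md)
})

test_that("contaminant filtering is rank-agnostic and case-insensitive", {
  tab <- tiny_table(matrix(1L, 3, 2), taxa = c("A", "B", "C"))
  tax <- taxonomy_map(
    c("A", "B", "C"),
    c("d__Bacteria;p__Cyanobacteria;c__;o__Chloroplast",
      "d__Bacteria;p__Firmicutes",
      "d__Bacteria;p__Proteobacteria;c__;o__;f__MITOCHONDRIA"))
  out <- filter_contaminants(tab, tax)
  expect_equal(taxon_ids(out), "B")
  expect_equal(sample_ids(out), sample_ids(tab))

  tax_clean <- taxonomy_map(c("A", "B", "C"), rep("d__Bacteria", 3))
  expect_identical(counts(filter_contaminants(tab, tax_clean)), counts(tab))

  tax_all <- taxonomy_map(c("A", "B", "C"), rep("o__Chloroplast", 3))
  expect_warning(empty <- filter_contaminants(tab, tax_all))
  expect_equal(nrow(counts(empty)), 0L)
})

test_that("rarefaction conserves depth and never exceeds original counts", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(40, 20), 8) + 1L
    tab <- tiny_table(m)
    r <- rarefy(tab, depth = 50, seed = i, drop_empty = FALSE)
    expect_true(all(sample_totals(r) == 50L))
    expect_true(all(counts(r) <= counts(tab)))
  }
})

test_that("rarefaction resolves depth='min' and errors on shallow samples", {
  tab <- tiny_table(matrix(c(23000L, 510L, 20000L, 10000L), 2))
  r <- rarefy(tab, depth = "min", seed = 1)
  expect_true(all(sample_totals(r) == 23510L))

  shallow <- tiny_table(matrix(c(5L, 5L, 4L, 6L), 2))
  r6 <- rarefy(shallow, depth = 6, seed = 2, drop_empty = FALSE)
  expect_true(all(sample_totals(r6) == 6L))
  expect_true(all(counts(r6) <= counts(shallow)))
  one <- tiny_table(matrix(c(4L, 6L), 2))
  expect_error(rarefy(one, depth = 11), class = "validation_error",
               regexp = "S01")
})

test_that("rarefied counts follow the hypergeometric marginal law", {
  # sample (8, 2) at depth 5: exact mean of taxon 1 is 5 * 8/10 = 4
  tab <- tiny_table(matrix(c(8L, 2L), 2))
  draws <- vapply(seq_len(2000), function(s)
    counts(rarefy(tab, depth = 5, seed = s, drop_empty = FALSE))[1, 1],
    integer(1))
  # exact hypergeometric variance: n*K/N*(N-K)/N*(N-n)/(N-1)
  v <- 5 * 0.8 * 0.2 * (10 - 5) / 9
  se <- sqrt(v / 2000)
  expect_lt(abs(mean(draws) - 4), 3 * se)
})

test_that("rarefaction is reproducible under a fixed seed", {
  tab <- tiny_table(matrix(rpois(60, 30), 10) + 1L)
  a <- rarefy(tab, depth = 100, seed = 99)
  b <- rarefy(tab, depth = 100, seed = 99)
  expect_identical(counts(a), counts(b))
})

test_that("cross-reference validation lists every offender", {
  tab <- tiny_table(matrix(1L, 3, 2), taxa = c("A", "B", "Zmissing"))
  tree <- tree_from_text("(A:1,(B:1,C:1):1);")
  err <- tryCatch(validate_crossrefs(tab, tree = tree), error = identity)
  expect_s3_class(err, "crossref_error")
  expect_match(conditionMessage(err), "Zmissing")
})
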