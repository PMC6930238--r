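test_that("gene tables are sorted by coordinate and ranked per contig", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("a", "b", "c"), protein_id = c("pa", "pb", "pc"),
    contig = "c1", start = c(100L, 900L, 50L), end = c(400L, 1200L, 80L),
    strand = "+", product = "x"
  ), path)
  genes <- read_gene_table(path)
  expect_identical(genes$gene_id, c("c", "a", "b"))
  expect_identical(genes$rank_on_contig, 0:2)

  # reader idempotence
  expect_identical(read_gene_table(path), genes)
})

test_that("gene table errors name the offending column or gene", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = "a", contig = "c1",
                                  start = 1L, end = 2L, strand = "+"), path)
  expect_error(read_gene_table(path), "protein_id",
               class = "tryp_format_error")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = "badgene", protein_id = "p", contig = "c1",
    start = 10L, end = 5L, strand = "+", product = "x"
  ), path2)
  expect_error(read_gene_table(path2), "badgene",
               class = "tryp_format_error")
})

test_that("empty gene table with header yields an empty record list", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tryptomine:::empty_gene_table()[, 1:6], path)
  expect_identical(nrow(read_gene_table(path)), 0L)
})

test_that("GFF3 and TSV encodings of one genome parse identically", {
  genes <- make_genes(5, strands = c("+", "-", "+", "+", "-"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(genes[, c("gene_id", "protein_id", "contig", "start",
                             "end", "strand", "product")], tsv)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("c1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=%s",
            genes$start, genes$end, genes$strand, genes$gene_id,
            genes$protein_id)
  ), gff)
  a <- read_gene_table(tsv)
  b <- read_gene_table(gff, format = "gff3")
  cols <- c("gene_id", "protein_id", "contig", "start", "end", "strand",
            "rank_on_contig")
  expect_identical(as.data.frame(a[, cols]), as.data.frame(b[, cols]))
})

test_that("domtblout parsing skips comments and keeps versioned accessions", {
  path <- withr::local_tempfile()
  writeLines(c(
    "# comment", "#", "# another",
    "p001 - 300 Trp_dioxygenase PF03301.2 200 1e-30 250 0.0 1 1 1e-30 1e-30 250",
    "p002 - 300 3-HAO PF06052.11 200 1e-25 200 0.0 1 1 1e-25 1e-25 200"
  ), path)
  hits <- read_domain_hits(path)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$protein_id, c("p001", "p002"))
  expect_identical(hits$accession, c("PF03301.2", "PF06052.11"))
  expect_equal(hits$evalue, c(1e-30, 1e-25))
  # versionless comparison downstream
  g <- toy_genome(domain_hits = hits[1, ])
  expect_true(has_domain(g, "PF03301")$present)
})

test_that("domtblout numeric garbage is rejected with a line number", {
  path <- withr::local_tempfile()
  writeLines("p001 - 300 dom PF03301 200 1e-30 250 0.0 1 1 1e-30 oops 250",
             path)
  expect_error(read_domain_hits(path), "line 1",
               class = "tryp_format_error")
})

test_that("outfmt-6 parsing attaches query lengths and validates shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tnaA_ECOLI\tp001\t85.0\t471\t20\t0\t1\t471\t1\t471\t1e-50\t800",
             path)
  hits <- read_homology_hits(path, c(tnaA_ECOLI = 471))
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$percent_identity, 85.0)
  expect_identical(hits$query_length, 471L)

  expect_error(read_homology_hits(path, c(other = 100)), "tnaA_ECOLI",
               class = "tryp_lookup_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q\ts\t85.0\t100", bad)
  expect_error(read_homology_hits(bad, c(q = 100)), "12",
               class = "tryp_format_error")
})

test_that("manifest loading rejects duplicates and inconsistent taxonomy", {
  dir <- withr::local_tempdir()
  res <- make_collection(collection_design(
    genera = tibble::tibble(genus = c("A", "B"), phylum = c("P1", "P2"),
                            n_strains = c(1L, 1L), n_gut_strains = c(1L, 0L)),
    seed = 5
  ), dir)
  coll <- load_genome_collection(res$manifest)
  expect_length(coll$genomes, 2)

  man <- readr::read_tsv(res$manifest, show_col_types = FALSE)
  dup <- file.path(dir, "dup.tsv")
  readr::write_tsv(rbind(man, man[1, ]), dup)
  expect_error(load_genome_collection(dup), "duplicate",
               class = "tryp_manifest_error")

  man2 <- man
  man2$phylum <- c("P1", "P1")
  man2$genus <- c("A", "A")
  man2$phylum[2] <- "P9"
  inc <- file.path(dir, "inconsistent.tsv")
  readr::write_tsv(man2, inc)
  expect_error(load_genome_collection(inc), "inconsistent",
               class = "tryp_manifest_error")
})

test_that("hit tables referencing unknown proteins fail integrity checks", {
  expect_error(
    toy_genome(domain_hits = domain_hit("not_a_protein", "PF03301")),
    "not_a_protein",
    class = "tryp_integrity_error"
  )
})
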