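#' Construct a genome record
#'
#' A genome record bundles one strain's gene annotations, protein-domain hits
#' and protein-homology hits with its taxonomy and gut-association flag.
#' Hit tables must reference proteins present in the gene table.
#'
#' @param genome_id Unique genome identifier.
#' @param phylum,genus,species,strain Taxonomy labels.
#' @param is_gut_associated Logical gut-association flag.
#' @param genes Tibble as returned by [read_gene_table()].
#' @param domain_hits Tibble as returned by [read_domain_hits()].
#' @param homology_hits Tibble as returned by [read_homology_hits()].
#' @return A `tryp_genome` object.
#' @export
genome_record <- function(genome_id, phylum = NA_character_,
                          genus = NA_character_, species = NA_character_,
                          strain = NA_character_, is_gut_associated = FALSE,
                          genes = empty_gene_table(),
                          domain_hits = empty_domain_hits(),
                          homology_hits = empty_homology_hits()) {
  g <- structure(
    list(
      genome_id = genome_id,
      phylum = phylum, genus = genus, species = species, strain = strain,
      is_gut_associated = isTRUE(is_gut_associated),
      genes = genes, domain_hits = domain_hits, homology_hits = homology_hits
    ),
    class = "tryp_genome"
  )
  check_genome_integrity(g)
  g
}

empty_gene_table <- function() {
  tibble::tibble(
    gene_id = character(), protein_id = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    rank_on_contig = integer(), product = character()
  )
}

empty_domain_hits <- function() {
  tibble::tibble(
    protein_id = character(), accession = character(),
    domain_name = character(), evalue = double(), bitscore = double()
  )
}

empty_homology_hits <- function() {
  tibble::tibble(
    query_tag = character(), subject_protein_id = character(),
    percent_identity = double(), alignment_length = integer(),
    evalue = double(), bitscore = double(), query_length = integer()
  )
}

check_genome_integrity <- function(genome) {
  prot <- genome$genes$protein_id
  bad_d <- setdiff(genome$domain_hits$protein_id, prot)
  bad_h <- setdiff(genome$homology_hits$subject_protein_id, prot)
  if (length(bad_d) + length(bad_h) > 0) {
    abort_tryp(
      paste0("genome '", genome$genome_id, "': hit tables reference unknown ",
             "protein(s): ", paste(unique(c(bad_d, bad_h)), collapse = ", ")),
      "tryp_integrity_error"
    )
  }
  invisible(genome)
}

#' @export
print.tryp_genome <- function(x, ...) {
  cat("<tryp_genome> ", x$genome_id, " (", x$genus, ", ", x$phylum, ")\n",
      sep = "")
  cat("  genes: ", nrow(x$genes), "; domain hits: ", nrow(x$domain_hits),
      "; homology hits: ", nrow(x$homology_hits),
      "; gut-associated: ", x$is_gut_associated, "\n", sep = "")
  invisible(x)
}

# Deterministic gene order: (contig, start, end, gene_id); ranks 0-based.
rank_genes <- function(genes) {
  genes <- dplyr::arrange(genes, .data$contig, .data$start, .data$end,
                          .data$gene_id)
  genes <- dplyr::group_by(genes, .data$contig)
  genes <- dplyr::mutate(genes, rank_on_contig = dplyr::row_number() - 1L)
  dplyr::ungroup(genes)
}

#' Read a gene annotation table
#'
#' Reads per-genome gene coordinates either from a TSV with header columns
#' `gene_id, protein_id, contig, start, end, strand, product` or from a GFF3
#' file, in which case CDS features are kept and `ID`/`protein_id`/`product`
#' attributes are consumed. All coordinates are 1-based inclusive; a GFF3
#' input already uses that convention. Records are sorted by
#' `(contig, start, end, gene_id)` and `rank_on_contig` is assigned 0-based
#' in that order — proximity analyses work in rank units.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gff3"`.
#' @return Tibble with columns `gene_id, protein_id, contig, start, end,
#'   strand, rank_on_contig, product`.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    genes <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               start = readr::col_integer(),
                               end = readr::col_integer(),
                               .default = readr::col_character()
                             ))
    need <- c("gene_id", "protein_id", "contig", "start", "end", "strand")
    miss <- setdiff(need, names(genes))
    if (length(miss) > 0) {
      abort_tryp(paste0("gene table '", path, "' lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 "tryp_format_error")
    }
    if (!"product" %in% names(genes)) genes$product <- NA_character_
    genes <- genes[, c(need, "product")]
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    meta <- S4Vectors::mcols(gr)
    pid <- if ("protein_id" %in% names(meta)) {
      as.character(meta$protein_id)
    } else {
      as.character(meta$ID)
    }
    genes <- tibble::tibble(
      gene_id = as.character(meta$ID),
      protein_id = pid,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product = if ("product" %in% names(meta)) {
        as.character(meta$product)
      } else {
        NA_character_
      }
    )
  }
  bad <- genes$gene_id[genes$start > genes$end]
  if (length(bad) > 0) {
    abort_tryp(paste0("gene table '", path, "': start > end for gene(s): ",
                      paste(bad, collapse = ", ")),
               "tryp_format_error")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_tryp(paste0("gene table '", path, "': strand must be '+' or '-'"),
               "tryp_format_error")
  }
  rank_genes(genes)
}

#' Read protein-domain hits (HMMER domtblout dialect)
#'
#' Parses a whitespace-delimited per-domain table in the hmmsearch domtblout
#' layout (protein sequences as targets, Pfam profiles as queries; lines
#' starting with `#` are comments). Consumed columns: target name (protein),
#' query name (domain name), query accession (Pfam accession), independent
#' e-value and domain score.
#'
#' @param path Input file.
#' @return Tibble with columns `protein_id, accession, domain_name, evalue,
#'   bitscore`.
#' @export
read_domain_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_domain_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- vapply(fields, length, integer(1))
  if (any(n_fields < 14)) {
    abort_tryp(paste0("domain hit table '", path, "': line ",
                      which(n_fields < 14)[1],
                      " has fewer than 14 whitespace-delimited fields"),
               "tryp_format_error")
  }
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 13)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 14)))
  if (anyNA(evalue) || anyNA(score)) {
    bad <- which(is.na(evalue) | is.na(score))[1]
    abort_tryp(paste0("domain hit table '", path, "': unparseable numeric ",
                      "field on data line ", bad),
               "tryp_format_error")
  }
  tibble::tibble(
    protein_id = vapply(fields, `[[`, "", 1),
    accession = vapply(fields, `[[`, "", 5),
    domain_name = vapply(fields, `[[`, "", 4),
    evalue = evalue,
    bitscore = score
  )
}

#' Read protein-homology hits (BLAST tabular outfmt 6)
#'
#' Parses the 12-column tab-delimited BLAST output (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) and
#' attaches each query's protein length from `query_lengths`, needed
#' downstream to apply the coverage threshold (outfmt 6 itself carries no
#' coverage column).
#'
#' @param path Input file (no header line).
#' @param query_lengths Named numeric vector or two-column data frame
#'   (`query_tag`, `length`) giving each query protein's length.
#' @return Tibble with columns `query_tag, subject_protein_id,
#'   percent_identity, alignment_length, evalue, bitscore, query_length`.
#' @export
read_homology_hits <- function(path, query_lengths) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(as.numeric(query_lengths[[2]]),
                                     as.character(query_lengths[[1]]))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_homology_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- vapply(fields, length, integer(1))
  if (any(n_fields != 12)) {
    abort_tryp(paste0("homology hit table '", path, "': line ",
                      which(n_fields != 12)[1],
                      " does not have 12 tab-delimited columns"),
               "tryp_format_error")
  }
  qseqid <- vapply(fields, `[[`, "", 1)
  unknown <- setdiff(unique(qseqid), names(query_lengths))
  if (length(unknown) > 0) {
    abort_tryp(paste0("homology hit table '", path, "': query tag(s) absent ",
                      "from query_lengths: ", paste(unknown, collapse = ", ")),
               "tryp_lookup_error")
  }
  tibble::tibble(
    query_tag = qseqid,
    subject_protein_id = vapply(fields, `[[`, "", 2),
    percent_identity = as.numeric(vapply(fields, `[[`, "", 3)),
    alignment_length = as.integer(vapply(fields, `[[`, "", 4)),
    evalue = as.numeric(vapply(fields, `[[`, "", 11)),
    bitscore = as.numeric(vapply(fields, `[[`, "", 12)),
    query_length = as.integer(query_lengths[qseqid])
  )
}

#' Load a genome collection from a manifest
#'
#' The manifest is a TSV with columns `genome_id, phylum, genus, species,
#' strain, is_gut_associated` (0/1) and per-genome file paths `gene_table,
#' domain_table, homology_table`, relative to the manifest's directory. A
#' `query_lengths.tsv` (columns `query_tag, length`) beside the manifest
#' supplies homolog query lengths unless `query_lengths` is given. Every
#' genome is fully loaded and cross-checked: duplicate genome ids, hit rows
#' referencing unknown proteins, and genera whose strains disagree on phylum
#' are all rejected.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param query_lengths Optional query-length mapping (see
#'   [read_homology_hits()]).
#' @return A `tryp_collection`: list with `genomes` (named list of
#'   `tryp_genome`) and `manifest` metadata.
#' @export
load_genome_collection <- function(manifest_path, query_lengths = NULL) {
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("genome_id", "phylum", "genus", "species", "strain",
            "is_gut_associated", "gene_table", "domain_table", "homology_table")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    abort_tryp(paste0("manifest '", manifest_path, "' lacks column(s): ",
                      paste(miss, collapse = ", ")),
               "tryp_format_error")
  }
  dup <- man$genome_id[duplicated(man$genome_id)]
  if (length(dup) > 0) {
    abort_tryp(paste0("manifest '", manifest_path, "': duplicate genome_id: ",
                      paste(unique(dup), collapse = ", ")),
               "tryp_manifest_error")
  }
  bad_tax <- dplyr::summarise(dplyr::group_by(man, .data$genus),
                              n_phyla = dplyr::n_distinct(.data$phylum))
  bad_tax <- bad_tax$genus[bad_tax$n_phyla > 1]
  if (length(bad_tax) > 0) {
    abort_tryp(paste0("manifest '", manifest_path, "': genus with ",
                      "inconsistent phylum labels: ",
                      paste(bad_tax, collapse = ", ")),
               "tryp_manifest_error")
  }
  base <- dirname(manifest_path)
  if (is.null(query_lengths)) {
    ql_path <- file.path(base, "query_lengths.tsv")
    query_lengths <- if (file.exists(ql_path)) {
      readr::read_tsv(ql_path, show_col_types = FALSE)
    } else {
      stats::setNames(numeric(), character())
    }
  }
  genomes <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    genome_record(
      genome_id = row$genome_id,
      phylum = row$phylum, genus = row$genus,
      species = row$species, strain = row$strain,
      is_gut_associated = row$is_gut_associated %in% c("1", "TRUE", "true"),
      genes = read_gene_table(file.path(base, row$gene_table)),
      domain_hits = read_domain_hits(file.path(base, row$domain_table)),
      homology_hits = read_homology_hits(file.path(base, row$homology_table),
                                         query_lengths)
    )
  })
  names(genomes) <- man$genome_id
  structure(
    list(genomes = genomes,
         manifest = man[, setdiff(need, c("gene_table", "domain_table",
                                          "homology_table"))]),
    class = "tryp_collection"
  )
}

#' Build a genome collection from in-memory genome records
#'
#' @param genomes List of `tryp_genome` objects.
#' @return A `tryp_collection`.
#' @export
genome_collection <- function(genomes) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) {
    abort_tryp(paste0("duplicate genome_id: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "tryp_manifest_error")
  }
  names(genomes) <- ids
  manifest <- tibble::tibble(
    genome_id = ids,
    phylum = vapply(genomes, `[[`, "", "phylum"),
    genus = vapply(genomes, `[[`, "", "genus"),
    species = vapply(genomes, `[[`, "", "species"),
    strain = vapply(genomes, `[[`, "", "strain"),
    is_gut_associated = as.character(as.integer(
      vapply(genomes, `[[`, logical(1), "is_gut_associated")
    ))
  )
  structure(list(genomes = genomes, manifest = manifest),
            class = "tryp_collection")
}

#' @export
print.tryp_collection <- function(x, ...) {
  cat("<tryp_collection> ", length(x$genomes), " genomes, ",
      dplyr::n_distinct(x$manifest$genus), " genera, ",
      dplyr::n_distinct(x$manifest$phylum), " phyla\n", sep = "")
  invisible(x)
}
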