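# In-code fixture builders shared across the test files.

# n genes on one contig, 1 kb apart, deterministic strands unless given.
make_genes <- function(n, contig = "c1", strands = NULL, prefix = "g") {
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n)
  tibble::tibble(
    gene_id = sprintf("%s%03d", prefix, seq_len(n)),
    protein_id = sprintf("p%03d", seq_len(n)),
    contig = contig,
    start = (seq_len(n) - 1L) * 1000L + 1L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = strands,
    rank_on_contig = seq_len(n) - 1L,
    product = NA_character_
  )
}

domain_hit <- function(protein_id, accession, evalue = 1e-30,
                       domain_name = "dom", bitscore = 200) {
  tibble::tibble(protein_id = protein_id, accession = accession,
                 domain_name = domain_name, evalue = evalue,
                 bitscore = bitscore)
}

homology_hit <- function(query_tag, subject, percent_identity = 95,
                         alignment_length = 500L, evalue = 1e-50,
                         bitscore = 800, query_length = 500L) {
  tibble::tibble(query_tag = query_tag, subject_protein_id = subject,
                 percent_identity = percent_identity,
                 alignment_length = as.integer(alignment_length),
                 evalue = evalue, bitscore = bitscore,
                 query_length = as.integer(query_length))
}

toy_genome <- function(genome_id = "G1", n_genes = 20, genus = "Escherichia",
                       phylum = "Proteobacteria", gut = TRUE,
                       domain_hits = NULL, homology_hits = NULL,
                       genes = NULL) {
  genome_record(
    genome_id, phylum = phylum, genus = genus, species = paste(genus, "sp."),
    strain = "s1", is_gut_associated = gut,
    genes = if (is.null(genes)) make_genes(n_genes) else genes,
    domain_hits = if (is.null(domain_hits)) {
      tryptomine:::empty_domain_hits()
    } else {
      domain_hits
    },
    homology_hits = if (is.null(homology_hits)) {
      tryptomine:::empty_homology_hits()
    } else {
      homology_hits
    }
  )
}

# Exhaustive oracle for minimal role-covering windows over one contig.
# Candidates: data frame with gene_id, rank, strand and a list-column roles.
oracle_windows <- function(cand, roles, max_gap, same_strand = FALSE) {
  strata <- if (same_strand) split(cand, cand$strand) else list(cand)
  out <- list()
  for (s in strata) {
    s <- s[order(s$rank), , drop = FALSE]
    n <- nrow(s)
    if (n == 0) next
    valid <- function(a, b) {
      rr <- unlist(s$roles[a:b])
      if (!all(roles %in% rr)) return(FALSE)
      gaps <- diff(s$rank[a:b]) - 1L
      length(gaps) == 0 || all(gaps <= max_gap)
    }
    for (a in seq_len(n)) {
      for (b in a:n) {
        if (!valid(a, b)) next
        minimal <- TRUE
        for (a2 in a:b) {
          for (b2 in a2:b) {
            if ((a2 != a || b2 != b) && valid(a2, b2)) minimal <- FALSE
          }
        }
        if (minimal) out[[length(out) + 1L]] <- s$gene_id[a:b]
      }
    }
  }
  out
}

# Full-enumeration two-sided p for the rank-sum of x vs y (tie-free inputs).
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  combos <- utils::combn(N, nx)
  W_all <- apply(combos, 2, function(idx) sum(seq_len(N)[idx]))
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}
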