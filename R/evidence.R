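#' Evidence thresholds
#'
#' The thresholds the homology and domain evidence must pass, and the
#' proximity window for gene-cluster detection. Defaults follow the BLAST
#' screening parameters used throughout the analysis: identity >= 70%,
#' query coverage >= 90%, e-value <= 1e-5 (all boundaries inclusive), a
#' domain-hit e-value ceiling of 1e-5, and a cluster/operon window of at most
#' 3 intervening genes between consecutive member genes.
#'
#' @param identity_min Minimum percent identity, in `[0, 100]`.
#' @param coverage_min Minimum query coverage percent, in `[0, 100]`.
#'   Coverage is computed as `100 * min(alignment_length, query_length) /
#'   query_length` (local alignments with gaps can exceed the query length;
#'   coverage clips at 100).
#' @param evalue_max Maximum homology e-value (> 0).
#' @param domain_evalue_max Maximum domain-hit independent e-value (> 0).
#' @param proximity_max_gap Maximum number of intervening genes between
#'   consecutive cluster members (and between an operonic gene pair).
#' @return A `tryp_thresholds` list.
#' @export
#' @examples
#' thresholds()
#' thresholds(identity_min = 80)
thresholds <- function(identity_min = 70, coverage_min = 90,
                       evalue_max = 1e-5, domain_evalue_max = 1e-5,
                       proximity_max_gap = 3L) {
  if (identity_min < 0 || identity_min > 100 ||
      coverage_min < 0 || coverage_min > 100) {
    abort_tryp("identity_min and coverage_min must lie in [0, 100]",
               "tryp_argument_error")
  }
  if (evalue_max <= 0 || domain_evalue_max <= 0) {
    abort_tryp("e-value ceilings must be positive", "tryp_argument_error")
  }
  if (proximity_max_gap < 0) {
    abort_tryp("proximity_max_gap must be >= 0", "tryp_argument_error")
  }
  structure(
    list(identity_min = identity_min, coverage_min = coverage_min,
         evalue_max = evalue_max, domain_evalue_max = domain_evalue_max,
         proximity_max_gap = as.integer(proximity_max_gap)),
    class = "tryp_thresholds"
  )
}

#' Filter homology hits by identity, coverage and e-value
#'
#' Keeps exactly the hits with `percent_identity >= identity_min`,
#' coverage `>= coverage_min` and `evalue <= evalue_max`; all three
#' boundaries are inclusive and input order is preserved. Coverage is
#' derived from the alignment length and the query protein length as
#' documented in [thresholds()].
#'
#' @param hits Tibble of homology hits (see [read_homology_hits()]).
#' @param t A `tryp_thresholds`.
#' @return The retained subset of `hits`.
#' @export
filter_homology_hits <- function(hits, t = thresholds()) {
  if (nrow(hits) == 0) return(hits)
  coverage <- 100 * pmin(hits$alignment_length, hits$query_length) /
    hits$query_length
  keep <- hits$percent_identity >= t$identity_min &
    coverage >= t$coverage_min &
    hits$evalue <= t$evalue_max
  hits[keep, , drop = FALSE]
}

#' Test a genome for presence of a Pfam functional domain
#'
#' A domain is present when at least one domain hit matches the accession
#' (version suffixes like `.11` are ignored on both sides) with independent
#' e-value at or below `domain_evalue_max`.
#'
#' @param genome A `tryp_genome`.
#' @param accession Pfam accession (`PF` + 5 digits, optional version).
#' @param t A `tryp_thresholds`.
#' @return List with `present` (logical) and `hits` (the supporting rows).
#' @export
has_domain <- function(genome, accession, t = thresholds()) {
  if (length(accession) != 1 || !is_pfam_accession(accession)) {
    abort_tryp(paste0("malformed Pfam accession: ",
                      paste(accession, collapse = ", ")),
               "tryp_argument_error")
  }
  hits <- genome$domain_hits
  keep <- pfam_match(hits$accession, accession) &
    hits$evalue <= t$domain_evalue_max
  hits <- hits[keep, , drop = FALSE]
  list(present = nrow(hits) > 0, hits = hits)
}

# Genes (rows of genome$genes) holding any of the given protein ids.
genes_for_proteins <- function(genome, protein_ids) {
  genome$genes[genome$genes$protein_id %in% protein_ids, , drop = FALSE]
}

#' Find gene clusters satisfying a proximity requirement
#'
#' Searches one genome for minimal windows of genes, on a single contig,
#' that contain at least one candidate gene for every member role with at
#' most `max_gap_genes` intervening genes between consecutive member genes
#' (gaps measured in gene-rank units, so intergenic distances in base pairs
#' are irrelevant). With `same_strand = TRUE` all member genes must lie on
#' one strand. A window is minimal when no proper sub-window also covers all
#' roles. Returns an empty list when any role has no candidate gene.
#'
#' @param genome A `tryp_genome`.
#' @param role_proteins Named list mapping each role to a character vector of
#'   candidate protein ids (may be empty).
#' @param req A cluster requirement (list with `roles`, `max_gap_genes`,
#'   `same_strand`), e.g. from the catalog's IPA rule.
#' @param t A `tryp_thresholds` (unused by the window search itself; retained
#'   for interface symmetry with the other evidence primitives).
#' @return List of cluster calls, each a list with `contig`,
#'   `member_gene_ids` (in rank order), `role_assignment` (role -> gene_id)
#'   and `span_genes` (window width in genes, including non-members).
#' @export
find_gene_cluster <- function(genome, role_proteins, req, t = thresholds()) {
  roles <- req$roles
  missing_roles <- setdiff(roles, names(role_proteins))
  if (length(missing_roles) > 0) {
    abort_tryp(paste0("role_proteins lacks role(s): ",
                      paste(missing_roles, collapse = ", ")),
               "tryp_argument_error")
  }
  if (any(vapply(role_proteins[roles], length, integer(1)) == 0)) {
    return(list())
  }
  genes <- genome$genes
  # candidate genes with the set of roles each serves
  cand_roles <- lapply(seq_len(nrow(genes)), function(i) {
    r <- roles[vapply(roles, function(role) {
      genes$protein_id[i] %in% role_proteins[[role]]
    }, logical(1))]
    r
  })
  is_cand <- vapply(cand_roles, length, integer(1)) > 0
  if (!any(is_cand)) return(list())
  cand <- genes[is_cand, , drop = FALSE]
  cand$roles <- cand_roles[is_cand]

  strata <- if (isTRUE(req$same_strand)) {
    split(cand, interaction(cand$contig, cand$strand, drop = TRUE))
  } else {
    split(cand, cand$contig)
  }

  calls <- list()
  for (s in strata) {
    s <- s[order(s$rank_on_contig), , drop = FALSE]
    # chains: maximal runs where consecutive candidates are within the gap
    breaks <- which(diff(s$rank_on_contig) - 1L > req$max_gap_genes)
    chain_id <- cumsum(c(1L, seq_len(nrow(s) - 1L) %in% breaks))
    for (chain in split(s, chain_id)) {
      calls <- c(calls, minimal_covering_windows(chain, roles))
    }
  }
  calls
}

# Two-pointer scan for minimal windows (over candidate genes in one chain)
# covering every role.
minimal_covering_windows <- function(chain, roles) {
  n <- nrow(chain)
  count <- stats::setNames(integer(length(roles)), roles)
  covers <- function() all(count > 0)
  out <- list()
  l <- 1L
  prev_l <- 0L
  for (r in seq_len(n)) {
    for (role in chain$roles[[r]]) count[role] <- count[role] + 1L
    if (!covers()) next
    # shrink from the left while coverage survives
    repeat {
      removable <- all(vapply(chain$roles[[l]],
                              function(role) count[role] > 1L, logical(1)))
      if (!removable || l == r) break
      for (role in chain$roles[[l]]) count[role] <- count[role] - 1L
      l <- l + 1L
    }
    # minimal iff the right end is necessary, i.e. the left pointer moved
    # (or this is the first covering window)
    if (l > prev_l || length(out) == 0) {
      window <- chain[l:r, , drop = FALSE]
      assignment <- lapply(roles, function(role) {
        window$gene_id[vapply(window$roles,
                              function(rr) role %in% rr, logical(1))][1]
      })
      names(assignment) <- roles
      out[[length(out) + 1L]] <- list(
        contig = window$contig[1],
        member_gene_ids = window$gene_id,
        role_assignment = assignment,
        span_genes = window$rank_on_contig[nrow(window)] -
          window$rank_on_contig[1] + 1L
      )
      prev_l <- l
    }
  }
  out
}

#' Test two genes for operonic proximity
#'
#' TRUE when the genes encoding the two proteins lie on the same contig with
#' at most `max_gap` intervening genes (`|rank difference| - 1 <= max_gap`)
#' and, if `same_strand`, on the same strand. Symmetric in its two protein
#' arguments.
#'
#' @param genome A `tryp_genome`.
#' @param protein_a,protein_b Protein ids; both must resolve to genes.
#' @param max_gap Maximum intervening genes.
#' @param same_strand Require equal strands?
#' @return Logical scalar.
#' @export
proximal_pair <- function(genome, protein_a, protein_b, max_gap = 3L,
                          same_strand = FALSE) {
  ga <- genes_for_proteins(genome, protein_a)
  gb <- genes_for_proteins(genome, protein_b)
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    missing <- c(protein_a, protein_b)[c(nrow(ga) == 0, nrow(gb) == 0)]
    abort_tryp(paste0("genome '", genome$genome_id, "': unknown protein(s): ",
                      paste(missing, collapse = ", ")),
               "tryp_lookup_error")
  }
  ga <- ga[1, ]
  gb <- gb[1, ]
  ga$contig == gb$contig &&
    abs(ga$rank_on_contig - gb$rank_on_contig) - 1L <= max_gap &&
    (!same_strand || ga$strand == gb$strand)
}
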