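#' Predict the six metabolite pathways for one strain
#'
#' Evaluates every catalog rule against one genome. Domain-evidence enzymes
#' are satisfied when any of their Pfam accessions is present
#' ([has_domain()]); homolog-evidence enzymes when at least one homology hit
#' to any of their query tags passes the thresholds
#' ([filter_homology_hits()]). A rule is true when all `all_of` enzymes and
#' at least one `any_of` enzyme (when declared) are satisfied; a rule with a
#' cluster requirement additionally needs at least one proximity window over
#' the satisfied member genes ([find_gene_cluster()]). The returned evidence
#' trail records, per enzyme leaf (plus a `cluster` pseudo-leaf where
#' applicable), whether it was satisfied and the supporting hits or windows.
#'
#' @param genome A `tryp_genome`.
#' @param catalog A `tryp_catalog`; defaults to [default_catalog()].
#' @param t A `tryp_thresholds`.
#' @return Tibble with one row per metabolite: `genome_id, metabolite,
#'   present` and an `evidence` list-column.
#' @export
predict_strain <- function(genome, catalog = default_catalog(),
                           t = thresholds()) {
  rows <- lapply(catalog$pathways, function(rule) {
    ev <- evaluate_rule(genome, rule, catalog, t)
    tibble::tibble(
      genome_id = genome$genome_id,
      metabolite = rule$metabolite,
      present = ev$present,
      evidence = list(ev$evidence)
    )
  })
  out <- dplyr::bind_rows(rows)
  out[match(tryp_metabolites(), out$metabolite), , drop = FALSE]
}

# satisfied leaf -> list(satisfied, support): support = passing hit rows
evaluate_leaf <- function(genome, enzyme, t) {
  if (enzyme$evidence_kind == "domain") {
    support <- list()
    for (acc in enzyme$pfam) {
      d <- has_domain(genome, acc, t)
      if (d$present) support[[length(support) + 1L]] <- d$hits
    }
    support <- if (length(support)) dplyr::bind_rows(support) else empty_domain_hits()
    list(satisfied = nrow(support) > 0, support = support)
  } else {
    hits <- genome$homology_hits
    hits <- hits[hits$query_tag %in% enzyme$queries, , drop = FALSE]
    hits <- filter_homology_hits(hits, t)
    list(satisfied = nrow(hits) > 0, support = hits)
  }
}

# proteins supporting a satisfied leaf (for cluster role mapping)
leaf_support_proteins <- function(leaf_eval, enzyme) {
  if (!leaf_eval$satisfied) return(character())
  if (enzyme$evidence_kind == "domain") {
    unique(leaf_eval$support$protein_id)
  } else {
    unique(leaf_eval$support$subject_protein_id)
  }
}

evaluate_rule <- function(genome, rule, catalog, t) {
  leaves <- unique(c(rule$all_of, rule$any_of))
  evals <- lapply(leaves, function(nm) {
    evaluate_leaf(genome, catalog$enzymes[[nm]], t)
  })
  names(evals) <- leaves
  sat <- vapply(evals, `[[`, logical(1), "satisfied")
  present <- all(sat[rule$all_of]) &&
    (length(rule$any_of) == 0 || any(sat[rule$any_of]))

  evidence <- tibble::tibble(
    leaf = leaves,
    satisfied = unname(sat),
    support = lapply(evals, `[[`, "support")
  )

  if (present && !is.null(rule$cluster)) {
    role_proteins <- lapply(rule$cluster$roles, function(nm) {
      leaf_support_proteins(evals[[nm]], catalog$enzymes[[nm]])
    })
    names(role_proteins) <- rule$cluster$roles
    clusters <- find_gene_cluster(genome, role_proteins, rule$cluster, t)
    present <- length(clusters) > 0
    evidence <- dplyr::bind_rows(evidence, tibble::tibble(
      leaf = "cluster", satisfied = present, support = list(clusters)
    ))
  }
  list(present = present, evidence = evidence)
}

#' Build the strain-by-pathway call matrix
#'
#' Runs [predict_strain()] over every genome of a collection. Rows are
#' ordered by genome id for determinism; the full per-call evidence is kept
#' in the `"calls"` attribute (see [call_evidence()]).
#'
#' @param collection A `tryp_collection`.
#' @param catalog A `tryp_catalog`.
#' @param t A `tryp_thresholds`.
#' @return A tibble of class `tryp_call_matrix`: column `genome_id` plus one
#'   logical column per metabolite.
#' @export
build_call_matrix <- function(collection, catalog = default_catalog(),
                              t = thresholds()) {
  if (length(collection$genomes) == 0) {
    abort_tryp("collection is empty", "tryp_argument_error")
  }
  ids <- sort(names(collection$genomes))
  calls <- dplyr::bind_rows(lapply(ids, function(id) {
    predict_strain(collection$genomes[[id]], catalog, t)
  }))
  wide <- tidyr::pivot_wider(calls[, c("genome_id", "metabolite", "present")],
                             names_from = "metabolite",
                             values_from = "present")
  wide <- wide[, c("genome_id", tryp_metabolites())]
  structure(wide, class = c("tryp_call_matrix", class(wide)),
            calls = calls)
}

#' Per-call evidence trail of a call matrix
#'
#' @param matrix A `tryp_call_matrix` from [build_call_matrix()].
#' @return Long tibble `genome_id, metabolite, present, evidence`.
#' @export
call_evidence <- function(matrix) {
  attr(matrix, "calls")
}

#' Per-phylum pathway prevalence
#'
#' For each phylum and metabolite, the proportion of the phylum's strains
#' called positive — the content of the phylum-level prevalence heat map.
#'
#' @param matrix A `tryp_call_matrix`.
#' @param collection The `tryp_collection` the matrix was built from.
#' @return Tibble `phylum, metabolite, n_strains, n_present, proportion`.
#' @export
phylum_proportions <- function(matrix, collection) {
  long <- tidyr::pivot_longer(tibble::as_tibble(matrix), -"genome_id",
                              names_to = "metabolite", values_to = "present")
  long <- dplyr::left_join(long,
                           collection$manifest[, c("genome_id", "phylum")],
                           by = "genome_id")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$phylum, .data$metabolite),
    n_strains = dplyr::n(),
    n_present = sum(.data$present),
    proportion = mean(.data$present),
    .groups = "drop"
  )
  out$metabolite <- factor(out$metabolite, levels = tryp_metabolites())
  dplyr::arrange(out, .data$phylum, .data$metabolite)
}

#' Gut-level pathway counts at phylum, genus and strain resolution
#'
#' Restricted to gut-associated genomes: for each metabolite, how many
#' distinct phyla, distinct genera and individual strains are predicted to
#' possess the pathway.
#'
#' @inheritParams phylum_proportions
#' @return Tibble `metabolite, n_phyla, n_genera, n_strains`.
#' @export
gut_level_counts <- function(matrix, collection) {
  man <- collection$manifest
  gut_ids <- man$genome_id[man$is_gut_associated %in% c("1", "TRUE", "true")]
  long <- tidyr::pivot_longer(tibble::as_tibble(matrix), -"genome_id",
                              names_to = "metabolite", values_to = "present")
  long <- long[long$genome_id %in% gut_ids & long$present, , drop = FALSE]
  long <- dplyr::left_join(long, man[, c("genome_id", "phylum", "genus")],
                           by = "genome_id")
  counts <- dplyr::summarise(
    dplyr::group_by(long, .data$metabolite),
    n_phyla = dplyr::n_distinct(.data$phylum),
    n_genera = dplyr::n_distinct(.data$genus),
    n_strains = dplyr::n(),
    .groups = "drop"
  )
  base <- tibble::tibble(metabolite = tryp_metabolites())
  out <- dplyr::left_join(base, counts, by = "metabolite")
  out[is.na(out)] <- 0L
  out
}
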