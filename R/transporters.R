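#' Profile tryptophan transporters in one genome
#'
#' Screens a genome for the three tryptophan importers. By default the
#' screen applies only to indole producers, mirroring the scope of the
#' original transporter analysis (indole production implies tryptophanase,
#' TnaB's operonic anchor); for a non-producer a not-applicable profile is
#' returned unless `restrict_to_indole = FALSE`.
#'
#' * **TnaB** — present when a gene carrying the TnaB functional domain lies
#'   operonically (same strand, within `proximity_max_gap` intervening genes)
#'   next to a gene whose protein is a passing tryptophanase homolog.
#' * **AroP**, **Mtr** — present when a homology hit to their query proteins
#'   passes the identity/coverage/e-value thresholds.
#'
#' @param genome A `tryp_genome`.
#' @param catalog A `tryp_catalog`.
#' @param t A `tryp_thresholds`.
#' @param indole_present Logical; the genome's indole call. When `NULL` it is
#'   computed via [predict_strain()].
#' @param restrict_to_indole Screen only indole producers (default TRUE).
#' @return A `tryp_transporter_profile`: list with `genome_id`, `applicable`,
#'   `transporters` (character subset of TnaB/AroP/Mtr) and per-transporter
#'   `evidence`.
#' @export
profile_transporters <- function(genome, catalog = default_catalog(),
                                 t = thresholds(), indole_present = NULL,
                                 restrict_to_indole = TRUE) {
  if (is.null(indole_present)) {
    calls <- predict_strain(genome, catalog, t)
    indole_present <- calls$present[calls$metabolite == "indole"]
  }
  prof <- structure(
    list(genome_id = genome$genome_id, applicable = TRUE,
         transporters = character(), evidence = list()),
    class = "tryp_transporter_profile"
  )
  if (restrict_to_indole && !isTRUE(indole_present)) {
    prof$applicable <- FALSE
    return(prof)
  }

  for (nm in names(catalog$transporters)) {
    spec <- catalog$transporters[[nm]]
    if (spec$mode == "homolog") {
      hits <- genome$homology_hits
      hits <- hits[hits$query_tag %in% spec$queries, , drop = FALSE]
      hits <- filter_homology_hits(hits, t)
      if (nrow(hits) > 0) {
        prof$transporters <- c(prof$transporters, nm)
        prof$evidence[[nm]] <- hits
      }
    } else {
      # proximity_to_anchor: domain gene operonic to an anchor-homolog gene
      anchor <- catalog$enzymes[[spec$anchor]]
      anchor_eval <- evaluate_leaf(genome, anchor, t)
      anchor_prot <- leaf_support_proteins(anchor_eval, anchor)
      dom_prot <- character()
      for (acc in spec$pfam) {
        d <- has_domain(genome, acc, t)
        dom_prot <- c(dom_prot, unique(d$hits$protein_id))
      }
      pairs <- expand.grid(a = unique(dom_prot), b = anchor_prot,
                           stringsAsFactors = FALSE)
      ok <- vapply(seq_len(nrow(pairs)), function(i) {
        proximal_pair(genome, pairs$a[i], pairs$b[i],
                      max_gap = t$proximity_max_gap, same_strand = TRUE)
      }, logical(1))
      if (any(ok)) {
        prof$transporters <- c(prof$transporters, nm)
        prof$evidence[[nm]] <- pairs[ok, , drop = FALSE]
      }
    }
  }
  prof
}

#' Summarize transporter profiles across genomes
#'
#' Aggregates the per-genome profiles of the applicable (screened) genomes
#' into: overall counts and the proportion of genomes with at least one
#' transporter (pie-chart analog); occupancy of the seven non-empty subsets
#' of \{TnaB, Mtr, AroP\} (Venn analog); and per-genus proportions of strains
#' carrying each transporter (heat-map analog).
#'
#' @param profiles List of `tryp_transporter_profile`.
#' @param collection The `tryp_collection` the profiles came from.
#' @return List with `counts` (tibble: `n_screened, n_with, n_without,
#'   prop_with`), `venn` (tibble: `subset, n`), and `per_genus` (tibble:
#'   `genus, transporter, n_strains, n_with, proportion`).
#' @export
transporter_summary <- function(profiles, collection) {
  profiles <- Filter(function(p) p$applicable, profiles)
  n <- length(profiles)
  sets <- lapply(profiles, `[[`, "transporters")
  n_with <- sum(vapply(sets, length, integer(1)) > 0)

  venn_names <- c("TnaB", "Mtr", "AroP", "TnaB+Mtr", "TnaB+AroP", "Mtr+AroP",
                  "TnaB+Mtr+AroP")
  subset_label <- function(s) {
    paste(c("TnaB", "Mtr", "AroP")[c("TnaB", "Mtr", "AroP") %in% s],
          collapse = "+")
  }
  labels <- vapply(sets, subset_label, "")
  venn <- tibble::tibble(
    subset = venn_names,
    n = vapply(unname(venn_names), function(v) sum(labels == v), integer(1),
               USE.NAMES = FALSE)
  )

  ids <- vapply(profiles, `[[`, "", "genome_id")
  genus <- collection$manifest$genus[match(ids, collection$manifest$genome_id)]
  per_genus <- dplyr::bind_rows(lapply(c("TnaB", "Mtr", "AroP"), function(tr) {
    has <- vapply(sets, function(s) tr %in% s, logical(1))
    d <- tibble::tibble(genus = genus, has = has)
    dplyr::summarise(dplyr::group_by(d, .data$genus),
                     transporter = tr,
                     n_strains = dplyr::n(),
                     n_with = sum(.data$has),
                     proportion = mean(.data$has),
                     .groups = "drop")
  }))
  per_genus <- dplyr::arrange(per_genus, .data$genus, .data$transporter)

  list(
    counts = tibble::tibble(
      n_screened = n, n_with = n_with, n_without = n - n_with,
      prop_with = if (n > 0) n_with / n else 0
    ),
    venn = venn,
    per_genus = per_genus
  )
}
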