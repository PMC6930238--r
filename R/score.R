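#' Genus-level strain tallies
#'
#' Collapses the strain-by-pathway call matrix to per-genus counts: total
#' strains, gut-associated strains, and per metabolite the number of strains
#' (and gut strains) called positive. These tallies feed the three factors
#' of the pathway-potential score.
#'
#' @param matrix A `tryp_call_matrix`.
#' @param collection The `tryp_collection` the matrix was built from.
#' @return Long tibble `genus, phylum, n_strains, n_gut_strains, metabolite,
#'   n_with_pathway, n_gut_with_pathway`.
#' @export
summarize_genus <- function(matrix, collection) {
  man <- collection$manifest
  gut <- man$is_gut_associated %in% c("1", "TRUE", "true")
  long <- tidyr::pivot_longer(tibble::as_tibble(matrix), -"genome_id",
                              names_to = "metabolite", values_to = "present")
  long <- dplyr::left_join(
    long,
    tibble::tibble(genome_id = man$genome_id, genus = man$genus,
                   phylum = man$phylum, gut = gut),
    by = "genome_id"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$genus, .data$phylum, .data$metabolite),
    n_strains = dplyr::n(),
    n_gut_strains = sum(.data$gut),
    n_with_pathway = sum(.data$present),
    n_gut_with_pathway = sum(.data$present & .data$gut),
    .groups = "drop"
  )
  out$metabolite <- factor(out$metabolite, levels = tryp_metabolites())
  out <- dplyr::arrange(out, .data$genus, .data$metabolite)
  out$metabolite <- as.character(out$metabolite)
  out[, c("genus", "phylum", "n_strains", "n_gut_strains", "metabolite",
          "n_with_pathway", "n_gut_with_pathway")]
}

#' Confidence rank of a genus (the score's alpha factor)
#'
#' Genera better represented in the collection get a higher confidence. The
#' genus's strain count is converted to an inclusive percentile among all
#' genera — `100 * (number of genera with count <= this count) / (number of
#' genera)` — and the percentile is mapped to a decile rank
#' `max(1, ceiling(percentile / 10))`, an integer 1..10. The best-represented
#' genus always ranks 10.
#'
#' @param n_strains Strain count(s) of the genus/genera being ranked.
#' @param all_counts Strain counts of every genus in the collection (one
#'   entry per genus).
#' @return Integer vector of ranks in 1..10, same length as `n_strains`.
#' @export
#' @examples
#' confidence_alpha(1:10, 1:10)  # counts 1..10 map to ranks 1..10
confidence_alpha <- function(n_strains, all_counts) {
  if (length(all_counts) == 0) {
    abort_tryp("all_counts must be nonempty", "tryp_argument_error")
  }
  pct <- vapply(n_strains, function(n) {
    100 * sum(all_counts <= n) / length(all_counts)
  }, numeric(1))
  pmax(1L, as.integer(ceiling(pct / 10)))
}

#' Gut weightage of a pathway in a genus (the score's beta factor)
#'
#' Measures enrichment of a pathway among the genus's gut-associated strains
#' relative to its non-gut strains, on a bounded 1..5 scale. With gut
#' prevalence `g = n_gut_with / n_gut_strains` and non-gut prevalence
#' `h = (n_with - n_gut_with) / (n_strains - n_gut_strains)` (either set to 0
#' when its denominator is 0), the gut share `s = g / (g + h)` (0 when both
#' prevalences are 0) is mapped affinely to `beta = 1 + 4 * s`. A pathway
#' found only in gut strains scores 5; equal prevalence scores 3; a pathway
#' absent from gut strains (or absent everywhere) scores 1.
#'
#' @param n_strains,n_gut_strains,n_with_pathway,n_gut_with_pathway Genus
#'   tallies as in [summarize_genus()] (vectorized).
#' @return Numeric vector in `[1, 5]`.
#' @export
gut_weightage_beta <- function(n_strains, n_gut_strains, n_with_pathway,
                               n_gut_with_pathway) {
  g <- ifelse(n_gut_strains > 0, n_gut_with_pathway / n_gut_strains, 0)
  n_other <- n_strains - n_gut_strains
  h <- ifelse(n_other > 0, (n_with_pathway - n_gut_with_pathway) / n_other, 0)
  s <- ifelse(g + h > 0, g / (g + h), 0)
  1 + 4 * s
}

#' Pathway-potential score of a (genus, metabolite) pair
#'
#' The score is the product of three factors: `P`, the proportion of the
#' genus's strains predicted to harbor the pathway (0..1); `alpha`, the
#' genus's confidence rank (1..10, [confidence_alpha()]); and `beta`, the
#' gut weightage (1..5, [gut_weightage_beta()]). The raw product therefore
#' ranges 0..50 and is rescaled linearly to the reported 0..10 scale by
#' dividing by 5.
#'
#' @param P Proportion(s) in `[0, 1]`.
#' @param alpha Integer confidence rank(s) in 1..10.
#' @param beta Gut weightage(s) in `[1, 5]`.
#' @return Tibble with columns `P, alpha, beta, raw, score`.
#' @export
#' @examples
#' scorbpeo(1, 10, 5)      # maximal: raw 50, score 10
#' scorbpeo(0.5, 4, 2)     # raw 4, score 0.8
scorbpeo <- function(P, alpha, beta) {
  if (any(P < 0 | P > 1)) {
    abort_tryp("P must lie in [0, 1]", "tryp_argument_error")
  }
  if (any(alpha != as.integer(alpha) | alpha < 1 | alpha > 10)) {
    abort_tryp("alpha must be an integer in 1..10", "tryp_argument_error")
  }
  if (any(beta < 1 | beta > 5)) {
    abort_tryp("beta must lie in [1, 5]", "tryp_argument_error")
  }
  raw <- P * alpha * beta
  tibble::tibble(P = P, alpha = as.integer(alpha), beta = beta,
                 raw = raw, score = raw / 5)
}

#' Genus-by-metabolite pathway-potential score matrix
#'
#' Composes [summarize_genus()], [confidence_alpha()],
#' [gut_weightage_beta()] and [scorbpeo()] into the full genus x metabolite
#' score table (heat-map content). With `gut_only = TRUE` only genera with
#' at least one gut-associated strain are reported.
#'
#' @inheritParams summarize_genus
#' @param gut_only Restrict rows to genera with gut strains?
#' @return Tibble of class `tryp_score_matrix`: `genus, phylum, metabolite,
#'   n_strains, P, alpha, beta, raw, score`.
#' @export
score_matrix <- function(matrix, collection, gut_only = FALSE) {
  summaries <- summarize_genus(matrix, collection)
  per_genus <- dplyr::distinct(summaries[, c("genus", "n_strains")])
  alpha_tbl <- tibble::tibble(
    genus = per_genus$genus,
    alpha = confidence_alpha(per_genus$n_strains, per_genus$n_strains)
  )
  out <- dplyr::left_join(summaries, alpha_tbl, by = "genus")
  out$P <- out$n_with_pathway / out$n_strains
  out$beta <- gut_weightage_beta(out$n_strains, out$n_gut_strains,
                                 out$n_with_pathway, out$n_gut_with_pathway)
  sc <- scorbpeo(out$P, out$alpha, out$beta)
  out$raw <- sc$raw
  out$score <- sc$score
  if (gut_only) {
    out <- out[out$n_gut_strains > 0, , drop = FALSE]
  }
  out <- out[, c("genus", "phylum", "metabolite", "n_strains", "P", "alpha",
                 "beta", "raw", "score")]
  structure(out, class = c("tryp_score_matrix", class(out)))
}
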