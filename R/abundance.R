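#' Read a case/control genus-abundance table
#'
#' Reads a long-format abundance TSV (`sample_id, genus, count`) and a group
#' TSV (`sample_id, group` with group `case` or `control`) and densifies
#' them: absent (sample, genus) pairs become 0.
#'
#' @param path Long abundance TSV.
#' @param groups_path Sample-group TSV.
#' @return A `tryp_abundance`: list with `data` (tibble `sample_id, group` +
#'   one numeric column per genus) and `normalized` (logical).
#' @export
read_abundance_table <- function(path, groups_path) {
  long <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            genus = readr::col_character(),
                            count = readr::col_double()
                          ))
  need <- c("sample_id", "genus", "count")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0) {
    abort_tryp(paste0("abundance table '", path, "' lacks column(s): ",
                      paste(miss, collapse = ", ")),
               "tryp_format_error")
  }
  if (any(long$count < 0)) {
    abort_tryp(paste0("abundance table '", path, "' contains negative counts"),
               "tryp_format_error")
  }
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort_tryp(paste0("group table '", groups_path,
                      "' must have columns sample_id, group"),
               "tryp_format_error")
  }
  bad_grp <- setdiff(unique(groups$group), c("case", "control"))
  if (length(bad_grp) > 0) {
    abort_tryp(paste0("group table '", groups_path, "': group must be ",
                      "'case' or 'control', got: ",
                      paste(bad_grp, collapse = ", ")),
               "tryp_format_error")
  }
  ungrouped <- setdiff(unique(long$sample_id), groups$sample_id)
  if (length(ungrouped) > 0) {
    abort_tryp(paste0("sample(s) without group label: ",
                      paste(ungrouped, collapse = ", ")),
               "tryp_metadata_error")
  }
  wide <- tidyr::pivot_wider(long, names_from = "genus",
                             values_from = "count", values_fill = 0)
  wide <- dplyr::left_join(wide, groups, by = "sample_id")
  wide <- wide[, c("sample_id", "group",
                   setdiff(names(wide), c("sample_id", "group")))]
  new_abundance(wide, normalized = FALSE)
}

new_abundance <- function(data, normalized) {
  structure(list(data = data, normalized = normalized),
            class = "tryp_abundance")
}

abundance_genera <- function(table) {
  setdiff(names(table$data), c("sample_id", "group"))
}

#' Convert counts to relative abundances
#'
#' Divides every sample's genus counts by the sample total so each row sums
#' to one, and flags the table as normalized.
#'
#' @param table A `tryp_abundance` with raw counts.
#' @return The normalized `tryp_abundance`.
#' @export
relative_abundance <- function(table) {
  if (isTRUE(table$normalized)) {
    abort_tryp("abundance table is already normalized", "tryp_argument_error")
  }
  genera <- abundance_genera(table)
  mat <- as.matrix(table$data[, genera])
  totals <- rowSums(mat)
  if (any(totals <= 0)) {
    bad <- table$data$sample_id[totals <= 0]
    abort_tryp(paste0("cannot normalize all-zero sample(s): ",
                      paste(bad, collapse = ", ")),
               "tryp_normalization_error")
  }
  table$data[, genera] <- mat / totals
  table$normalized <- TRUE
  table
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Tests whether two samples come from distributions differing in location,
#' reporting the rank-sum statistic `W` of `x` (sum of the mid-ranks of `x`
#' in the pooled ranking) and a two-sided p-value. The p-value is exact (by
#' enumeration of rank assignments, via [stats::wilcox.test()]) when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `W` (rank-sum of `x`) and `p_value`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort_tryp("both samples must be non-empty", "tryp_argument_error")
  }
  pooled <- c(x, y)
  W <- sum(rank(pooled)[seq_along(x)])
  use_exact <- length(pooled) <= 20 && !any(duplicated(pooled))
  ht <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  list(W = W, p_value = ht$p.value)
}

#' Differentially abundant genera between case and control
#'
#' Applies the Wilcoxon rank-sum test per genus to case versus control
#' relative abundances and keeps genera with `p <= p_max` (default 0.01, as
#' a raw threshold without multiple-testing adjustment). Direction is
#' assigned from the group medians; if the medians tie the group means
#' decide, and a remaining tie is flagged `ambiguous`.
#'
#' @param table A normalized `tryp_abundance`.
#' @param p_max Raw p-value threshold in `(0, 1]`.
#' @return Tibble `genus, statistic, p_value, direction, median_case,
#'   median_control`, ordered by p-value.
#' @export
differential_genera <- function(table, p_max = 0.01) {
  if (!isTRUE(table$normalized)) {
    abort_tryp("abundance table must be normalized first (relative_abundance)",
               "tryp_argument_error")
  }
  if (p_max <= 0 || p_max > 1) {
    abort_tryp("p_max must lie in (0, 1]", "tryp_argument_error")
  }
  grp <- table$data$group
  if (!all(c("case", "control") %in% grp)) {
    abort_tryp("both case and control samples are required",
               "tryp_argument_error")
  }
  genera <- abundance_genera(table)
  rows <- lapply(genera, function(g) {
    x <- table$data[[g]][grp == "case"]
    y <- table$data[[g]][grp == "control"]
    res <- wilcoxon_rank_sum(x, y)
    med_x <- stats::median(x)
    med_y <- stats::median(y)
    direction <- if (med_x > med_y) {
      "case_enriched"
    } else if (med_x < med_y) {
      "control_enriched"
    } else if (mean(x) > mean(y)) {
      "case_enriched"
    } else if (mean(x) < mean(y)) {
      "control_enriched"
    } else {
      "ambiguous"
    }
    tibble::tibble(genus = g, statistic = res$W, p_value = res$p_value,
                   direction = direction,
                   median_case = med_x, median_control = med_y)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$p_value <= p_max, , drop = FALSE]
  dplyr::arrange(out, .data$p_value, .data$genus)
}

#' Link differential genera to pathway potential
#'
#' For every differentially abundant genus present in the score matrix,
#' emits one edge per metabolite with a positive pathway-potential score,
#' weighted by that score — the content of the genus-to-pathway Sankey
#' diagram. Differential genera absent from the score matrix emit nothing
#' and are reported via a message.
#'
#' @param differentials Tibble from [differential_genera()].
#' @param scores A `tryp_score_matrix` from [score_matrix()].
#' @return Tibble `genus, metabolite, group, scorbpeo_weight, p_value`
#'   ordered by (group, genus, metabolite).
#' @export
pathway_links <- function(differentials, scores) {
  empty <- tibble::tibble(genus = character(), metabolite = character(),
                          group = character(), scorbpeo_weight = double(),
                          p_value = double())
  if (nrow(differentials) == 0) return(empty)
  unknown <- setdiff(differentials$genus, scores$genus)
  for (g in unknown) {
    message("pathway_links: genus '", g,
            "' is differential but absent from the score matrix; skipped")
  }
  diff_tbl <- differentials[!differentials$genus %in% unknown, , drop = FALSE]
  if (nrow(diff_tbl) == 0) return(empty)
  diff_tbl$group <- sub("_enriched$", "", diff_tbl$direction)
  joined <- dplyr::inner_join(
    diff_tbl[, c("genus", "group", "p_value")],
    tibble::as_tibble(scores)[, c("genus", "metabolite", "score")],
    by = "genus", relationship = "many-to-many"
  )
  joined <- joined[joined$score > 0, , drop = FALSE]
  out <- tibble::tibble(
    genus = joined$genus, metabolite = joined$metabolite,
    group = joined$group, scorbpeo_weight = joined$score,
    p_value = joined$p_value
  )
  dplyr::arrange(out, .data$group, .data$genus, .data$metabolite)
}

#' Write a Sankey edge-list document
#'
#' Serializes pathway links as a JSON document with deduplicated `nodes`
#' (genus nodes tagged with their enriched group, metabolite nodes) and
#' `links` (source genus, target metabolite, value = score weight),
#' consumable by standard Sankey renderers. Ordering is deterministic:
#' (group, genus, metabolite).
#'
#' @param links Tibble from [pathway_links()] (may be empty).
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [read_sankey()]
#' @export
write_sankey <- function(links, path) {
  links <- dplyr::arrange(links, .data$group, .data$genus, .data$metabolite)
  genus_nodes <- dplyr::distinct(links[, c("genus", "group")])
  nodes <- c(
    lapply(seq_len(nrow(genus_nodes)), function(i) {
      list(id = genus_nodes$genus[i], type = "genus",
           group = genus_nodes$group[i])
    }),
    lapply(unique(links$metabolite), function(m) {
      list(id = m, type = "metabolite")
    })
  )
  edges <- lapply(seq_len(nrow(links)), function(i) {
    list(source = links$genus[i], target = links$metabolite[i],
         value = links$scorbpeo_weight[i], group = links$group[i],
         p_value = links$p_value[i])
  })
  doc <- list(nodes = nodes, links = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Sankey edge-list document back into a link table
#'
#' Inverse of [write_sankey()] for round-tripping and downstream use.
#'
#' @param path A JSON file written by [write_sankey()].
#' @return Tibble with the same columns as [pathway_links()] output.
#' @export
read_sankey <- function(path) {
  doc <- jsonlite::read_json(path)
  if (length(doc$links) == 0) {
    return(tibble::tibble(genus = character(), metabolite = character(),
                          group = character(), scorbpeo_weight = double(),
                          p_value = double()))
  }
  dplyr::bind_rows(lapply(doc$links, function(e) {
    tibble::tibble(genus = e$source, metabolite = e$target, group = e$group,
                   scorbpeo_weight = e$value, p_value = e$p_value)
  }))
}
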