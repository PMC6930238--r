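#' Configuration for an end-to-end pipeline run
#'
#' @param manifest Path to a genome-collection manifest
#'   ([load_genome_collection()]).
#' @param out_dir Output directory for all report files.
#' @param catalog Optional path to a catalog override YAML
#'   ([load_catalog()]); `NULL` uses [default_catalog()].
#' @param abundance,groups Optional paths to a case/control abundance study
#'   ([read_abundance_table()]); both or neither.
#' @param thresholds A `tryp_thresholds`.
#' @param p_max Raw p-value threshold for differential genera.
#' @param gut_only Restrict the score matrix to genera with gut strains?
#' @param transporters_all Screen all genomes for transporters instead of
#'   only indole producers?
#' @param seed Optional integer seed recorded in the run log (the analysis
#'   itself is deterministic).
#' @return A `tryp_run_config`.
#' @export
run_config <- function(manifest, out_dir, catalog = NULL, abundance = NULL,
                       groups = NULL, thresholds = tryptomine::thresholds(),
                       p_max = 0.01, gut_only = FALSE,
                       transporters_all = FALSE, seed = NULL) {
  if (p_max <= 0 || p_max > 1) {
    abort_tryp("p_max must lie in (0, 1]", "tryp_argument_error")
  }
  if (xor(is.null(abundance), is.null(groups))) {
    abort_tryp("abundance and groups must be given together",
               "tryp_argument_error")
  }
  structure(
    list(manifest = manifest, out_dir = out_dir, catalog = catalog,
         abundance = abundance, groups = groups, thresholds = thresholds,
         p_max = p_max, gut_only = isTRUE(gut_only),
         transporters_all = isTRUE(transporters_all), seed = seed),
    class = "tryp_run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Composes the stages end-to-end: load the genome collection, predict the
#' six pathways per strain, summarize phylum prevalence and gut-level
#' counts, score every (genus, metabolite) pair, profile transporters in the
#' indole producers, and — when an abundance study is configured — call
#' differential genera and write the Sankey edge list linking them to
#' pathway potential. Every table is written as TSV (the Sankey document as
#' JSON) into `out_dir`, together with a machine-readable run log recording
#' the package version, thresholds and mapping choices. Outputs are
#' deterministic given identical inputs and configuration.
#'
#' @param config A `tryp_run_config`.
#' @return Invisibly, a list with the in-memory results and the paths of all
#'   written files.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_tryp(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)),
                 "tryp_pipeline_error")
    })
  }

  catalog <- stage("catalog", {
    if (is.null(config$catalog)) default_catalog() else load_catalog(config$catalog)
  })
  collection <- stage("load", load_genome_collection(config$manifest))
  calls <- stage("predict", build_call_matrix(collection, catalog, t))
  phyla <- stage("phylum_proportions", phylum_proportions(calls, collection))
  gut_counts <- stage("gut_counts", gut_level_counts(calls, collection))
  scores <- stage("score", score_matrix(calls, collection,
                                        gut_only = config$gut_only))

  profiles <- stage("transporters", {
    lapply(names(collection$genomes), function(id) {
      indole <- calls$indole[calls$genome_id == id]
      profile_transporters(collection$genomes[[id]], catalog, t,
                           indole_present = indole,
                           restrict_to_indole = !config$transporters_all)
    })
  })
  trans_summary <- stage("transporter_summary",
                         transporter_summary(profiles, collection))

  paths <- list()
  wr <- function(x, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(x, p)
    paths[[name]] <<- p
    p
  }
  call_out <- tibble::as_tibble(calls)
  call_out[tryp_metabolites()] <- lapply(call_out[tryp_metabolites()],
                                         as.integer)
  wr(call_out, "call_matrix.tsv")
  wr(tidyr::pivot_wider(phyla[, c("phylum", "metabolite", "proportion")],
                        names_from = "metabolite",
                        values_from = "proportion"),
     "phylum_proportions.tsv")
  wr(gut_counts, "gut_counts.tsv")
  wr(tibble::as_tibble(scores), "score_matrix.tsv")
  wr(tidyr::pivot_wider(
    tibble::as_tibble(scores)[, c("genus", "metabolite", "score")],
    names_from = "metabolite", values_from = "score"
  ), "score_matrix_wide.tsv")
  profile_tbl <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(genome_id = p$genome_id, applicable = p$applicable,
                   TnaB = "TnaB" %in% p$transporters,
                   AroP = "AroP" %in% p$transporters,
                   Mtr = "Mtr" %in% p$transporters)
  }))
  wr(profile_tbl, "transporter_profiles.tsv")
  wr(trans_summary$venn, "transporter_venn.tsv")
  wr(trans_summary$per_genus, "transporter_per_genus.tsv")

  differentials <- NULL
  links <- NULL
  if (!is.null(config$abundance)) {
    abundance <- stage("abundance", {
      relative_abundance(read_abundance_table(config$abundance, config$groups))
    })
    differentials <- stage("differential",
                           differential_genera(abundance, config$p_max))
    links <- stage("link", pathway_links(differentials, scores))
    wr(differentials, "differential_genera.tsv")
    p <- file.path(config$out_dir, "sankey.json")
    stage("sankey", write_sankey(links, p))
    paths[["sankey.json"]] <- p
  }

  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(
    list(
      package = "tryptomine",
      version = as.character(utils::packageVersion("tryptomine")),
      config = list(
        manifest = config$manifest, catalog = config$catalog,
        abundance = config$abundance, groups = config$groups,
        thresholds = unclass(t), p_max = config$p_max,
        gut_only = config$gut_only, transporters_all = config$transporters_all,
        seed = config$seed
      ),
      mappings = list(
        alpha = "inclusive strain-count percentile, decile-ceiling to 1..10",
        beta = "gut prevalence share g/(g+h) mapped affinely to [1,5]",
        rescale = "raw score / 5"
      )
    ),
    log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths[["run_log.json"]] <- log_path

  invisible(list(
    collection = collection, calls = calls, phylum_proportions = phyla,
    gut_counts = gut_counts, scores = scores, profiles = profiles,
    transporter_summary = trans_summary, differentials = differentials,
    links = links, paths = paths
  ))
}
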