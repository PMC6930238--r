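#' Design for a synthetic genome collection
#'
#' Describes the genome collection the generator will emit: the genera (with
#' phylum, strain count and gut-strain count), the planted per-genus pathway
#' prevalences (separately for gut and non-gut strains), the probability
#' with which each of the three transporters is planted in an
#' indole-positive strain, a decoy rate, and the seed.
#'
#' @param genera Tibble with columns `genus, phylum, n_strains,
#'   n_gut_strains`.
#' @param planted_prevalence Tibble `genus, metabolite, gut_prev,
#'   nongut_prev` with prevalences in `[0, 1]`. `NULL` applies
#'   [default_prevalence()] to every genus.
#' @param transporter_probs Named numeric probabilities for TnaB/AroP/Mtr
#'   planting in indole-positive strains.
#' @param decoy_domain_rate Per-strain probability of planting decoy
#'   evidence (domains and homolog hits that satisfy no rule).
#' @param seed Integer seed; the same seed reproduces byte-identical files.
#' @return A validated `tryp_collection_design`.
#' @export
collection_design <- function(genera, planted_prevalence = NULL,
                              transporter_probs = c(TnaB = 0.4, AroP = 0.3,
                                                    Mtr = 0.3),
                              decoy_domain_rate = 0.2, seed = 1L) {
  need <- c("genus", "phylum", "n_strains", "n_gut_strains")
  miss <- setdiff(need, names(genera))
  if (length(miss) > 0) {
    abort_tryp(paste0("genera table lacks column(s): ",
                      paste(miss, collapse = ", ")),
               "tryp_argument_error")
  }
  if (any(genera$n_gut_strains > genera$n_strains)) {
    abort_tryp("n_gut_strains must be <= n_strains", "tryp_argument_error")
  }
  if (is.null(planted_prevalence)) {
    planted_prevalence <- tidyr::crossing(
      genus = genera$genus, default_prevalence()
    )
  }
  pv <- c(planted_prevalence$gut_prev, planted_prevalence$nongut_prev)
  if (any(pv < 0 | pv > 1)) {
    abort_tryp("prevalences must lie in [0, 1]", "tryp_argument_error")
  }
  if (decoy_domain_rate < 0 || decoy_domain_rate > 1) {
    abort_tryp("decoy_domain_rate must lie in [0, 1]", "tryp_argument_error")
  }
  structure(
    list(genera = genera, planted_prevalence = planted_prevalence,
         transporter_probs = transporter_probs,
         decoy_domain_rate = decoy_domain_rate, seed = as.integer(seed)),
    class = "tryp_collection_design"
  )
}

#' Default planted pathway prevalences
#'
#' Per-metabolite gut and non-gut prevalences emulating the observed
#' gradient across gut bacteria: indole most common, IAA next, the
#' kynurenine-route and tryptamine pathways intermediate, and the clustered
#' IPA locus rare.
#'
#' @return Tibble `metabolite, gut_prev, nongut_prev`.
#' @export
default_prevalence <- function() {
  tibble::tibble(
    metabolite = tryp_metabolites(),
    gut_prev = c(0.30, 0.30, 0.60, 0.40, 0.15, 0.30),
    nongut_prev = c(0.20, 0.20, 0.30, 0.30, 0.05, 0.20)
  )
}

#' A ready-made 5-genus, 40-strain collection design
#'
#' Five genera across five phyla (eight strains each, gut-strain counts
#' 6/5/6/4/3) under [default_prevalence()] — a desk-scale stand-in for the
#' taxonomic structure of a gut-genome census.
#'
#' @param seed Integer seed.
#' @return A `tryp_collection_design`.
#' @export
example_collection_design <- function(seed = 7L) {
  collection_design(
    genera = tibble::tibble(
      genus = c("Escherichia", "Clostridium", "Bacteroides",
                "Bifidobacterium", "Fusobacterium"),
      phylum = c("Proteobacteria", "Firmicutes", "Bacteroidetes",
                 "Actinobacteria", "Fusobacteria"),
      n_strains = rep(8L, 5),
      n_gut_strains = c(6L, 5L, 6L, 4L, 3L)
    ),
    seed = seed
  )
}

# query-protein lengths used by the generator (and written beside the
# manifest for the readers); decoy_Q is referenced by no catalog rule.
generator_query_lengths <- function() {
  c(tnaA_ECOLI = 471, iaaM_PSESV = 557, ipdC_ENTCL = 552,
    tdc_CLOSG = 470, tdc_RUMGN = 480,
    aroP_ECOLI = 457, aroP_CORGL = 470, mtr_ECOLI = 414,
    decoy_Q = 300)
}

# Fixed gene slots on the 20-gene background contig. Slots never overlap, so
# deleting one planted evidence item affects exactly one pathway.
slot_layout <- function() {
  list(indole = 5L, tnab = 6L, kynurenine = 8L, quinolinate = c(10L, 11L, 12L),
       IAA = 14L, tryptamine = 16L, AroP = 18L, Mtr = 19L,
       decoy_dom = 2L, decoy_hom = 3L)
}

blast_row <- function(query, subject, pident, qlen, evalue, bitscore) {
  paste(query, subject, format(pident, nsmall = 1), qlen,
        round(qlen * 0.05), 0, 1, qlen, 1, qlen,
        format(evalue, scientific = TRUE), bitscore, sep = "\t")
}

domtbl_row <- function(protein, domain_name, accession, evalue, score) {
  paste(protein, "-", 300, domain_name, accession, 200,
        format(evalue, scientific = TRUE), score, 0.0, 1, 1,
        format(evalue, scientific = TRUE),
        format(evalue, scientific = TRUE), score)
}

#' Generate a synthetic genome collection with planted pathway evidence
#'
#' For every strain of the design, draws pathway presence from the planted
#' gut/non-gut prevalences and writes a gene table, a domain-hit table and a
#' homology-hit table in which each planted pathway is satisfied by exactly
#' the default catalog's rule — a PF03301 domain hit for kynurenine, the
#' three quinolinate domains, a passing tryptophanase homolog for indole, a
#' passing homolog of one of the two IAA enzymes, a contiguous five-gene Fld
#' cluster for IPA, and a tryptophan-decarboxylase homolog for tryptamine.
#' Indole-positive strains may additionally receive transporters: a TnaB
#' domain gene planted on the same strand immediately next to the
#' tryptophanase gene, and passing AroP/Mtr homolog hits. Decoy evidence
#' (unlisted Pfam accessions, hits to an unused query, sub-threshold hits)
#' satisfies no rule. Planted evidence values sit far from the thresholds
#' (identity 95, coverage 100, e-values 1e-30 or better) and the planting is
#' minimal-sufficient: removing any single planted item flips its call.
#'
#' @param design A `tryp_collection_design`.
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (path) and `truth`: `calls` (wide tibble of
#'   intended strain calls), `transporters` (tibble `genome_id, applicable,
#'   TnaB, AroP, Mtr`), and `planted` (tibble `genome_id, metabolite, type,
#'   protein_id, key` — one row per planted evidence item, where `key` is
#'   the Pfam accession or query tag). The truth is also written to
#'   `truth.json` in `out_dir`.
#' @export
make_collection <- function(design, out_dir) {
  if (!inherits(design, "tryp_collection_design")) {
    abort_tryp("design must be a tryp_collection_design", "tryp_argument_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slots <- slot_layout()
  qlen <- generator_query_lengths()
  mets <- tryp_metabolites()

  manifest_rows <- list()
  call_rows <- list()
  transporter_rows <- list()
  planted_rows <- list()

  with_seed(design$seed, {
    for (gi in seq_len(nrow(design$genera))) {
      grow <- design$genera[gi, ]
      prev <- design$planted_prevalence[
        design$planted_prevalence$genus == grow$genus, , drop = FALSE]
      for (si in seq_len(grow$n_strains)) {
        genome_id <- sprintf("%s_s%02d", grow$genus, si)
        is_gut <- si <= grow$n_gut_strains
        pcol <- if (is_gut) "gut_prev" else "nongut_prev"
        present <- stats::setNames(vapply(mets, function(m) {
          p <- prev[[pcol]][prev$metabolite == m]
          if (length(p) == 0) p <- 0
          stats::runif(1) < p
        }, logical(1)), mets)

        n_bg <- 20L
        strand <- sample(c("+", "-"), n_bg, replace = TRUE)
        genes <- tibble::tibble(
          gene_id = sprintf("%s_g%03d", genome_id, seq_len(n_bg)),
          protein_id = sprintf("%s_p%03d", genome_id, seq_len(n_bg)),
          contig = "c1",
          start = (seq_len(n_bg) - 1L) * 1000L + 1L,
          end = (seq_len(n_bg) - 1L) * 1000L + 900L,
          strand = strand,
          product = "hypothetical protein"
        )
        dom_lines <- character()
        hom_lines <- character()
        planted <- list()
        plant <- function(metabolite, type, protein, key) {
          planted[[length(planted) + 1L]] <<- tibble::tibble(
            genome_id = genome_id, metabolite = metabolite, type = type,
            protein_id = protein, key = key
          )
        }
        pid <- function(slot) genes$protein_id[slot]

        if (present[["kynurenine"]]) {
          dom_lines <- c(dom_lines, domtbl_row(pid(slots$kynurenine),
                                               "Trp_dioxygenase", "PF03301.5",
                                               1e-30, 250))
          plant("kynurenine", "domain", pid(slots$kynurenine), "PF03301")
        }
        if (present[["quinolinate"]]) {
          accs <- c("PF06052.11", "PF01494.18", "PF00266.18")
          nms <- c("3-HAO", "FAD_binding_3", "Aminotran_5")
          for (k in 1:3) {
            dom_lines <- c(dom_lines, domtbl_row(pid(slots$quinolinate[k]),
                                                 nms[k], accs[k], 1e-25, 200))
            plant("quinolinate", "domain", pid(slots$quinolinate[k]),
                  pfam_strip_version(accs[k]))
          }
        }
        if (present[["indole"]]) {
          hom_lines <- c(hom_lines, blast_row("tnaA_ECOLI", pid(slots$indole),
                                              95.0, qlen[["tnaA_ECOLI"]],
                                              1e-50, 800))
          plant("indole", "homolog", pid(slots$indole), "tnaA_ECOLI")
        }
        if (present[["IAA"]]) {
          q <- sample(c("iaaM_PSESV", "ipdC_ENTCL"), 1)
          hom_lines <- c(hom_lines, blast_row(q, pid(slots$IAA), 95.0,
                                              qlen[[q]], 1e-45, 750))
          plant("IAA", "homolog", pid(slots$IAA), q)
        }
        if (present[["tryptamine"]]) {
          q <- sample(c("tdc_CLOSG", "tdc_RUMGN"), 1)
          hom_lines <- c(hom_lines, blast_row(q, pid(slots$tryptamine), 95.0,
                                              qlen[[q]], 1e-45, 740))
          plant("tryptamine", "homolog", pid(slots$tryptamine), q)
        }
        if (present[["IPA"]]) {
          fld <- c(FldA = "PF90001", FldB = "PF90002", FldC = "PF90003",
                   FldI = "PF90004", FldL = "PF90005")
          for (k in seq_along(fld)) {
            idx <- n_bg + k
            genes <- dplyr::bind_rows(genes, tibble::tibble(
              gene_id = sprintf("%s_g%03d", genome_id, idx),
              protein_id = sprintf("%s_p%03d", genome_id, idx),
              contig = "c1",
              start = (idx - 1L) * 1000L + 1L,
              end = (idx - 1L) * 1000L + 900L,
              strand = sample(c("+", "-"), 1),
              product = paste0(names(fld)[k], " phenyllactate dehydratase locus")
            ))
            dom_lines <- c(dom_lines, domtbl_row(
              genes$protein_id[nrow(genes)], names(fld)[k], fld[[k]],
              1e-30, 220))
            plant("IPA", "domain", genes$protein_id[nrow(genes)], fld[[k]])
          }
        }

        # transporters: only meaningful for indole producers
        trans <- c(TnaB = FALSE, AroP = FALSE, Mtr = FALSE)
        if (present[["indole"]]) {
          trans <- vapply(names(trans), function(tr) {
            stats::runif(1) < design$transporter_probs[[tr]]
          }, logical(1))
          if (trans[["TnaB"]]) {
            genes$strand[slots$tnab] <- genes$strand[slots$indole]
            dom_lines <- c(dom_lines, domtbl_row(pid(slots$tnab), "TnaB_dom",
                                                 "PF90006", 1e-30, 210))
            plant("transporter:TnaB", "domain", pid(slots$tnab), "PF90006")
          }
          if (trans[["AroP"]]) {
            hom_lines <- c(hom_lines, blast_row("aroP_ECOLI", pid(slots$AroP),
                                                95.0, qlen[["aroP_ECOLI"]],
                                                1e-40, 700))
            plant("transporter:AroP", "homolog", pid(slots$AroP), "aroP_ECOLI")
          }
          if (trans[["Mtr"]]) {
            hom_lines <- c(hom_lines, blast_row("mtr_ECOLI", pid(slots$Mtr),
                                                95.0, qlen[["mtr_ECOLI"]],
                                                1e-40, 690))
            plant("transporter:Mtr", "homolog", pid(slots$Mtr), "mtr_ECOLI")
          }
        }

        if (stats::runif(1) < design$decoy_domain_rate) {
          acc <- sample(c("PF11111", "PF22222", "PF33333"), 1)
          dom_lines <- c(dom_lines, domtbl_row(pid(slots$decoy_dom),
                                               "decoy_dom", acc, 1e-20, 150))
          hom_lines <- c(hom_lines, blast_row("decoy_Q", pid(slots$decoy_hom),
                                              99.0, qlen[["decoy_Q"]],
                                              1e-40, 600))
          # sub-threshold hit to a real query: must never satisfy a rule
          hom_lines <- c(hom_lines, blast_row("tnaA_ECOLI",
                                              pid(slots$decoy_hom), 40.0,
                                              qlen[["tnaA_ECOLI"]], 1e-40, 200))
        }

        gene_path <- paste0(genome_id, "_genes.tsv")
        dom_path <- paste0(genome_id, "_domains.txt")
        hom_path <- paste0(genome_id, "_blast.tsv")
        # shuffle row order on disk; readers re-sort and assign ranks
        readr::write_tsv(genes[sample(nrow(genes)), ],
                         file.path(out_dir, gene_path))
        writeLines(c("# synthetic domtblout", "#", dom_lines),
                   file.path(out_dir, dom_path))
        writeLines(hom_lines, file.path(out_dir, hom_path))

        manifest_rows[[length(manifest_rows) + 1L]] <- tibble::tibble(
          genome_id = genome_id, phylum = grow$phylum, genus = grow$genus,
          species = paste0(grow$genus, " sp."), strain = sprintf("s%02d", si),
          is_gut_associated = as.integer(is_gut),
          gene_table = gene_path, domain_table = dom_path,
          homology_table = hom_path
        )
        call_rows[[length(call_rows) + 1L]] <- tibble::tibble(
          genome_id = genome_id, metabolite = mets,
          present = unname(present)
        )
        transporter_rows[[length(transporter_rows) + 1L]] <- tibble::tibble(
          genome_id = genome_id, applicable = present[["indole"]],
          TnaB = unname(trans[["TnaB"]]), AroP = unname(trans[["AroP"]]),
          Mtr = unname(trans[["Mtr"]])
        )
        planted_rows <- c(planted_rows, planted)
      }
    }
  })

  manifest <- dplyr::bind_rows(manifest_rows)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  readr::write_tsv(
    tibble::tibble(query_tag = names(generator_query_lengths()),
                   length = unname(generator_query_lengths())),
    file.path(out_dir, "query_lengths.tsv")
  )

  calls_long <- dplyr::bind_rows(call_rows)
  calls <- tidyr::pivot_wider(calls_long, names_from = "metabolite",
                              values_from = "present")
  calls <- dplyr::arrange(calls, .data$genome_id)
  truth <- list(
    calls = calls,
    transporters = dplyr::arrange(dplyr::bind_rows(transporter_rows),
                                  .data$genome_id),
    planted = if (length(planted_rows)) {
      dplyr::bind_rows(planted_rows)
    } else {
      tibble::tibble(genome_id = character(), metabolite = character(),
                     type = character(), protein_id = character(),
                     key = character())
    }
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest_path, truth = truth)
}

#' Design for a synthetic case/control abundance study
#'
#' Describes a genus-level 16S-style study: cohort sizes, genera, a
#' log-normal composition model (per-genus baseline log-abundances drawn
#' once from `N(0, log_mean_sd)`, per-sample noise `N(0, log_sd)`), planted
#' fold changes applied to case samples before renormalization, and a
#' sequencing-depth range.
#'
#' @param n_case,n_control Cohort sizes.
#' @param genera Character vector of genus names.
#' @param log_mean_sd SD of the between-genus baseline log-abundances.
#' @param log_sd Within-group per-sample log-abundance SD.
#' @param effect_genera Named numeric vector of fold changes (> 0) applied
#'   to case samples; names must be genera.
#' @param depth_range Integer range (min, max) of per-sample total counts.
#' @param seed Integer seed.
#' @return A validated `tryp_study_design`.
#' @export
study_design <- function(n_case = 15L, n_control = 15L,
                         genera = sprintf("Genus%02d", 1:20),
                         log_mean_sd = 1, log_sd = 0.5,
                         effect_genera = c(Genus01 = 4, Genus02 = 4),
                         depth_range = c(20000L, 50000L), seed = 1L) {
  if (n_case < 1 || n_control < 1) {
    abort_tryp("cohort sizes must be >= 1", "tryp_argument_error")
  }
  if (length(effect_genera) > 0) {
    if (any(effect_genera <= 0)) {
      abort_tryp("fold changes must be > 0", "tryp_argument_error")
    }
    bad <- setdiff(names(effect_genera), genera)
    if (length(bad) > 0) {
      abort_tryp(paste0("effect genera not in design: ",
                        paste(bad, collapse = ", ")),
                 "tryp_argument_error")
    }
  }
  if (any(depth_range < 1) || depth_range[2] < depth_range[1]) {
    abort_tryp("depth_range must be an increasing pair of depths >= 1",
               "tryp_argument_error")
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         genera = genera, log_mean_sd = log_mean_sd, log_sd = log_sd,
         effect_genera = effect_genera,
         depth_range = as.integer(depth_range), seed = as.integer(seed)),
    class = "tryp_study_design"
  )
}

#' Generate a synthetic case/control abundance study
#'
#' Draws each sample's genus composition from the design's log-normal model,
#' multiplies case compositions of the effect genera by their fold change,
#' renormalizes, scales to a sampled sequencing depth and rounds to counts.
#' Zero cells are omitted from the long file (the reader densifies them).
#'
#' @param design A `tryp_study_design`.
#' @param out_dir Output directory (created if needed).
#' @return List with `abundance` (path), `groups` (path) and `truth`
#'   (list with `effect_genera`).
#' @export
make_abundance_study <- function(design, out_dir) {
  if (!inherits(design, "tryp_study_design")) {
    abort_tryp("design must be a tryp_study_design", "tryp_argument_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_g <- length(design$genera)
  samples <- c(sprintf("case%02d", seq_len(design$n_case)),
               sprintf("ctrl%02d", seq_len(design$n_control)))
  groups <- c(rep("case", design$n_case), rep("control", design$n_control))

  long <- with_seed(design$seed, {
    mu <- stats::rnorm(n_g, 0, design$log_mean_sd)
    rows <- lapply(seq_along(samples), function(i) {
      v <- exp(stats::rnorm(n_g, mu, design$log_sd))
      if (groups[i] == "case" && length(design$effect_genera) > 0) {
        idx <- match(names(design$effect_genera), design$genera)
        v[idx] <- v[idx] * design$effect_genera
      }
      p <- v / sum(v)
      depth <- sample(seq(design$depth_range[1], design$depth_range[2]), 1)
      tibble::tibble(sample_id = samples[i], genus = design$genera,
                     count = round(depth * p))
    })
    dplyr::bind_rows(rows)
  })
  long <- long[long$count > 0, , drop = FALSE]

  abundance_path <- file.path(out_dir, "abundance.tsv")
  groups_path <- file.path(out_dir, "groups.tsv")
  readr::write_tsv(long, abundance_path)
  readr::write_tsv(tibble::tibble(sample_id = samples, group = groups),
                   groups_path)
  truth <- list(effect_genera = design$effect_genera)
  jsonlite::write_json(truth, file.path(out_dir, "truth_study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(abundance = abundance_path, groups = groups_path, truth = truth)
}
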