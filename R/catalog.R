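#' Pathway rulebook: enzymes, pathway rules and transporter specs
#'
#' A catalog is the machine-readable rulebook the predictor applies to each
#' genome. It holds three sections:
#'
#' * `enzymes` — named enzyme specifications. Each spec carries an EC number
#'   (may be empty), an `evidence_kind` (`"domain"`: presence of a Pfam
#'   functional domain; `"homolog"`: a BLAST hit to a characterized query
#'   protein passing identity/coverage/e-value thresholds), the Pfam
#'   accessions and/or homolog `queries` that supply the evidence.
#' * `pathways` — one rule per metabolite. A rule is satisfied when all
#'   enzymes in `all_of` and at least one in `any_of` (when non-empty) are
#'   evidenced; a rule may additionally carry a `cluster` requirement forcing
#'   the member enzymes' genes to co-locate on one contig within a maximum
#'   number of intervening genes.
#' * `transporters` — the tryptophan importers TnaB, AroP and Mtr. TnaB is
#'   detected by genomic proximity of its functional-domain gene to a
#'   tryptophanase gene (the pair is operonic in *E. coli*); AroP and Mtr by
#'   protein homology.
#'
#' @name catalog
NULL

enzyme_spec <- function(name, ec = "", evidence_kind = c("domain", "homolog"),
                        pfam = character(), queries = character()) {
  evidence_kind <- match.arg(evidence_kind)
  list(
    name = name, ec = ec, evidence_kind = evidence_kind,
    pfam = as.character(pfam), queries = as.character(queries)
  )
}

pathway_rule <- function(metabolite, all_of = character(), any_of = character(),
                         cluster = NULL) {
  list(
    metabolite = metabolite,
    all_of = as.character(all_of), any_of = as.character(any_of),
    cluster = cluster
  )
}

cluster_requirement <- function(roles, max_gap_genes = 3L,
                                same_contig = TRUE, same_strand = FALSE) {
  list(
    roles = as.character(roles),
    max_gap_genes = as.integer(max_gap_genes),
    same_contig = isTRUE(same_contig),
    same_strand = isTRUE(same_strand)
  )
}

transporter_spec <- function(name, mode = c("homolog", "proximity_to_anchor"),
                             anchor = NULL, pfam = character(),
                             queries = character()) {
  mode <- match.arg(mode)
  list(
    name = name, mode = mode, anchor = anchor,
    pfam = as.character(pfam), queries = as.character(queries)
  )
}

new_catalog <- function(enzymes, pathways, transporters) {
  structure(
    list(enzymes = enzymes, pathways = pathways, transporters = transporters),
    class = "tryp_catalog"
  )
}

#' Default pathway catalog for the six tryptophan metabolites
#'
#' Returns the shipped rulebook:
#'
#' * **kynurenine** — presence of the tryptophan 2,3-dioxygenase (TDO) domain
#'   Trp_dioxygenase (PF03301). TDO catalyzes the rate-limiting oxidation of
#'   L-tryptophan and its domain is pathway-specific, so the domain alone
#'   predicts the pathway.
#' * **quinolinate** — presence of all three domains of the downstream
#'   kynurenine-pathway enzymes: 3-HAO (PF06052, enzyme HAD), FAD_binding_3
#'   (PF01494, enzyme KMO) and Aminotran_5 (PF00266, enzyme KYN). The three
#'   genes are not reliably clustered, so domain presence is ANDed without a
#'   proximity requirement.
#' * **indole** — a tryptophanase (EC 4.1.99.1) protein homolog passing the
#'   BLAST thresholds; the tryptophanase domain (Beta_elim_lyase) occurs in
#'   many unrelated enzymes, so whole-protein homology is used instead.
#' * **IAA** — a homolog of tryptophan 2-monooxygenase (EC 1.13.12.3) *or* of
#'   indolepyruvate decarboxylase (EC 4.1.1.74): the two are alternate routes
#'   characterized in different organisms, so either alone suffices.
#' * **IPA** — domains for all five phenyllactate-dehydratase locus roles
#'   (FldA, FldB, FldC, the activator FldI and AMP-binding FldL), whose genes
#'   must additionally form a cluster on one contig (default at most 3
#'   intervening genes between consecutive members, strand-free).
#' * **tryptamine** — a homolog of tryptophan decarboxylase (EC 4.1.1.28)
#'   characterized in *Clostridium sporogenes* or *Ruminococcus gnavus*.
#'
#' The Fld* and TnaB Pfam accessions and the homolog query identifiers shipped
#' here are synthetic placeholders (PF9xxxx series, `*_ECOLI`-style tags):
#' stand-ins to be overridden with curated accessions via [load_catalog()].
#' The pathway-defining accessions PF03301/PF06052/PF01494/PF00266 are the
#' curated ones.
#'
#' @return A `tryp_catalog` object; see [catalog].
#' @seealso [validate_catalog()], [load_catalog()], [dump_catalog()]
#' @export
#' @examples
#' cat <- default_catalog()
#' names(cat$pathways)
default_catalog <- function() {
  enzymes <- list(
    TDO = enzyme_spec("TDO", "1.13.11.11", "domain", pfam = "PF03301"),
    KMO = enzyme_spec("KMO", "1.14.13.9", "domain", pfam = "PF01494"),
    KYN = enzyme_spec("KYN", "3.7.1.3", "domain", pfam = "PF00266"),
    HAD = enzyme_spec("HAD", "1.13.11.6", "domain", pfam = "PF06052"),
    tryptophanase = enzyme_spec("tryptophanase", "4.1.99.1", "homolog",
                                queries = "tnaA_ECOLI"),
    tryptophan_2_monooxygenase = enzyme_spec(
      "tryptophan_2_monooxygenase", "1.13.12.3", "homolog",
      queries = "iaaM_PSESV"
    ),
    indolepyruvate_decarboxylase = enzyme_spec(
      "indolepyruvate_decarboxylase", "4.1.1.74", "homolog",
      queries = "ipdC_ENTCL"
    ),
    tryptophan_decarboxylase = enzyme_spec(
      "tryptophan_decarboxylase", "4.1.1.28", "homolog",
      queries = c("tdc_CLOSG", "tdc_RUMGN")
    ),
    # Synthetic placeholder accessions for the IPA locus roles (see docs).
    FldA = enzyme_spec("FldA", "", "domain", pfam = "PF90001"),
    FldB = enzyme_spec("FldB", "", "domain", pfam = "PF90002"),
    FldC = enzyme_spec("FldC", "", "domain", pfam = "PF90003"),
    FldI = enzyme_spec("FldI", "", "domain", pfam = "PF90004"),
    FldL = enzyme_spec("FldL", "", "domain", pfam = "PF90005")
  )
  fld_roles <- c("FldA", "FldB", "FldC", "FldI", "FldL")
  pathways <- list(
    kynurenine = pathway_rule("kynurenine", all_of = "TDO"),
    quinolinate = pathway_rule("quinolinate", all_of = c("HAD", "KMO", "KYN")),
    indole = pathway_rule("indole", all_of = "tryptophanase"),
    IAA = pathway_rule("IAA", any_of = c("tryptophan_2_monooxygenase",
                                         "indolepyruvate_decarboxylase")),
    IPA = pathway_rule("IPA", all_of = fld_roles,
                       cluster = cluster_requirement(fld_roles,
                                                     max_gap_genes = 3L,
                                                     same_strand = FALSE)),
    tryptamine = pathway_rule("tryptamine", all_of = "tryptophan_decarboxylase")
  )
  transporters <- list(
    TnaB = transporter_spec("TnaB", "proximity_to_anchor",
                            anchor = "tryptophanase", pfam = "PF90006"),
    AroP = transporter_spec("AroP", "homolog",
                            queries = c("aroP_ECOLI", "aroP_CORGL")),
    Mtr = transporter_spec("Mtr", "homolog", queries = "mtr_ECOLI")
  )
  new_catalog(enzymes, pathways, transporters)
}

#' Validate a pathway catalog
#'
#' Checks every structural invariant of a catalog and returns the violations
#' as a character vector (empty when the catalog is valid). Violations are
#' returned, not raised, so callers can report them all at once.
#'
#' Checked invariants: exactly one pathway rule per metabolite (six rules in
#' all); every rule references only enzymes defined in the catalog and has a
#' non-empty logic; Pfam accessions match `PF` + 5 digits (an ignored version
#' suffix is permitted); domain-evidence enzymes carry at least one accession
#' and homolog-evidence enzymes at least one query tag; cluster requirements
#' have at least two roles, a non-negative gap and resolvable roles; exactly
#' the three transporters TnaB (proximity to a defined anchor enzyme), AroP
#' and Mtr (homolog mode with queries) are present.
#'
#' @param catalog A `tryp_catalog`.
#' @return Character vector of human-readable violations; `character(0)` if
#'   valid.
#' @export
#' @examples
#' validate_catalog(default_catalog())
validate_catalog <- function(catalog) {
  v <- character()
  note <- function(...) v <<- c(v, paste0(...))

  enz_names <- names(catalog$enzymes)
  for (e in catalog$enzymes) {
    bad <- e$pfam[!is_pfam_accession(e$pfam)]
    for (b in bad) {
      note("enzyme '", e$name, "': accession '", b,
           "' does not match the Pfam pattern PF+5 digits")
    }
    if (e$evidence_kind == "domain" && length(e$pfam) == 0) {
      note("enzyme '", e$name, "': domain evidence requires >=1 Pfam accession")
    }
    if (e$evidence_kind == "homolog" && length(e$queries) == 0) {
      note("enzyme '", e$name, "': homolog evidence requires >=1 query tag")
    }
  }

  missing <- setdiff(tryp_metabolites(), names(catalog$pathways))
  for (m in missing) note("catalog lacks a pathway rule for metabolite '", m, "'")
  extra <- setdiff(names(catalog$pathways), tryp_metabolites())
  for (m in extra) note("pathway rule '", m, "' is not one of the six metabolites")

  for (p in catalog$pathways) {
    leaves <- c(p$all_of, p$any_of)
    if (length(leaves) == 0) {
      note("pathway '", p$metabolite, "': empty logic tree")
    }
    for (leaf in setdiff(leaves, enz_names)) {
      note("pathway '", p$metabolite, "': leaf '", leaf,
           "' references an undefined enzyme")
    }
    if (!is.null(p$cluster)) {
      cl <- p$cluster
      if (length(cl$roles) < 2) {
        note("pathway '", p$metabolite, "': cluster requires >=2 member roles")
      }
      if (cl$max_gap_genes < 0) {
        note("pathway '", p$metabolite, "': cluster max_gap_genes must be >= 0")
      }
      for (r in setdiff(cl$roles, enz_names)) {
        note("pathway '", p$metabolite, "': cluster role '", r,
             "' references an undefined enzyme")
      }
    }
  }

  want <- c("TnaB", "AroP", "Mtr")
  for (m in setdiff(want, names(catalog$transporters))) {
    note("catalog lacks transporter spec '", m, "'")
  }
  for (m in setdiff(names(catalog$transporters), want)) {
    note("transporter '", m, "' is not one of TnaB/AroP/Mtr")
  }
  tnab <- catalog$transporters$TnaB
  if (!is.null(tnab)) {
    if (!identical(tnab$mode, "proximity_to_anchor")) {
      note("transporter 'TnaB': mode must be proximity_to_anchor")
    }
    if (is.null(tnab$anchor) || !tnab$anchor %in% enz_names) {
      note("transporter 'TnaB': anchor enzyme missing or undefined")
    }
    if (length(tnab$pfam) == 0) {
      note("transporter 'TnaB': requires >=1 Pfam accession")
    }
    bad <- tnab$pfam[!is_pfam_accession(tnab$pfam)]
    for (b in bad) note("transporter 'TnaB': accession '", b, "' malformed")
  }
  for (nm in c("AroP", "Mtr")) {
    sp <- catalog$transporters[[nm]]
    if (is.null(sp)) next
    if (!identical(sp$mode, "homolog")) {
      note("transporter '", nm, "': mode must be homolog")
    }
    if (length(sp$queries) == 0) {
      note("transporter '", nm, "': requires >=1 query tag")
    }
  }
  v
}

catalog_to_list <- function(catalog) {
  list(
    enzymes = lapply(catalog$enzymes, function(e) {
      list(ec = e$ec, evidence_kind = e$evidence_kind,
           pfam = as.list(e$pfam), queries = as.list(e$queries))
    }),
    pathways = lapply(catalog$pathways, function(p) {
      out <- list(all_of = as.list(p$all_of), any_of = as.list(p$any_of))
      if (!is.null(p$cluster)) {
        out$cluster <- list(
          roles = as.list(p$cluster$roles),
          max_gap_genes = p$cluster$max_gap_genes,
          same_contig = p$cluster$same_contig,
          same_strand = p$cluster$same_strand
        )
      }
      out
    }),
    transporters = lapply(catalog$transporters, function(s) {
      list(mode = s$mode, anchor = s$anchor,
           pfam = as.list(s$pfam), queries = as.list(s$queries))
    })
  )
}

list_to_catalog <- function(x) {
  chr <- function(v) as.character(unlist(v))
  enzymes <- lapply(names(x$enzymes), function(nm) {
    e <- x$enzymes[[nm]]
    enzyme_spec(nm, ec = e$ec %||% "", evidence_kind = e$evidence_kind,
                pfam = chr(e$pfam), queries = chr(e$queries))
  })
  names(enzymes) <- names(x$enzymes)
  pathways <- lapply(names(x$pathways), function(nm) {
    p <- x$pathways[[nm]]
    cl <- NULL
    if (!is.null(p$cluster)) {
      cl <- cluster_requirement(
        chr(p$cluster$roles),
        max_gap_genes = p$cluster$max_gap_genes %||% 3L,
        same_contig = p$cluster$same_contig %||% TRUE,
        same_strand = p$cluster$same_strand %||% FALSE
      )
    }
    pathway_rule(nm, all_of = chr(p$all_of), any_of = chr(p$any_of),
                 cluster = cl)
  })
  names(pathways) <- names(x$pathways)
  transporters <- lapply(names(x$transporters), function(nm) {
    s <- x$transporters[[nm]]
    transporter_spec(nm, mode = s$mode, anchor = s$anchor,
                     pfam = chr(s$pfam), queries = chr(s$queries))
  })
  names(transporters) <- names(x$transporters)
  new_catalog(enzymes, pathways, transporters)
}

# Recursive merge of an override list onto the default list representation.
merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write a catalog to a YAML config file
#'
#' The written file is a complete dump: [load_catalog()] on it reproduces the
#' catalog field-for-field.
#'
#' @param catalog A `tryp_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_catalog <- function(catalog, path) {
  yaml::write_yaml(catalog_to_list(catalog), path)
  invisible(path)
}

#' Load a catalog from a YAML config file
#'
#' The config file may be partial: any field it does not set is inherited
#' from [default_catalog()]. Sections are merged per name and per field, so a
#' config containing only `pathways: {IPA: {cluster: {max_gap_genes: 5}}}`
#' changes exactly that one value.
#'
#' @param path Path to a YAML file with optional sections `enzymes`,
#'   `pathways`, `transporters`.
#' @return A validated `tryp_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    abort_tryp(paste0("catalog config not found: ", path), "tryp_config_error")
  }
  parsed <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort_tryp(paste0("catalog config '", path, "' failed to parse: ",
                        conditionMessage(e)),
                 "tryp_config_error")
    }
  )
  merged <- merge_lists(catalog_to_list(default_catalog()), parsed)
  catalog <- list_to_catalog(merged)
  violations <- validate_catalog(catalog)
  if (length(violations) > 0) {
    abort_tryp(paste0("catalog config '", path, "' is invalid:\n",
                      paste0("- ", violations, collapse = "\n")),
               "tryp_validation_error")
  }
  catalog
}

#' @export
print.tryp_catalog <- function(x, ...) {
  cat("<tryp_catalog>\n")
  cat("  enzymes:     ", paste(names(x$enzymes), collapse = ", "), "\n")
  cat("  pathways:    ", paste(names(x$pathways), collapse = ", "), "\n")
  cat("  transporters:", paste(names(x$transporters), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
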