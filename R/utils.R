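#' The six neuro-active tryptophan metabolites
#'
#' Canonical order of the six tryptophan-derived neuro-active metabolites the
#' package predicts: kynurenine, quinolinate, indole, indole acetic acid
#' (IAA), indole propionic acid (IPA) and tryptamine.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' tryp_metabolites()
tryp_metabolites <- function() {
  c("kynurenine", "quinolinate", "indole", "IAA", "IPA", "tryptamine")
}

# Pfam accessions compare versionless: "PF06052.11" == "PF06052".
pfam_strip_version <- function(x) sub("\\.[0-9]+$", "", x)

is_pfam_accession <- function(x) {
  grepl("^PF[0-9]{5}(\\.[0-9]+)?$", x)
}

pfam_match <- function(x, accession) {
  pfam_strip_version(x) == pfam_strip_version(accession)
}

abort_tryp <- function(msg, class) {
  rlang::abort(msg, class = c(class, "tryptomine_error"))
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
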