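test_that("a lone TDO domain predicts kynurenine and nothing else", {
  g <- toy_genome(domain_hits = domain_hit("p001", "PF03301", evalue = 1e-20))
  calls <- predict_strain(g)
  expect_identical(calls$metabolite, tryp_metabolites())
  expect_identical(calls$present, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("quinolinate needs all three domains (AND semantics)", {
  two <- toy_genome(domain_hits = rbind(domain_hit("p001", "PF06052.11"),
                                        domain_hit("p002", "PF01494.18")))
  calls <- predict_strain(two)
  expect_false(calls$present[calls$metabolite == "quinolinate"])

  three <- toy_genome(domain_hits = rbind(domain_hit("p001", "PF06052.11"),
                                          domain_hit("p002", "PF01494.18"),
                                          domain_hit("p003", "PF00266.18")))
  calls3 <- predict_strain(three)
  expect_true(calls3$present[calls3$metabolite == "quinolinate"])
})

test_that("either IAA-route homolog alone suffices (OR semantics)", {
  for (q in c("iaaM_PSESV", "ipdC_ENTCL")) {
    g <- toy_genome(homology_hits = homology_hit(q, "p001"))
    calls <- predict_strain(g)
    expect_true(calls$present[calls$metabolite == "IAA"])
  }
})

test_that("IPA requires the five Fld domains to cluster within the gap", {
  fld <- c("PF90001", "PF90002", "PF90003", "PF90004", "PF90005")
  contiguous <- toy_genome(domain_hits = dplyr::bind_rows(lapply(1:5, function(k) {
    domain_hit(sprintf("p%03d", 4 + k), fld[k])
  })))
  calls <- predict_strain(contiguous)
  expect_true(calls$present[calls$metabolite == "IPA"])

  # same domains scattered further apart than max_gap = 3
  scattered <- toy_genome(n_genes = 30, domain_hits = dplyr::bind_rows(
    lapply(1:5, function(k) domain_hit(sprintf("p%03d", 6 * k - 5), fld[k]))
  ))
  calls2 <- predict_strain(scattered)
  expect_false(calls2$present[calls2$metabolite == "IPA"])
  # ... but the domain leaves themselves are satisfied (the cluster fails)
  ev <- calls2$evidence[[which(calls2$metabolite == "IPA")]]
  expect_true(all(ev$satisfied[ev$leaf != "cluster"]))
  expect_false(ev$satisfied[ev$leaf == "cluster"])
})

test_that("every true call carries at least one satisfied supporting leaf", {
  dir <- withr::local_tempdir()
  res <- make_collection(collection_design(
    genera = tibble::tibble(genus = "A", phylum = "P1", n_strains = 6L,
                            n_gut_strains = 3L), seed = 13
  ), dir)
  coll <- load_genome_collection(res$manifest)
  for (g in coll$genomes) {
    calls <- predict_strain(g)
    for (i in which(calls$present)) {
      ev <- calls$evidence[[i]]
      expect_true(any(ev$satisfied))
    }
  }
})

test_that("predictions are invariant to hit-table row order", {
  g <- toy_genome(
    domain_hits = rbind(domain_hit("p001", "PF06052"),
                        domain_hit("p002", "PF01494"),
                        domain_hit("p003", "PF00266")),
    homology_hits = rbind(homology_hit("tnaA_ECOLI", "p004"),
                          homology_hit("tdc_CLOSG", "p005"))
  )
  g2 <- g
  g2$domain_hits <- g2$domain_hits[3:1, ]
  g2$homology_hits <- g2$homology_hits[2:1, ]
  expect_identical(predict_strain(g)[, c("metabolite", "present")],
                   predict_strain(g2)[, c("metabolite", "present")])
})

test_that("adding evidence never turns a true call false", {
  base <- toy_genome(
    domain_hits = domain_hit("p001", "PF03301"),
    homology_hits = homology_hit("tnaA_ECOLI", "p004")
  )
  before <- predict_strain(base)
  more <- base
  more$domain_hits <- rbind(more$domain_hits, domain_hit("p006", "PF06052"))
  more$homology_hits <- rbind(more$homology_hits,
                              homology_hit("ipdC_ENTCL", "p007"))
  after <- predict_strain(more)
  expect_true(all(after$present >= before$present))
})

test_that("phylum proportions and gut counts tally correctly", {
  genomes <- lapply(1:4, function(i) {
    toy_genome(genome_id = paste0("G", i), genus = "Escherichia",
               phylum = "Proteobacteria", gut = i <= 2,
               homology_hits = if (i <= 3) {
                 homology_hit("tnaA_ECOLI", "p004")
               } else {
                 NULL
               })
  })
  coll <- genome_collection(genomes)
  m <- build_call_matrix(coll)
  props <- phylum_proportions(m, coll)
  indole <- props[props$metabolite == "indole", ]
  expect_equal(indole$proportion, 0.75)
  expect_equal(props$proportion[props$metabolite == "IPA"], 0)

  counts <- gut_level_counts(m, coll)
  expect_identical(
    unlist(counts[counts$metabolite == "indole",
                  c("n_phyla", "n_genera", "n_strains")], use.names = FALSE),
    c(1L, 1L, 2L)
  )
  expect_identical(sum(counts$n_strains[counts$metabolite == "IPA"]), 0L)
})
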