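test_that("homology filtering is inclusive at all three boundaries", {
  t <- thresholds()
  at <- homology_hit("q", "p001", percent_identity = 70,
                     alignment_length = 450L, query_length = 500L,
                     evalue = 1e-5)  # coverage exactly 90
  expect_identical(nrow(filter_homology_hits(at, t)), 1L)

  eps_id <- at; eps_id$percent_identity <- 69.999
  eps_cov <- at; eps_cov$alignment_length <- 449L
  eps_ev <- at; eps_ev$evalue <- 1.001e-5
  expect_identical(nrow(filter_homology_hits(eps_id, t)), 0L)
  expect_identical(nrow(filter_homology_hits(eps_cov, t)), 0L)
  expect_identical(nrow(filter_homology_hits(eps_ev, t)), 0L)
})

test_that("coverage clips at 100 for gapped alignments longer than the query", {
  h <- homology_hit("q", "p001", alignment_length = 620L, query_length = 500L)
  expect_identical(nrow(filter_homology_hits(h, thresholds())), 1L)
})

test_that("homology filter equals the per-hit predicate on random tables", {
  set.seed(42)
  n <- 200
  hits <- tibble::tibble(
    query_tag = "q", subject_protein_id = sprintf("p%03d", 1:n),
    percent_identity = runif(n, 50, 100),
    alignment_length = as.integer(round(runif(n, 300, 600))),
    evalue = 10^runif(n, -60, -2), bitscore = runif(n, 50, 900),
    query_length = 500L
  )
  t <- thresholds()
  got <- filter_homology_hits(hits, t)
  keep <- vapply(seq_len(n), function(i) {
    cov <- 100 * min(hits$alignment_length[i], hits$query_length[i]) /
      hits$query_length[i]
    hits$percent_identity[i] >= t$identity_min && cov >= t$coverage_min &&
      hits$evalue[i] <= t$evalue_max
  }, logical(1))
  expect_identical(got, hits[keep, ])
  # pure filter: idempotent and a subset of the input
  expect_identical(filter_homology_hits(got, t), got)
  # loosening thresholds never removes a retained hit
  loose <- thresholds(identity_min = 60, coverage_min = 80, evalue_max = 1e-3)
  expect_true(all(got$subject_protein_id %in%
                    filter_homology_hits(hits, loose)$subject_protein_id))
})

test_that("domain presence respects the e-value ceiling and accession syntax", {
  g <- toy_genome(domain_hits = domain_hit("p001", "PF03301", evalue = 1e-30))
  r <- has_domain(g, "PF03301")
  expect_true(r$present)
  expect_identical(nrow(r$hits), 1L)
  expect_false(has_domain(toy_genome(), "PF03301")$present)
  weak <- toy_genome(domain_hits = domain_hit("p001", "PF03301",
                                              evalue = 1e-3))
  expect_false(has_domain(weak, "PF03301")$present)
  expect_error(has_domain(g, "PFX"), class = "tryp_argument_error")
})

test_that("adjacent role genes form one cluster; split contigs form none", {
  g <- toy_genome(n_genes = 10)
  req <- list(roles = c("A", "B", "C"), max_gap_genes = 3L,
              same_contig = TRUE, same_strand = FALSE)
  rp <- list(A = "p005", B = "p006", C = "p007")  # ranks 4,5,6
  calls <- find_gene_cluster(g, rp, req)
  expect_length(calls, 1)
  expect_identical(calls[[1]]$member_gene_ids, c("g005", "g006", "g007"))
  expect_identical(calls[[1]]$span_genes, 3L)

  genes2 <- rbind(make_genes(5, contig = "c1"),
                  make_genes(5, contig = "c2", prefix = "h"))
  genes2$protein_id <- sprintf("p%03d", 1:10)
  g2 <- toy_genome(genes = genes2)
  expect_length(find_gene_cluster(g2, list(A = "p002", B = "p008"),
                                  list(roles = c("A", "B"),
                                       max_gap_genes = 3L,
                                       same_contig = TRUE,
                                       same_strand = FALSE)), 0)

  # an unrepresented role yields no cluster at all
  expect_length(find_gene_cluster(g, list(A = "p005", B = "p006",
                                          C = character()), req), 0)
})

test_that("cluster detection matches exhaustive window enumeration", {
  set.seed(7)
  roles <- c("A", "B", "C")
  for (rep in 1:50) {
    n <- 30
    strands <- sample(c("+", "-"), n, replace = TRUE)
    genes <- make_genes(n, strands = strands)
    # each role planted on 0-3 random genes
    role_genes <- lapply(roles, function(r) sample(n, sample(0:3, 1)))
    names(role_genes) <- roles
    rp <- lapply(role_genes, function(idx) genes$protein_id[idx])
    max_gap <- sample(0:4, 1)
    same_strand <- sample(c(TRUE, FALSE), 1)
    req <- list(roles = roles, max_gap_genes = max_gap, same_contig = TRUE,
                same_strand = same_strand)
    g <- toy_genome(genes = genes)

    got <- find_gene_cluster(g, rp, req)
    got_sets <- lapply(got, `[[`, "member_gene_ids")

    cand_idx <- sort(unique(unlist(role_genes)))
    cand <- data.frame(gene_id = genes$gene_id[cand_idx],
                       rank = genes$rank_on_contig[cand_idx],
                       strand = genes$strand[cand_idx])
    cand$roles <- lapply(cand_idx, function(i) {
      roles[vapply(roles, function(r) i %in% role_genes[[r]], logical(1))]
    })
    want_sets <- if (any(vapply(role_genes, length, integer(1)) == 0)) {
      list()
    } else {
      oracle_windows(cand, roles, max_gap, same_strand)
    }
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
  }
})

test_that("cluster calls depend only on gene ranks, not coordinates", {
  genes <- make_genes(10)
  rp <- list(A = "p002", B = "p004")
  req <- list(roles = c("A", "B"), max_gap_genes = 2L, same_contig = TRUE,
              same_strand = FALSE)
  a <- find_gene_cluster(toy_genome(genes = genes), rp, req)
  genes2 <- genes
  genes2$start <- genes2$start + 500000L  # translate coordinates
  genes2$end <- genes2$end + 500000L
  b <- find_gene_cluster(toy_genome(genes = genes2), rp, req)
  expect_identical(lapply(a, `[[`, "member_gene_ids"),
                   lapply(b, `[[`, "member_gene_ids"))
})

test_that("proximal_pair matches the brute-force pairwise check", {
  g <- toy_genome(n_genes = 15)
  expect_true(proximal_pair(g, "p003", "p004", max_gap = 0,
                            same_strand = FALSE))
  expect_false(proximal_pair(g, "p001", "p012", max_gap = 3,
                             same_strand = FALSE))
  expect_error(proximal_pair(g, "p001", "nope", 3, FALSE),
               class = "tryp_lookup_error")

  genes <- g$genes
  for (i in 1:15) {
    for (j in 1:15) {
      if (i == j) next
      for (ss in c(TRUE, FALSE)) {
        want <- abs(genes$rank_on_contig[i] - genes$rank_on_contig[j]) - 1 <= 2 &&
          (!ss || genes$strand[i] == genes$strand[j])
        got <- proximal_pair(g, genes$protein_id[i], genes$protein_id[j],
                             max_gap = 2, same_strand = ss)
        expect_identical(got, want)
        # symmetry
        expect_identical(got, proximal_pair(g, genes$protein_id[j],
                                            genes$protein_id[i],
                                            max_gap = 2, same_strand = ss))
      }
    }
  }
})
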