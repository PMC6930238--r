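write_study <- function(long, groups) {
  a <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  g <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(long, a)
  readr::write_tsv(groups, g)
  list(abundance = a, groups = g)
}

test_that("long abundance input densifies with zeros and keeps groups", {
  long <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    genus = c("A", "B", "C", "A", "C"),
    count = c(2, 3, 5, 1, 4)
  )
  groups <- tibble::tibble(sample_id = c("s1", "s2"),
                           group = c("case", "control"))
  p <- write_study(long, groups)
  tab <- read_abundance_table(p$abundance, p$groups)
  expect_identical(dim(tab$data), c(2L, 5L))  # sample_id, group + 3 genera
  expect_equal(tab$data$B[tab$data$sample_id == "s2"], 0)  # missing pair -> 0
  expect_false(tab$normalized)

  # a sample without a group label is an error
  p2 <- write_study(long, groups[1, ])
  expect_error(read_abundance_table(p2$abundance, p2$groups), "s2",
               class = "tryp_metadata_error")

  # negative counts are rejected
  long$count[1] <- -1
  p3 <- write_study(long, groups)
  expect_error(read_abundance_table(p3$abundance, p3$groups),
               class = "tryp_format_error")
})

test_that("relative abundance normalizes each sample to sum one", {
  long <- tibble::tibble(sample_id = "s1", genus = c("A", "B", "C"),
                         count = c(2, 3, 5))
  groups <- tibble::tibble(sample_id = "s1", group = "case")
  p <- write_study(long, groups)
  tab <- relative_abundance(read_abundance_table(p$abundance, p$groups))
  expect_equal(unlist(tab$data[1, c("A", "B", "C")], use.names = FALSE),
               c(0.2, 0.3, 0.5))
  expect_true(tab$normalized)
  expect_error(relative_abundance(tab), class = "tryp_argument_error")

  # random tables always row-sum to 1
  set.seed(5)
  long2 <- tidyr::crossing(sample_id = sprintf("s%d", 1:6),
                           genus = sprintf("G%d", 1:8))
  long2$count <- rpois(nrow(long2), 40)
  groups2 <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                            group = rep(c("case", "control"), 3))
  p2 <- write_study(long2, groups2)
  tab2 <- relative_abundance(read_abundance_table(p2$abundance, p2$groups))
  genera <- setdiff(names(tab2$data), c("sample_id", "group"))
  expect_equal(rowSums(tab2$data[, genera]), rep(1, 6), tolerance = 1e-9)
})

test_that("rank-sum test: exact reference case and symmetry laws", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$W, 6)

  # identical samples (ties force the approximation branch): p = 1
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)

  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(7)
    b <- rnorm(9)
    ra <- wilcoxon_rank_sum(a, b)
    rb <- wilcoxon_rank_sum(b, a)
    expect_equal(ra$p_value, rb$p_value)
    N <- length(a) + length(b)
    expect_equal(ra$W + rb$W, N * (N + 1) / 2)
  }
  expect_error(wilcoxon_rank_sum(numeric(), 1:3),
               class = "tryp_argument_error")
})

test_that("exact branch equals the full-enumeration oracle on 8-vs-8 input", {
  set.seed(23)
  for (i in 1:3) {
    x <- rnorm(8)
    y <- rnorm(8, 0.5)
    got <- wilcoxon_rank_sum(x, y)$p_value
    expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("differential calling keeps p <= p_max with median direction", {
  set.seed(17)
  n <- 10
  long <- tidyr::crossing(
    sample_id = c(sprintf("case%02d", 1:n), sprintf("ctrl%02d", 1:n)),
    genus = c("Up", "Flat")
  )
  counts <- numeric(nrow(long))
  is_case <- grepl("^case", long$sample_id)
  counts[long$genus == "Up" & is_case] <- runif(n, 100, 120)
  counts[long$genus == "Up" & !is_case] <- runif(n, 10, 20)
  counts[long$genus == "Flat"] <- runif(2 * n, 50, 60)
  long$count <- counts
  groups <- tibble::tibble(
    sample_id = unique(long$sample_id),
    group = ifelse(grepl("^case", unique(long$sample_id)), "case", "control")
  )
  p <- write_study(long, groups)
  tab <- relative_abundance(read_abundance_table(p$abundance, p$groups))

  d <- differential_genera(tab, p_max = 0.01)
  expect_identical(d$direction[d$genus == "Up"], "case_enriched")
  # with two genera the composition is fully coupled: the flat genus's
  # relative abundance drops in cases, so it is control-enriched
  expect_identical(d$direction[d$genus == "Flat"], "control_enriched")

  # p_max = 1 keeps every genus; tiny p_max keeps none
  expect_identical(nrow(differential_genera(tab, p_max = 1)), 2L)
  expect_identical(nrow(differential_genera(tab, p_max = 1e-12)), 0L)
  # unnormalized input is refused
  raw <- read_abundance_table(p$abundance, p$groups)
  expect_error(differential_genera(raw), class = "tryp_argument_error")
})

test_that("pathway links are the positive-score cross product", {
  diffs <- tibble::tibble(
    genus = c("Burk", "Pseu", "Ghost"),
    statistic = c(300, 310, 290), p_value = c(0.001, 0.004, 0.009),
    direction = c("case_enriched", "control_enriched", "case_enriched"),
    median_case = c(0.2, 0.1, 0.3), median_control = c(0.05, 0.3, 0.1)
  )
  scores <- tibble::tibble(
    genus = rep(c("Burk", "Pseu"), each = 3),
    metabolite = rep(c("kynurenine", "quinolinate", "indole"), 2),
    score = c(8.61, 3.75, 0, 0, 0, 2.5)
  )
  expect_message(links <- pathway_links(diffs, scores), "Ghost")
  expect_identical(nrow(links), 3L)
  expect_setequal(paste(links$genus, links$metabolite),
                  c("Burk kynurenine", "Burk quinolinate", "Pseu indole"))
  expect_identical(links$group[links$genus == "Pseu"], "control")
  expect_true(all(links$scorbpeo_weight > 0 & links$scorbpeo_weight <= 10))
})

test_that("sankey documents round-trip and order deterministically", {
  links <- tibble::tibble(
    genus = c("B", "A", "A"), metabolite = c("indole", "indole", "IAA"),
    group = c("control", "case", "case"),
    scorbpeo_weight = c(2.5, 8.61, 1.2), p_value = c(0.004, 0.001, 0.001)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_sankey(links, path)
  back <- read_sankey(path)
  expect_identical(nrow(back), 3L)
  # deterministic (group, genus, metabolite) order
  expect_identical(back$genus, c("A", "A", "B"))
  expect_identical(back$metabolite, c("IAA", "indole", "indole"))
  expect_equal(sort(back$scorbpeo_weight), sort(links$scorbpeo_weight))
  doc <- jsonlite::read_json(path)
  expect_length(doc$nodes, 4)  # 2 genus nodes + 2 metabolite nodes

  # empty edge set is valid
  write_sankey(links[0, ], path)
  expect_identical(nrow(read_sankey(path)), 0L)
  expect_length(jsonlite::read_json(path)$links, 0)
})
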