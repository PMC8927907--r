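test_that("expression filter applies the count/fraction rule at boundaries", {
  counts <- rbind(gKeep = c(3, 3, 3, 0, 100),
                  gDrop = c(3, 3, 0, 0, 100),
                  gZero = c(0, 0, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:5)
  kept <- filter_expressed_genes(counts, min_count = 3, min_frac = 0.8)
  expect_identical(kept, "gKeep")          # 4/5 = 0.8 exactly
  expect_setequal(filter_expressed_genes(counts, min_count = 0),
                  rownames(counts))        # identity
  # the strict "> min_count" reading drops the boundary gene
  expect_length(filter_expressed_genes(counts, 3, 0.8,
                                       strict_greater = TRUE), 0)
  expect_error(filter_expressed_genes(counts, 3, 0), "min_frac")
})

test_that("target map deduplicates and summarizes correctly", {
  it <- data.frame(mirna_id = c("m1", "m1", "m1", "m2"),
                   gene_id = c("gA", "gA", "gB", "gB"),
                   source_db = "db", stringsAsFactors = FALSE)
  tm <- build_target_map(it, c("m1", "m2"))
  expect_setequal(tm$targets$m1, c("gA", "gB"))
  expect_identical(tm$targets$m2, "gB")
  expect_equal(tm$n_interactions, 3)
  expect_equal(tm$n_unique_genes, 2)
  expect_lte(tm$n_unique_genes, tm$n_interactions)

  tm_f <- build_target_map(it, c("m1", "m2"), expressed = "gB")
  expect_identical(tm_f$targets$m1, "gB")
  expect_identical(tm_f$targets$m2, "gB")

  tm_e <- build_target_map(it, character(0))
  expect_length(tm_e$targets, 0)
  expect_equal(tm_e$n_interactions, 0)
  expect_warning(tm_a <- build_target_map(it, c("m1", "mX")), "mX")
  expect_length(tm_a$targets$mX, 0)
})

test_that("filtering before mapping equals mapping then filtering", {
  set.seed(41)
  it <- data.frame(mirna_id = sample(paste0("m", 1:5), 60, TRUE),
                   gene_id = sample(paste0("g", 1:30), 60, TRUE),
                   source_db = "db", stringsAsFactors = FALSE)
  expressed <- paste0("g", 1:15)
  a <- build_target_map(it, paste0("m", 1:5), expressed = expressed)
  it_pre <- it[it$gene_id %in% expressed, ]
  b <- suppressWarnings(build_target_map(it_pre, paste0("m", 1:5)))
  expect_identical(a$targets, b$targets)
})

test_that("Jaccard distance handles the canonical cases", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard_distance(character(0), character(0)), "undefined")
})

test_that("similarity clustering is symmetric, deterministic, and matches a brute-force linkage", {
  tm <- list(targets = list(m1 = c("a", "b", "c"), m2 = c("b", "c", "d"),
                            m3 = c("x", "y"), m4 = c("x", "y"),
                            m5 = c("a", "q", "r"), m6 = c("s")))
  class(tm) <- "target_map"
  cl <- mirna_similarity_clustering(tm)
  expect_true(isSymmetric(cl$dist))
  expect_true(all(diag(cl$dist) == 0))
  # identical sets merge first at height 0
  expect_equal(min(cl$hclust$height), 0)
  first <- sort(cl$hclust$merge[1, ])
  expect_setequal(colnames(cl$dist)[-first], c("m3", "m4"))
  # linkage heights match the brute-force average-linkage oracle
  expect_equal(sort(cl$hclust$height),
               oracle_average_linkage_heights(cl$dist), tolerance = 1e-12)
  tm1 <- list(targets = list(m1 = "a")); class(tm1) <- "target_map"
  expect_error(mirna_similarity_clustering(tm1), "at least 2")
})

test_that("random-set null is degenerate at k = |universe| and reproducible", {
  it <- data.frame(mirna_id = rep(paste0("m", 1:4), each = 3),
                   gene_id = paste0("g", 1:12), source_db = "db",
                   stringsAsFactors = FALSE)
  u <- paste0("m", 1:4)
  full <- suppressWarnings(build_target_map(it, u))
  nd <- random_set_target_null(it, u, k = 4, n_draws = 20, seed = 1)
  expect_true(all(nd$n_unique_genes == full$n_unique_genes))
  expect_true(all(nd$n_interactions == full$n_interactions))
  nd2 <- random_set_target_null(it, u, k = 2, n_draws = 50, seed = 7)
  nd3 <- random_set_target_null(it, u, k = 2, n_draws = 50, seed = 7)
  expect_identical(nd2, nd3)
  expect_error(random_set_target_null(it, u, k = 9), "exceeds")
})

test_that("densely-targeting planted sets exceed the random-set null", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    planted <- paste0("p", 1:5)
    others <- paste0("m", 1:45)
    rows <- rbind(
      data.frame(mirna_id = rep(planted, each = 100),
                 gene_id = sample(paste0("g", 1:2000), 500, TRUE),
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = rep(others, each = 10),
                 gene_id = sample(paste0("g", 1:2000), 450, TRUE),
                 stringsAsFactors = FALSE))
    rows$source_db <- "db"
    obs <- suppressWarnings(build_target_map(rows, planted))
    nd <- random_set_target_null(rows, c(planted, others), k = 5,
                                 n_draws = 100, seed = s)
    empirical_percentile(nd$n_interactions, obs$n_interactions) >= 0.95
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("reference overlap counts and fractions are consistent", {
  ov <- reference_overlap(list(e1 = c("a", "b", "c", "d", "e")),
                          reference = c("b", "c"))
  expect_equal(ov$n_in_reference, 2)
  expect_equal(ov$frac_in_reference, 0.4)
  ov2 <- reference_overlap(list(e = c("a", "b")), reference = c("a", "b", "z"))
  expect_equal(ov2$frac_in_reference, 1)
  ov3 <- reference_overlap(list(e = c("a", "b")), reference = c("z"))
  expect_equal(ov3$n_in_reference, 0)
  expect_warning(reference_overlap(list(e = "a"), character(0)), "empty")
  # with an expressed filter the invariant chain holds
  ov4 <- reference_overlap(list(e = c("a", "b", "c")), reference = c("a", "b"),
                           expressed = c("a", "c"))
  expect_true(ov4$n_in_reference <= ov4$n_expressed &&
                ov4$n_expressed <= ov4$n_total)
  expect_equal(ov4$n_in_reference, 1)
})
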