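test_that("clone sharing matches the worked cross-pair example", {
  # single donor; A = 2 cells of c1; B = 1 cell of c1 + 1 cell of c2
  assign <- data.frame(
    cell_id = c("a1", "a2", "b1", "b2"),
    clone_id = c("c1", "c1", "c1", "c2"),
    donor = "D1", stringsAsFactors = FALSE)
  expect_equal(clone_sharing_fraction(assign, c("a1", "a2"), c("b1", "b2")), 0.5)
  # no shared clones -> 0
  assign$clone_id <- c("c1", "c1", "c2", "c2")
  expect_equal(clone_sharing_fraction(assign, c("a1", "a2"), c("b1", "b2")), 0)
  # mirrored single-cell groups of the same clone -> 1
  assign2 <- data.frame(cell_id = c("x", "y"), clone_id = "c1", donor = "D1")
  expect_equal(clone_sharing_fraction(assign2, "x", "y"), 1)
  # disjointness enforced; undefined denominator warns and returns NA
  expect_error(clone_sharing_fraction(assign, "a1", "a1"), "disjoint")
  assign3 <- data.frame(cell_id = c("x", "y"), clone_id = c("c1", "c2"),
                        donor = c("D1", "D2"))
  expect_warning(out <- clone_sharing_fraction(assign3, "x", "y"), "undefined")
  expect_true(is.na(out))
})

test_that("clone sharing equals the exhaustive pair oracle and is symmetric", {
  withr::local_seed(17)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    assign <- data.frame(
      cell_id = sprintf("cell%03d", 1:n),
      donor = sample(sprintf("D%d", 1:3), n, replace = TRUE),
      stringsAsFactors = FALSE)
    assign$clone_id <- paste0(assign$donor, ":c", sample(1:4, n, replace = TRUE))
    split_ab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    a <- assign$cell_id[split_ab]; b <- assign$cell_id[!split_ab]
    got <- suppressWarnings(clone_sharing_fraction(assign, a, b))
    want <- oracle_sharing(assign, a, b)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, suppressWarnings(clone_sharing_fraction(assign, b, a)),
                 tolerance = 1e-12)
  }
})

test_that("composition test: background-like clones null, pure clones significant", {
  withr::local_seed(2)
  types <- LETTERS[1:5]
  # 30 background-composition clones plus one pure clone of 20 cells
  bg <- toy_assign(rep(sprintf("D1:c%02d", 1:30), each = 10),
                   cell_type = rep(types, 60))
  pure <- toy_assign(rep("D1:pure", 20), cell_type = "A")
  pure$cell_id <- paste0("p", seq_len(nrow(pure)))
  assign <- rbind(bg, pure)
  res <- celltype_association_test(assign, n_sim = 999, seed = 4)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(res$significant[res$clone_id == "D1:pure"])
  expect_true(res$p[res$clone_id == "D1:pure"] < 0.01)
  expect_true(all(res$p[res$clone_id != "D1:pure"] > 0.2))
  # BH never drops below the raw p and is monotone in sorted order
  ord <- order(res$p)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04, 0.5), method = "BH"),
               c(0.04, 0.04, 0.04 / 0.75, 0.5))
})

test_that("tissue enrichment labels planted clones with exact Fisher p-values", {
  mk <- function(n_t, n_n, clone) {
    rbind(toy_assign(rep(clone, n_t), tissue = "tumor"),
          toy_assign(rep(clone, n_n), tissue = "NILT"))
  }
  bg <- do.call(rbind, lapply(1:10, function(i) {
    out <- mk(10, 10, sprintf("D1:bg%02d", i)); out
  }))
  planted <- mk(12, 0, "D1:hot")
  assign <- rbind(bg, planted)
  assign$cell_id <- sprintf("cell%04d", seq_len(nrow(assign)))
  res <- tissue_enrichment_test(assign, min_cells = 10)
  hot <- res[res$clone_id == "D1:hot", ]
  expect_equal(hot$label, "tumor-enriched")
  expect_true(all(res$label[res$clone_id != "D1:hot"] == "neither"))
  # p equals the exact two-sided hypergeometric enumeration
  expect_equal(hot$p, oracle_fisher_p(12, 0, 100, 100), tolerance = 1e-10)
  # symmetric planted depletion is NILT-enriched
  assign2 <- rbind(bg, mk(0, 12, "D1:cold"))
  assign2$cell_id <- sprintf("cell%04d", seq_len(nrow(assign2)))
  res2 <- tissue_enrichment_test(assign2, min_cells = 10)
  expect_equal(res2$label[res2$clone_id == "D1:cold"], "NILT-enriched")
  # one-sided tail of the worked 8-vs-0 example
  expect_equal(oracle_fisher_p_upper(8, 0, 100, 100), prod((108 - 0:7) / (208 - 0:7)),
               tolerance = 1e-12)
  expect_error(tissue_enrichment_test(toy_assign(rep("c", 12), tissue = "tumor")),
               "both tumor and NILT")
})

test_that("Fisher p-values equal hypergeometric enumeration on random tables", {
  withr::local_seed(23)
  for (rep in 1:60) {
    tot <- sample(4:500, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    got <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    expect_equal(got, oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("clone-frequency correlations reproduce the worked rank examples", {
  mk_type <- function(type, counts) {
    toy_assign(rep(sprintf("D1:c%d", seq_along(counts)), counts),
               cell_type = type)
  }
  assign <- rbind(mk_type("A", c(2, 4, 6)), mk_type("B", c(6, 4, 2)))
  assign$cell_id <- sprintf("cell%04d", seq_len(nrow(assign)))
  res <- clone_frequency_correlation(assign, min_cells = 5)
  expect_equal(res$pearson["A", "B"], -1)
  expect_equal(res$kendall["A", "B"], -1)
  expect_equal(res$pearson["A", "A"], 1)
  # identical count vectors
  assign2 <- rbind(mk_type("A", c(2, 4, 6)), mk_type("B", c(2, 4, 6)))
  assign2$cell_id <- sprintf("cell%04d", seq_len(nrow(assign2)))
  res2 <- clone_frequency_correlation(assign2, min_cells = 5)
  expect_equal(res2$pearson["A", "B"], 1)
  expect_equal(res2$kendall["A", "B"], 1)
  # Kendall tau 1/3 for (1,2,3) vs (1,3,2), against the pair-enumeration oracle
  assign3 <- rbind(mk_type("A", c(4, 8, 12)), mk_type("B", c(4, 12, 8)))
  assign3$cell_id <- sprintf("cell%04d", seq_len(nrow(assign3)))
  res3 <- clone_frequency_correlation(assign3, min_cells = 5)
  expect_equal(res3$kendall["A", "B"], 1 / 3)
  expect_equal(oracle_kendall(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
})

test_that("purity permutation: observed purities, exact expectation, strata", {
  # all clones pure -> observed purity 1
  assign <- toy_assign(rep(c("D1:c1", "D1:c2"), each = 4),
                       cell_type = rep(c("A", "B"), each = 4))
  res <- clone_purity_permutation(assign, n_perm = 10, seed = 1)
  expect_true(all(res$observed == 1))
  # exact enumeration: clone of 3 under a 50/50 two-type background
  expect_equal(expected_permuted_purity(3, c(0.5, 0.5)), 0.75)
  # Monte-Carlo permutation mean converges to the exact value (large sample)
  n <- 400
  big <- toy_assign(c(rep("D1:c1", 3), rep(sprintf("D1:f%03d", 1:(n - 3)))),
                    cell_type = rep(c("A", "B"), n / 2))
  res2 <- clone_purity_permutation(big, min_cells = 3, n_perm = 2000, seed = 8)
  mc <- mean(res2$permuted[, "D1:c1"])
  se <- stats::sd(res2$permuted[, "D1:c1"]) / sqrt(2000)
  expect_lt(abs(mc - 0.75), 3 * se + 0.01)
  # permuting within sample preserves per-sample type counts exactly
  two_sample <- rbind(
    toy_assign(rep("D1:c1", 6), cell_type = c("A", "A", "B", "B", "B", "B"),
               sample = "s1"),
    toy_assign(rep("D1:c2", 6), cell_type = c("A", "A", "A", "A", "B", "B"),
               sample = "s2"))
  two_sample$cell_id <- sprintf("cell%04d", seq_len(nrow(two_sample)))
  set.seed(3)
  perm <- two_sample$cell_type
  for (rows in split(seq_len(nrow(two_sample)), two_sample$sample)) {
    perm[rows] <- perm[sample(rows)]
  }
  expect_equal(table(perm[two_sample$sample == "s1"]),
               table(two_sample$cell_type[two_sample$sample == "s1"]))
  expect_error(clone_purity_permutation(assign, n_perm = 0), "n_perm")
})

test_that("per-clone two-group test flags differential clones only", {
  a <- toy_assign(c(rep("D1:c1", 10), rep(sprintf("D1:f%02d", 1:9), each = 10)),
                  tissue = "PBMC")
  b <- toy_assign(rep(sprintf("D1:f%02d", 1:9), c(rep(11, 8), 12)),
                  tissue = "tumor")
  b$cell_id <- paste0("b", b$cell_id)
  assign <- rbind(a, b)
  res <- per_clone_two_group_test(assign, list(tissue = "PBMC"),
                                  list(tissue = "tumor"))
  expect_true(res$flagged[res$clone_id == "D1:c1"])
  expect_equal(res$p[res$clone_id == "D1:c1"],
               oracle_fisher_p(10, 0, 90, 100), tolerance = 1e-10)
  # a clone with identical frequency in both groups is not flagged
  even <- rbind(toy_assign(rep(c("D1:c1", "D1:c2"), c(5, 45)), tissue = "PBMC"),
                local({
                  x <- toy_assign(rep(c("D1:c1", "D1:c2"), c(5, 45)),
                                  tissue = "tumor")
                  x$cell_id <- paste0("b", x$cell_id); x
                }))
  res2 <- per_clone_two_group_test(even, list(tissue = "PBMC"),
                                   list(tissue = "tumor"))
  expect_false(any(res2$flagged))
  expect_error(per_clone_two_group_test(assign, list(tissue = "PBMC"),
                                        list(tissue = "PBMC")), "disjoint")
})

test_that("cumulative clone-fraction AUC behaves over the clonality range", {
  # single clone holding 100% -> AUC 1
  one <- toy_assign(rep("D1:c1", 10))
  expect_equal(cumulative_clone_fraction_auc(one)$auc$auc, 1)
  # K equal clones -> (K^2 + 1) / (2 K^2) -> 1/2
  for (K in c(4, 20, 100)) {
    eq <- toy_assign(rep(sprintf("D1:c%03d", 1:K), each = 2))
    expect_equal(cumulative_clone_fraction_auc(eq)$auc$auc,
                 (K^2 + 1) / (2 * K^2))
  }
  # merging two clones never decreases the AUC when curves are compared on a
  # matched clone axis (the merged set padded with an empty clone): the
  # merged sorted fractions majorize the original ones
  auc_on_grid <- function(fracs, K) {
    fr <- c(sort(fracs, decreasing = TRUE), rep(0, K - length(fracs)))
    y <- cumsum(fr); x <- c(0, seq_len(K) / K); y <- c(y[1], y)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  withr::local_seed(31)
  for (rep in 1:15) {
    k <- sample(3:8, 1)
    sizes <- sample(1:20, k, replace = TRUE)
    fr0 <- sizes / sum(sizes)
    fr1 <- c(fr0[1] + fr0[2], fr0[-(1:2)])
    expect_true(auc_on_grid(fr1, k) >= auc_on_grid(fr0, k) - 1e-12)
  }
  # relabeling invariance
  assign <- toy_assign(rep(sprintf("D1:c%d", 1:4), c(5, 3, 2, 1)))
  relab <- assign
  relab$clone_id <- sprintf("D1:z%s", match(assign$clone_id, unique(assign$clone_id)))
  expect_equal(cumulative_clone_fraction_auc(assign)$auc$auc,
               cumulative_clone_fraction_auc(relab)$auc$auc)
  # identical clone structure in both tissues -> zero AUC difference
  both <- rbind(toy_assign(rep(sprintf("D1:c%d", 1:3), c(4, 2, 1)), tissue = "tumor"),
                local({
                  x <- toy_assign(rep(sprintf("D1:c%d", 1:3), c(4, 2, 1)),
                                  tissue = "NILT")
                  x$cell_id <- paste0("b", x$cell_id); x
                }))
  expect_equal(auc_tissue_difference(both)$auc_diff, 0)
})

test_that("lineage-bias clustering separates planted archetypes", {
  withr::local_seed(6)
  mk_clone <- function(id, n, probs, tissue) {
    toy_assign(rep(id, n),
               cell_type = sample(names(probs), n, TRUE, prob = probs),
               tissue = tissue)
  }
  dcp <- c(DC3 = 0.8, CD14_mono = 0.15, MoMac1 = 0.05)
  mfp <- c(DC3 = 0.05, CD14_mono = 0.15, MoMac1 = 0.8)
  assign <- do.call(rbind, c(
    lapply(1:6, function(i) rbind(
      mk_clone(sprintf("D1:dc%02d", i), 15, dcp, "tumor"),
      mk_clone(sprintf("D1:dc%02d", i), 15, dcp, "NILT"))),
    lapply(1:6, function(i) rbind(
      mk_clone(sprintf("D1:mf%02d", i), 15, mfp, "tumor"),
      mk_clone(sprintf("D1:mf%02d", i), 15, mfp, "NILT")))))
  assign$cell_id <- sprintf("cell%05d", seq_len(nrow(assign)))
  res <- lineage_bias_clustering(assign, k = 2)
  cl <- res$clusters
  dc_cluster <- cl$cluster[grepl(":dc", cl$clone_id)]
  mf_cluster <- cl$cluster[grepl(":mf", cl$clone_id)]
  expect_equal(length(unique(dc_cluster)), 1L)
  expect_equal(length(unique(mf_cluster)), 1L)
  expect_false(dc_cluster[1] == mf_cluster[1])
  expect_true(all(cl$label[grepl(":dc", cl$clone_id)] == "DC3-biased"))
  expect_true(all(cl$label[grepl(":mf", cl$clone_id)] == "MoMac1-biased"))
  # all clones identical -> a single cluster
  same <- do.call(rbind, lapply(1:4, function(i) {
    x <- toy_assign(rep(sprintf("D1:s%d", i), 4),
                    cell_type = c("DC3", "DC3", "MoMac1", "MoMac1"),
                    tissue = "tumor")
    x$cell_id <- paste0(i, x$cell_id); x
  }))
  res2 <- lineage_bias_clustering(same, k = 2)
  expect_equal(length(unique(res2$clusters$cluster)), 1L)
  expect_error(lineage_bias_clustering(same[1:4, ], k = 2), "eligible")
})
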