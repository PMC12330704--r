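test_that("binarization counts the threshold itself as detected", {
  m <- matrix(c(0.07, 0, 0.5, 0.069), 2, 2,
              dimnames = list(c("c1", "c2"), c("100A>T", "200C>G")))
  B <- binarize(heteroplasmy_matrix(m), threshold = 0.07)
  expect_equal(as.matrix(B$calls),
               matrix(c(1, 0, 1, 0), 2, 2, dimnames = dimnames(m)))
  expect_equal(B$threshold, 0.07)
  expect_error(binarize(heteroplasmy_matrix(m), threshold = 0), "threshold")
})

test_that("prevalence filter removes >20% and <3-cell variants", {
  m <- matrix(0, 100, 3)
  m[1:21, 1] <- 1   # 21% of donor cells -> removed
  m[1:2, 2] <- 1    # 2 cells -> removed
  m[1:3, 3] <- 1    # 3 of 100 -> retained
  B <- filter_variants_by_prevalence(toy_binary(m))
  expect_equal(colnames(B$calls), "103A>T")
  # boundary: exactly 20% is retained (rule is strict > removal)
  m2 <- matrix(0, 100, 1); m2[1:20, 1] <- 1
  expect_equal(ncol(filter_variants_by_prevalence(toy_binary(m2))$calls), 1L)
})

test_that("graph weights equal the phi coefficient, hand cases included", {
  # identical columns
  m <- matrix(0, 6, 2); m[1:3, ] <- 1
  G <- build_variant_graph(toy_binary(m))
  expect_equal(G$edges$weight, 1)
  # overlapping columns {1,2,3} vs {3,4,5} in 6 cells -> -1/3
  m <- matrix(0, 6, 2); m[1:3, 1] <- 1; m[3:5, 2] <- 1
  expect_equal(build_variant_graph(toy_binary(m))$edges$weight, -1 / 3)
  # disjoint single-cell columns in 10 cells -> -1/9
  m <- matrix(0, 10, 2); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(build_variant_graph(toy_binary(m))$edges$weight, -1 / 9)
})

test_that("graph weights match the phi oracle on random binary matrices", {
  withr::local_seed(3)
  for (rep in 1:20) {
    m <- matrix(rbinom(30 * 4, 1, 0.3), 30, 4)
    B <- toy_binary(m)
    G <- build_variant_graph(B)
    for (e in seq_len(nrow(G$edges))) {
      i <- match(G$edges$v1[e], colnames(B$calls))
      j <- match(G$edges$v2[e], colnames(B$calls))
      expect_equal(G$edges$weight[e], oracle_phi(m[, i], m[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero-variance columns produce no edges", {
  m <- matrix(0, 6, 2); m[, 1] <- 1; m[1:3, 2] <- 1
  G <- build_variant_graph(toy_binary(m))
  expect_equal(nrow(G$edges), 0L)
})

test_that("merging keeps weight-0.5 edges and closes transitively", {
  G <- structure(list(
    vertices = c("a", "b", "c"),
    edges = data.frame(v1 = c("a", "b", "a"), v2 = c("b", "c", "c"),
                       weight = c(0.9, 0.7, 0.2))), class = "variant_graph")
  expect_equal(merge_variants(G), list(c("a", "b", "c")))
  G$edges$weight <- c(0.4, 0.49, 0.2)
  expect_equal(merge_variants(G), list("a", "b", "c"))
  G$edges$weight <- c(0.5, 0.1, 0.1)     # boundary kept
  expect_equal(merge_variants(G), list(c("a", "b"), "c"))
})

test_that("connected components equal the transitive-closure oracle", {
  withr::local_seed(42)
  for (rep in 1:120) {
    G <- random_graph(sample(2:50, 1))
    expect_identical(merge_variants(G, edge_min = 0.5),
                     unname(oracle_components(G$vertices, G$edges)))
  }
})

test_that("assignment requires all clone variants and discards multi-matches", {
  m <- matrix(0, 4, 3, dimnames = list(
    sprintf("c%d", 1:4), c("100A>T", "200C>G", "300G>A")))
  m[1, 1] <- 1               # c1: vA only, clone {vA,vB} -> unassigned
  m[2, c(1, 2)] <- 1         # c2: both -> assigned to multi-variant clone
  m[3, c(1, 2, 3)] <- 1      # c3: matches both clones -> discarded
  m[4, 3] <- 1               # c4: single-variant clone -> assigned
  B <- toy_binary(m)
  cs <- assign_cells(B, list(c("100A>T", "200C>G"), "300G>A"), donor = "D1")
  expect_equal(as.character(cs$assignment$status),
               c("unassigned", "assigned", "discarded_multi", "assigned"))
  expect_equal(cs$assignment$clone_id,
               c(NA, "D1:100A>T", NA, "D1:300G>A"))
  expect_equal(cs$candidates[[3]], c("D1:100A>T", "D1:300G>A"))
})

test_that("clone calling partitions cells and is deterministic", {
  ez <- easy_fixture()
  clones <- ez$res$clones
  for (cs in clones) {
    expect_false(anyDuplicated(unlist(cs$clones)) > 0)
    expect_true(all(table(as.character(cs$assignment$status)) >= 0))
    expect_setequal(as.character(unique(cs$assignment$status)),
                    intersect(c("assigned", "unassigned", "discarded_multi"),
                              as.character(cs$assignment$status)))
    expect_false(anyDuplicated(cs$assignment$cell_id) > 0)
  }
  rerun <- call_clones(ez$sim$H, ez$sim$annotation, ez$fx$params,
                       donor_variants = select_variants(
                         ez$sim$counts, ez$sim$annotation, ez$fx$params)$donor_variants)
  expect_identical(lapply(rerun, function(x) x[c("donor", "clones", "assignment")]),
                   lapply(clones, function(x) x[c("donor", "clones", "assignment")]))
})

test_that("raising the threshold never increases positive calls", {
  ez <- easy_fixture()
  H <- ez$sim$H
  pos <- vapply(c(0.02, 0.07, 0.12, 0.3),
                function(t) length(binarize(H, t)$calls@x), 0)
  expect_true(all(diff(pos) <= 0))
})

test_that("adding a new clone's variants never reassigns an assigned cell", {
  withr::local_seed(9)
  n <- 60
  m <- matrix(0, n, 2, dimnames = list(sprintf("c%d", 1:n),
                                       c("100A>T", "200C>G")))
  m[1:10, 1] <- 1; m[11:20, 2] <- 1
  B1 <- toy_binary(m)
  cs1 <- assign_cells(B1, merge_variants(build_variant_graph(B1)), donor = "D1")
  m2 <- cbind(m, "300G>A" = 0)
  m2[c(5:8, 21:30), 3] <- 1    # new clone overlapping some assigned cells
  B2 <- toy_binary(m2)
  cs2 <- assign_cells(B2, merge_variants(build_variant_graph(B2)), donor = "D1")
  was <- cs1$assignment
  now <- cs2$assignment[match(was$cell_id, cs2$assignment$cell_id), ]
  moved <- was$status == "assigned" & now$status == "assigned" &
    was$clone_id != now$clone_id
  expect_false(any(moved))
  expect_true(all(now$status[was$status == "assigned"] %in%
                    c("assigned", "discarded_multi")))
})

test_that("a uniformly injected 30% variant is excluded from every clone", {
  ez <- easy_fixture()
  H <- ez$sim$H
  withr::local_seed(5)
  inject <- "9000A>G"
  newcol <- Matrix::Matrix(rbinom(nrow(H$values), 1, 0.3) * 0.5, ncol = 1,
                           sparse = TRUE, dimnames = list(rownames(H$values), inject))
  H2 <- heteroplasmy_matrix(cbind(H$values, newcol), coverage = H$coverage)
  cl <- call_clones(H2, ez$sim$annotation, ez$fx$params)
  expect_false(inject %in% unlist(lapply(cl, function(cs) unlist(cs$clones))))
})

test_that("an empty heteroplasmy matrix yields an empty clone set", {
  m <- matrix(numeric(0), 2, 0,
              dimnames = list(c("c1", "c2"), character()))
  H <- heteroplasmy_matrix(m, coverage = c(c1 = 50, c2 = 50))
  ann <- cell_annotation(data.frame(cell_id = c("c1", "c2"), donor = "D1",
                                    sample = "s1", tissue = "tumor",
                                    cell_type = "T"))
  expect_warning(cl <- call_clones(H, ann), "no retained variants")
  expect_length(cl$D1$clones, 0L)
  expect_true(all(cl$D1$assignment$status == "unassigned"))
})
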