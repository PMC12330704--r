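#' Tabulate assigned cells with their annotation
#'
#' Joins clone assignments to the cell annotation, yielding the tidy per-cell
#' table the downstream clonal statistics consume.
#'
#' @param clones A `clone_set` or list of `clone_set`s.
#' @param annotation A `cell_annotation`.
#' @param assigned_only Keep only assigned cells (default `TRUE`).
#' @return Data.frame with `cell_id`, `donor`, `clone_id`, `status`,
#'   `sample`, `tissue`, `cell_type`.
#' @export
assignment_table <- function(clones, annotation, assigned_only = TRUE) {
  if (inherits(clones, "clone_set")) clones <- list(clones)
  tab <- do.call(rbind, lapply(clones, function(cs) {
    cbind(cs$assignment, donor = cs$donor, stringsAsFactors = FALSE)
  }))
  idx <- match(tab$cell_id, annotation$cell_id)
  tab$sample <- as.character(annotation$sample[idx])
  tab$tissue <- as.character(annotation$tissue[idx])
  tab$cell_type <- as.character(annotation$cell_type[idx])
  if (assigned_only) tab <- tab[tab$status == "assigned", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fraction of same-clone cell pairs between two cell groups
#'
#' For two disjoint cell groups A and B, counts cross-group cell pairs that
#' share a clone and normalizes by all same-donor cross-group pairs: with
#' per-clone counts `X[i,1]`, `X[i,2]` of clone i's cells in A and B, and
#' per-donor column totals `D[j,1]`, `D[j,2]` over the donor's clones, the
#' statistic is `sum_i X[i,1]*X[i,2] / sum_j D[j,1]*D[j,2]`. Cross-donor
#' pairs can never share a (donor-scoped) clone and are excluded from the
#' normalization.
#'
#' @param assign Assignment table from [assignment_table()] (assigned cells).
#' @param cells_a,cells_b Disjoint character vectors of cell ids.
#' @return A fraction in `[0, 1]`; `NA` with a warning when no donor
#'   contributes cells to both groups.
#' @export
clone_sharing_fraction <- function(assign, cells_a, cells_b) {
  if (length(intersect(cells_a, cells_b))) stop("groups A and B must be disjoint")
  a <- assign[assign$cell_id %in% cells_a, c("clone_id", "donor")]
  b <- assign[assign$cell_id %in% cells_b, c("clone_id", "donor")]
  clones <- unique(rbind(a, b))
  if (!nrow(clones)) {
    warning("no assigned cells in either group; sharing undefined")
    return(NA_real_)
  }
  x1 <- as.numeric(table(factor(a$clone_id, levels = clones$clone_id)))
  x2 <- as.numeric(table(factor(b$clone_id, levels = clones$clone_id)))
  num <- sum(x1 * x2)
  d1 <- tapply(x1, clones$donor, sum)
  d2 <- tapply(x2, clones$donor, sum)
  den <- sum(d1 * d2)
  if (den == 0) {
    warning("no donor contributes cells to both groups; sharing undefined")
    return(NA_real_)
  }
  num / den
}

multinomial_gof_pvalue <- function(x, prob, n_sim = 2000L) {
  # Monte-Carlo exact multinomial goodness-of-fit: the p-value is the
  # probability of drawing a table at most as probable as the observed one.
  obs <- stats::dmultinom(x, prob = prob)
  sims <- stats::rmultinom(n_sim, size = sum(x), prob = prob)
  d <- apply(sims, 2L, stats::dmultinom, prob = prob)
  (1 + sum(d <= obs * (1 + 1e-7))) / (n_sim + 1)
}

#' Per-clone cell-type composition association test
#'
#' Tests, for every clone with at least `min_cells` cells, whether its
#' cell-type composition deviates from the pooled background composition of
#' all assigned cells, with Benjamini-Hochberg adjustment across clones.
#' The default test is a Monte-Carlo exact multinomial goodness-of-fit
#' against the background proportions; `method = "kruskal"` instead runs a
#' Kruskal-Wallis test of the cell's clone-membership indicator grouped by
#' cell type (a rank test of whether membership rates differ across types).
#'
#' @param assign Assignment table from [assignment_table()].
#' @param min_cells Minimum clone size (default 5).
#' @param method `"multinomial"` (default) or `"kruskal"`.
#' @param n_sim Monte-Carlo draws per clone for the multinomial test.
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return Data.frame `clone_id`, `n_cells`, `p`, `p_adj`, `significant`
#'   (adjusted p < 0.05).
#' @export
celltype_association_test <- function(assign, min_cells = 5L,
                                      method = c("multinomial", "kruskal"),
                                      n_sim = 2000L, seed = 1L) {
  method <- match.arg(method)
  types <- unique(assign$cell_type)
  if (length(types) < 2L) stop("need at least 2 cell types")
  sizes <- table(assign$clone_id)
  eligible <- names(sizes)[sizes >= min_cells]
  if (!length(eligible)) {
    return(data.frame(clone_id = character(), n_cells = integer(),
                      p = numeric(), p_adj = numeric(), significant = logical()))
  }
  bg <- table(factor(assign$cell_type, levels = types)) / nrow(assign)
  set.seed(seed)
  p <- vapply(eligible, function(cl) {
    x <- table(factor(assign$cell_type[assign$clone_id == cl], levels = types))
    if (method == "multinomial") {
      multinomial_gof_pvalue(as.integer(x), prob = as.numeric(bg), n_sim = n_sim)
    } else {
      member <- as.integer(assign$clone_id == cl)
      stats::kruskal.test(member, factor(assign$cell_type, levels = types))$p.value
    }
  }, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(clone_id = eligible, n_cells = as.integer(sizes[eligible]),
             p = unname(p), p_adj = unname(p_adj),
             significant = unname(p_adj < 0.05), stringsAsFactors = FALSE)
}

#' Per-clone tissue enrichment test (tumor vs non-involved tissue)
#'
#' Restricted to cells in tumor and NILT, tests each clone with at least
#' `min_cells` cells across the two sites with a 2x2 Fisher's exact test of
#' (clone vs rest) x (tumor vs NILT), Benjamini-Hochberg adjusted across
#' clones. Direction comes from the odds ratio; clones with adjusted
#' p < 0.05 are labeled `tumor-enriched` or `NILT-enriched`, the rest
#' `neither`.
#'
#' @param assign Assignment table from [assignment_table()].
#' @param min_cells Minimum clone size in tumor + NILT (default 10).
#' @return Data.frame `clone_id`, `n_tumor`, `n_nilt`, `odds_ratio`, `p`,
#'   `p_adj`, `label`.
#' @export
tissue_enrichment_test <- function(assign, min_cells = 10L) {
  df <- assign[assign$tissue %in% c("tumor", "NILT"), , drop = FALSE]
  tot_t <- sum(df$tissue == "tumor")
  tot_n <- sum(df$tissue == "NILT")
  if (tot_t == 0L || tot_n == 0L) stop("both tumor and NILT cells are required")
  sizes <- table(df$clone_id)
  eligible <- names(sizes)[sizes >= min_cells]
  res <- lapply(eligible, function(cl) {
    a <- sum(df$clone_id == cl & df$tissue == "tumor")
    b <- sum(df$clone_id == cl & df$tissue == "NILT")
    tab <- matrix(c(a, b, tot_t - a, tot_n - b), nrow = 2L, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    orr <- (a / b) / ((tot_t - a) / (tot_n - b))
    data.frame(clone_id = cl, n_tumor = a, n_nilt = b,
               odds_ratio = orr, p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(clone_id = character(), n_tumor = integer(),
                      n_nilt = integer(), odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), label = character()))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$label <- ifelse(out$p_adj >= 0.05, "neither",
                      ifelse(out$odds_ratio > 1, "tumor-enriched", "NILT-enriched"))
  rownames(out) <- NULL
  out
}

#' Clone-frequency correlation between cell groups
#'
#' For each cell group (by default each cell type, optionally crossed with
#' tissue), the clone-frequency vector holds every eligible clone's share of
#' that group's assigned cells (zero-count clones included so all vectors
#' share a common clone axis). Returns both Pearson and Kendall correlation
#' matrices across groups.
#'
#' @param assign Assignment table from [assignment_table()].
#' @param min_cells Minimum clone size across all samples (default 5).
#' @param group_cols Columns defining the groups (default `"cell_type"`).
#' @return List with `pearson`, `kendall` (symmetric matrices, diagonal 1
#'   where defined) and `frequencies` (clones x groups matrix). Groups in
#'   which fewer than 2 clones are represented are dropped with a warning.
#' @export
clone_frequency_correlation <- function(assign, min_cells = 5L,
                                        group_cols = "cell_type") {
  sizes <- table(assign$clone_id)
  clones <- names(sizes)[sizes >= min_cells]
  if (length(clones) < 2L) stop("need at least 2 eligible clones")
  df <- assign[assign$clone_id %in% clones, , drop = FALSE]
  grp <- interaction(df[group_cols], drop = TRUE, sep = ":")
  counts <- table(factor(df$clone_id, levels = clones), grp)
  rep_ok <- colSums(counts > 0) >= 2L
  if (any(!rep_ok)) {
    warning("dropping group(s) with fewer than 2 clones represented: ",
            paste(colnames(counts)[!rep_ok], collapse = ", "))
  }
  counts <- counts[, rep_ok, drop = FALSE]
  freq <- sweep(unclass(counts), 2L, pmax(colSums(counts), 1L), "/")
  list(pearson = suppressWarnings(stats::cor(freq, method = "pearson")),
       kendall = suppressWarnings(stats::cor(freq, method = "kendall")),
       frequencies = freq)
}

clone_purities <- function(clone_id, cell_type, clones) {
  vapply(clones, function(cl) {
    tt <- table(cell_type[clone_id == cl])
    max(tt) / sum(tt)
  }, 0)
}

#' Clone purity against a within-sample permutation null
#'
#' The purity of a clone is the proportion of its cells sharing the clone's
#' most common cell type. The null distribution permutes cell-type labels
#' among cells of the same sample (clone structure fixed), preserving
#' per-sample type counts exactly. Observed and permuted purity
#' distributions are compared with a Kruskal-Wallis test.
#'
#' @param assign Assignment table from [assignment_table()].
#' @param min_cells Minimum clone size (default 3).
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return List with `observed` (named vector), `permuted`
#'   (`n_perm` x n_clones matrix), `p_value` (Kruskal-Wallis), `n_perm`,
#'   `seed`.
#' @export
clone_purity_permutation <- function(assign, min_cells = 3L, n_perm = 1000L,
                                     seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  sizes <- table(assign$clone_id)
  clones <- names(sizes)[sizes >= min_cells]
  if (!length(clones)) stop("no clones with >= min_cells cells")
  observed <- clone_purities(assign$clone_id, assign$cell_type, clones)
  set.seed(seed)
  sample_idx <- split(seq_len(nrow(assign)), assign$sample)
  permuted <- matrix(NA_real_, n_perm, length(clones),
                     dimnames = list(NULL, clones))
  for (b in seq_len(n_perm)) {
    perm_type <- assign$cell_type
    for (rows in sample_idx) perm_type[rows] <- perm_type[sample(rows)]
    permuted[b, ] <- clone_purities(assign$clone_id, perm_type, clones)
  }
  kw <- stats::kruskal.test(list(observed, as.numeric(permuted)))
  list(observed = observed, permuted = permuted, p_value = kw$p.value,
       n_perm = n_perm, seed = seed)
}

#' Exact expected permuted clone purity
#'
#' For a clone of `n` cells whose permuted labels are i.i.d. draws from type
#' probabilities `probs`, enumerates all multinomial compositions to give the
#' exact expectation of the dominant-type fraction. Used as the closed-form
#' check on the Monte-Carlo permutation null for small clones.
#'
#' @param n Clone size.
#' @param probs Numeric vector of type probabilities (sums to 1).
#' @return The exact expected purity.
#' @export
expected_permuted_purity <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  k <- length(probs)
  total <- 0
  recurse <- function(remaining, slot, counts) {
    if (slot == k) {
      counts[k] <- remaining
      pr <- stats::dmultinom(counts, prob = probs)
      total <<- total + pr * max(counts) / n
      return(invisible())
    }
    for (c0 in 0:remaining) recurse(remaining - c0, slot + 1L, { counts[slot] <- c0; counts })
  }
  recurse(n, 1L, integer(k))
  total
}

resolve_group <- function(assign, group) {
  if (is.logical(group)) {
    stopifnot(length(group) == nrow(assign))
    return(group)
  }
  mask <- rep(TRUE, nrow(assign))
  for (col in names(group)) mask <- mask & assign[[col]] %in% group[[col]]
  mask
}

#' Per-clone two-group frequency comparison
#'
#' For two disjoint cell selections (e.g. circulating vs tissue cells of a
#' cell type), tests each clone present in either group with a 2x2 Fisher's
#' exact test of clone membership x group, Benjamini-Hochberg adjusted;
#' clones with adjusted p < 0.05 are flagged.
#'
#' @param assign Assignment table from [assignment_table()].
#' @param group_a,group_b Logical masks over `assign` rows, or named lists of
#'   column filters such as `list(cell_type = "CD14_mono", tissue = "PBMC")`.
#' @return Data.frame `clone_id`, `n_a`, `n_b`, `p`, `p_adj`, `flagged`.
#' @export
per_clone_two_group_test <- function(assign, group_a, group_b) {
  ma <- resolve_group(assign, group_a)
  mb <- resolve_group(assign, group_b)
  if (any(ma & mb)) stop("groups must be disjoint")
  if (!any(ma) || !any(mb)) stop("empty group")
  na_tot <- sum(ma); nb_tot <- sum(mb)
  clones <- sort(unique(assign$clone_id[ma | mb]))
  if (!length(clones)) {
    return(data.frame(clone_id = character(), n_a = integer(), n_b = integer(),
                      p = numeric(), p_adj = numeric(), flagged = logical()))
  }
  res <- lapply(clones, function(cl) {
    a <- sum(ma & assign$clone_id == cl)
    b <- sum(mb & assign$clone_id == cl)
    tab <- matrix(c(a, b, na_tot - a, nb_tot - b), nrow = 2L, byrow = TRUE)
    data.frame(clone_id = cl, n_a = a, n_b = b,
               p = stats::fisher.test(tab)$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

cumulative_auc <- function(fracs) {
  # Trapezoid AUC of the cumulative clone-fraction curve over normalized
  # rank; the curve is anchored at (0, largest fraction) so a single clone
  # holding everything scores 1 and K equal clones approach 1/2.
  y <- cumsum(sort(fracs, decreasing = TRUE))
  x <- seq_along(y) / length(y)
  x <- c(0, x); y <- c(y[1L], y)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Cumulative clone-fraction curves and their AUC per cell group
#'
#' Within each group (default cell type x tissue), clone fractions are sorted
#' in decreasing order and accumulated over normalized clone rank; the area
#' under this curve summarizes the group's overall clonality (1 = one clone
#' holds every cell; 0.5 = perfectly even clone sizes).
#'
#' @param assign Assignment table from [assignment_table()].
#' @param group_cols Columns defining groups (default
#'   `c("cell_type", "tissue")`).
#' @return List with `curves` (long data.frame `group`, `rank_frac`,
#'   `cum_frac`) and `auc` (data.frame `group`, `n_clones`, `auc`). Groups
#'   with zero clones are absent.
#' @export
cumulative_clone_fraction_auc <- function(assign,
                                          group_cols = c("cell_type", "tissue")) {
  grp <- interaction(assign[group_cols], drop = TRUE, sep = ":")
  pieces <- split(assign$clone_id, grp)
  curves <- list(); aucs <- list()
  for (g in names(pieces)) {
    fr <- as.numeric(table(pieces[[g]])) / length(pieces[[g]])
    y <- cumsum(sort(fr, decreasing = TRUE))
    curves[[g]] <- data.frame(group = g, rank_frac = seq_along(y) / length(y),
                              cum_frac = y, stringsAsFactors = FALSE)
    aucs[[g]] <- data.frame(group = g, n_clones = length(fr),
                            auc = cumulative_auc(fr), stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
       auc = do.call(rbind, c(aucs, list(make.row.names = FALSE))))
}

#' Per-cell-type AUC difference between tumor and non-involved tissue
#'
#' @param assign Assignment table from [assignment_table()].
#' @return Data.frame `cell_type`, `auc_tumor`, `auc_nilt`, `auc_diff`
#'   (positive = larger clone sizes in tumor). Cell types missing a site get
#'   `NA`.
#' @export
auc_tissue_difference <- function(assign) {
  df <- assign[assign$tissue %in% c("tumor", "NILT"), , drop = FALSE]
  res <- cumulative_clone_fraction_auc(df, group_cols = c("cell_type", "tissue"))$auc
  parts <- do.call(rbind, strsplit(res$group, ":", fixed = TRUE))
  res$cell_type <- parts[, 1L]; res$tissue <- parts[, 2L]
  types <- unique(res$cell_type)
  get <- function(ct, ts) {
    v <- res$auc[res$cell_type == ct & res$tissue == ts]
    if (length(v)) v else NA_real_
  }
  at <- vapply(types, get, 0, ts = "tumor")
  an <- vapply(types, get, 0, ts = "NILT")
  data.frame(cell_type = types, auc_tumor = at, auc_nilt = an,
             auc_diff = at - an, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster clones by lineage-biased subtype composition
#'
#' Builds a clone-by-(subtype x tissue) proportion matrix (proportions
#' normalized within each tissue), restricted to clones detected in both
#' tissue sites or holding at least `min_cells` cells, and groups clones by
#' average-linkage hierarchical clustering on Euclidean distance, cutting the
#' tree at `k`. Each cluster is named after the dominant subtype of its
#' centroid (optionally restricted to the differentiated subtypes so that
#' shared monocyte content does not name every cluster).
#'
#' @param assign Assignment table from [assignment_table()] restricted to the
#'   subtypes of interest (e.g. myeloid subtypes).
#' @param k Number of clusters to cut (default 2). If every profile is
#'   identical (all distances 0) a single cluster is returned.
#' @param min_cells Eligibility floor for single-tissue clones (default 3).
#' @param differentiated Optional character vector of subtype names used for
#'   cluster naming.
#' @return List with `clusters` (data.frame `clone_id`, `cluster`, `label`),
#'   `profiles` (the proportion matrix), `hclust` (or `NULL` when degenerate).
#' @export
lineage_bias_clustering <- function(assign, k = 2L, min_cells = 3L,
                                    differentiated = NULL) {
  df <- assign[assign$tissue %in% c("tumor", "NILT"), , drop = FALSE]
  tiss_per_clone <- tapply(df$tissue, df$clone_id, function(x) length(unique(x)))
  sizes <- table(df$clone_id)
  eligible <- names(sizes)[tiss_per_clone[names(sizes)] == 2L | sizes >= min_cells]
  if (length(eligible) < 2L) stop("fewer than 2 eligible clones")
  df <- df[df$clone_id %in% eligible, , drop = FALSE]
  subtypes <- sort(unique(df$cell_type))
  cols <- as.vector(outer(subtypes, c("tumor", "NILT"), paste, sep = ":"))
  prof <- matrix(0, length(eligible), length(cols),
                 dimnames = list(sort(eligible), cols))
  for (ts in c("tumor", "NILT")) {
    sub <- df[df$tissue == ts, , drop = FALSE]
    if (!nrow(sub)) next
    cnt <- table(factor(sub$clone_id, levels = rownames(prof)),
                 factor(sub$cell_type, levels = subtypes))
    tot <- rowSums(cnt)
    pr <- sweep(unclass(cnt), 1L, pmax(tot, 1L), "/")
    prof[, paste(subtypes, ts, sep = ":")] <- pr
  }
  d <- stats::dist(prof)
  if (max(d) == 0) {
    clusters <- data.frame(clone_id = rownames(prof), cluster = 1L,
                           stringsAsFactors = FALSE)
    hc <- NULL
  } else {
    hc <- stats::hclust(d, method = "average")
    clusters <- data.frame(clone_id = rownames(prof),
                           cluster = unname(stats::cutree(hc, k = k)),
                           stringsAsFactors = FALSE)
  }
  name_cols <- if (is.null(differentiated)) subtypes else differentiated
  keep_cols <- cols[sub("(.*):.*", "\\1", cols) %in% name_cols]
  labels <- vapply(sort(unique(clusters$cluster)), function(cl) {
    cent <- colMeans(prof[clusters$clone_id[clusters$cluster == cl], keep_cols,
                          drop = FALSE])
    sub("(.*):.*", "\\1", names(cent)[which.max(cent)])
  }, "")
  clusters$label <- paste0(labels[clusters$cluster], "-biased")
  list(clusters = clusters, profiles = prof, hclust = hc)
}
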