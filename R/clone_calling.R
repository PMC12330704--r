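#' Binarize a heteroplasmy matrix into positive-unlabeled calls
#'
#' A cell is called positive for a variant iff its heteroplasmy is at or
#' above `threshold` (values below the threshold are treated as not
#' detected, so the boundary value itself counts as positive). Entries with
#' missing coverage are 0 — the resulting matrix is "positive-unlabeled":
#' 1 means detected, 0 conflates absent with undetected.
#'
#' @param H A `heteroplasmy_matrix`.
#' @param threshold Detection cutoff in (0, 1); default 0.07.
#' @param donor Optional donor scope tag recorded for provenance.
#' @return An object of class `binary_call_matrix` with elements `calls`
#'   (sparse 0/1 `dgCMatrix`), `threshold`, `donor`.
#' @export
binarize <- function(H, threshold = 0.07, donor = NA_character_) {
  stopifnot(inherits(H, "heteroplasmy_matrix"),
            threshold > 0, threshold < 1)
  calls <- methods::as(methods::as(H$values >= threshold, "dMatrix"), "CsparseMatrix")
  calls <- Matrix::drop0(calls)
  structure(list(calls = calls, threshold = threshold, donor = donor),
            class = "binary_call_matrix")
}

#' @export
print.binary_call_matrix <- function(x, ...) {
  cat(sprintf("binary_call_matrix: %d cells x %d variants, threshold %.3g, %d positives\n",
              nrow(x$calls), ncol(x$calls), x$threshold, length(x$calls@x)))
  invisible(x)
}

#' Remove variants by call prevalence
#'
#' Variants positive in more than `max_frac` of cells in scope (likely
#' technical artifacts or homoplasmic variants that would generate spurious
#' linkages) or in fewer than `min_cells` cells are removed. The upper rule
#' is strict: a variant is dropped iff its positive count exceeds
#' `floor(max_frac * n_cells)`.
#'
#' @param B A `binary_call_matrix`.
#' @param max_frac Prevalence ceiling as a fraction of scope cells (default
#'   0.20).
#' @param min_cells Minimum positive cells (default 3).
#' @param samples Optional factor of per-cell sample labels; when given, the
#'   prevalence ceiling is evaluated within each sample (a variant exceeding
#'   the ceiling in any sample is removed) while `min_cells` applies to the
#'   total. Default is donor scope: the whole matrix is the denominator.
#' @return The filtered `binary_call_matrix`.
#' @export
filter_variants_by_prevalence <- function(B, max_frac = 0.20, min_cells = 3L,
                                          samples = NULL) {
  stopifnot(inherits(B, "binary_call_matrix"))
  npos <- Matrix::colSums(B$calls)
  keep <- npos >= min_cells
  if (is.null(samples)) {
    keep <- keep & npos <= floor(max_frac * nrow(B$calls))
  } else {
    stopifnot(length(samples) == nrow(B$calls))
    for (rows in split(seq_len(nrow(B$calls)), samples)) {
      ns <- Matrix::colSums(B$calls[rows, , drop = FALSE])
      keep <- keep & ns <= floor(max_frac * length(rows))
    }
  }
  B$calls <- B$calls[, keep, drop = FALSE]
  B
}

phi_matrix <- function(calls) {
  # Pearson correlation of 0/1 columns (the phi coefficient), computed from
  # co-occurrence counts; zero-variance columns yield NA.
  n <- nrow(calls)
  r <- Matrix::colSums(calls)
  n11 <- as.matrix(Matrix::crossprod(calls))
  num <- n * n11 - outer(r, r)
  den <- sqrt(outer(r * (n - r), r * (n - r)))
  phi <- num / den
  phi[den == 0] <- NA_real_
  phi
}

#' Build the variant co-occurrence graph
#'
#' Vertices are variants; the weight of each edge is the Pearson correlation
#' (phi coefficient) between the two variants' 0/1 call columns across cells.
#' Zero-variance columns produce no edges; there are no self-loops.
#'
#' @param B A `binary_call_matrix`.
#' @return An object of class `variant_graph`: list with `vertices`
#'   (character) and `edges` (data.frame `v1`, `v2`, `weight`).
#' @export
build_variant_graph <- function(B) {
  stopifnot(inherits(B, "binary_call_matrix"))
  vars <- colnames(B$calls)
  if (length(vars) < 1L) stop("no retained variants")
  if (length(vars) == 1L) {
    edges <- data.frame(v1 = character(), v2 = character(), weight = numeric())
  } else {
    phi <- phi_matrix(B$calls)
    ut <- which(upper.tri(phi) & !is.na(phi), arr.ind = TRUE)
    edges <- data.frame(v1 = vars[ut[, 1L]], v2 = vars[ut[, 2L]],
                        weight = phi[ut], stringsAsFactors = FALSE)
  }
  structure(list(vertices = vars, edges = edges), class = "variant_graph")
}

#' Merge correlated variants into clone definitions
#'
#' Removes edges with weight strictly below `edge_min` (an edge of exactly
#' `edge_min` is kept) and returns the connected components of the remaining
#' graph as clone variant groups. Frequently co-occurring variants — which
#' may reflect genuine subclonal structure — collapse into a single clone;
#' isolated variants form single-variant clones.
#'
#' @param G A `variant_graph`.
#' @param edge_min Edge retention floor (default 0.5).
#' @return List of character vectors (each sorted), one per clone, ordered by
#'   their lexicographically smallest variant id.
#' @export
merge_variants <- function(G, edge_min = 0.5) {
  stopifnot(inherits(G, "variant_graph"))
  keep <- G$edges[!is.na(G$edges$weight) & G$edges$weight >= edge_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep[, c("v1", "v2")], directed = FALSE,
                                     vertices = data.frame(name = G$vertices))
  comp <- igraph::components(g)
  groups <- split(G$vertices, comp$membership[G$vertices])
  groups <- lapply(groups, function(v) sort(unname(v)))
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}

#' Assign cells to clones
#'
#' A cell matches a single-variant clone iff it is positive for that variant,
#' and a multi-variant clone iff it is positive for every one of the clone's
#' variants. Cells matching exactly one clone are assigned; cells matching
#' two or more clones are discarded (`discarded_multi`) to avoid
#' contamination by non-informative variants of technical or biological
#' origin; all remaining cells are unassigned.
#'
#' @param B A `binary_call_matrix` (donor scope).
#' @param clone_defs List of variant groups as from [merge_variants()].
#' @param donor Donor id used to mint clone ids.
#' @param params Optional parameter snapshot stored on the result.
#' @return A [clone_set()].
#' @export
assign_cells <- function(B, clone_defs, donor = NA_character_, params = list()) {
  stopifnot(inherits(B, "binary_call_matrix"))
  cells <- rownames(B$calls)
  ids <- vapply(clone_defs, function(v) paste0(donor, ":", v[1L]), "")
  names(clone_defs) <- ids
  match_mat <- matrix(FALSE, length(cells), length(clone_defs),
                      dimnames = list(cells, ids))
  for (k in seq_along(clone_defs)) {
    v <- clone_defs[[k]]
    match_mat[, k] <- Matrix::rowSums(B$calls[, v, drop = FALSE] > 0) == length(v)
  }
  nmatch <- rowSums(match_mat)
  status <- factor(ifelse(nmatch == 0L, "unassigned",
                          ifelse(nmatch == 1L, "assigned", "discarded_multi")),
                   levels = c("assigned", "unassigned", "discarded_multi"))
  clone_id <- rep(NA_character_, length(cells))
  one <- nmatch == 1L
  if (any(one)) {
    clone_id[one] <- ids[max.col(match_mat[one, , drop = FALSE], ties.method = "first")]
  }
  candidates <- vector("list", length(cells))
  multi <- nmatch >= 2L
  candidates[multi] <- lapply(which(multi), function(i) ids[match_mat[i, ]])
  clone_set(donor = donor,
            clones = clone_defs[order(names(clone_defs))],
            assignment = data.frame(cell_id = cells, clone_id = clone_id,
                                    status = status, stringsAsFactors = FALSE),
            candidates = candidates, params = params)
}

#' Construct a clone set
#'
#' Donor-scoped clone definitions (disjoint variant groups) together with the
#' cell-to-clone assignment and discard records. Clone ids are deterministic:
#' `"<donor>:<smallest variant id>"`.
#'
#' @param donor Donor id.
#' @param clones Named list mapping clone id to a sorted character vector of
#'   variant ids; variant sets must be pairwise disjoint.
#' @param assignment Data.frame with `cell_id`, `clone_id` (`NA` when not
#'   assigned) and `status` in `assigned`/`unassigned`/`discarded_multi`.
#' @param candidates Optional list (parallel to `assignment` rows) of the
#'   candidate clone ids that triggered a `discarded_multi`.
#' @param params Parameter snapshot for provenance.
#' @return An object of class `clone_set`.
#' @export
clone_set <- function(donor, clones, assignment, candidates = NULL,
                      params = list()) {
  allv <- unlist(clones, use.names = FALSE)
  if (anyDuplicated(allv)) stop("clone variant sets must be pairwise disjoint")
  if (!all(c("cell_id", "clone_id", "status") %in% names(assignment))) {
    stop("assignment must have cell_id, clone_id, status")
  }
  assignment$status <- factor(as.character(assignment$status),
                              levels = c("assigned", "unassigned", "discarded_multi"))
  bad <- assignment$status == "assigned" & !(assignment$clone_id %in% names(clones))
  if (any(bad)) stop("assigned cells must reference a defined clone")
  rownames(assignment) <- NULL
  structure(list(donor = donor, clones = clones, assignment = assignment,
                 candidates = candidates, params = params),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  tab <- table(x$assignment$status)
  cat(sprintf("clone_set donor %s: %d clones; %d assigned, %d unassigned, %d discarded_multi\n",
              x$donor, length(x$clones), tab[["assigned"]], tab[["unassigned"]],
              tab[["discarded_multi"]]))
  invisible(x)
}

#' Call clones per donor from a heteroplasmy matrix
#'
#' Runs the donor-scoped core: coverage filter, restriction to donor-valid
#' variants (when supplied), binarization, prevalence filter, co-occurrence
#' graph, component merging, and conservative assignment — independently for
#' each donor. Deterministic for fixed input and parameters.
#'
#' @param H A `heteroplasmy_matrix` covering all donors.
#' @param annotation A `cell_annotation` covering the matrix cells.
#' @param params Parameter list as from [default_params()].
#' @param donor_variants Optional named list (donor -> valid variant ids),
#'   typically from [select_variants()]; when `NULL` all variants are used
#'   (the blacklist is still applied).
#' @return Named list of [clone_set()], one per donor. Donors with zero
#'   retained variants yield an empty clone set with a warning.
#' @export
call_clones <- function(H, annotation, params = default_params(),
                        donor_variants = NULL) {
  stopifnot(inherits(H, "heteroplasmy_matrix"))
  annotation <- annotation[annotation$cell_id %in% rownames(H$values), , drop = FALSE]
  donors <- unique(as.character(annotation$donor))
  out <- stats::setNames(lapply(donors, function(d) {
    dcells <- as.character(annotation$cell_id[annotation$donor == d])
    vars <- if (is.null(donor_variants)) {
      apply_blacklist(colnames(H$values), regions = params$blacklist)
    } else {
      intersect(donor_variants[[d]], colnames(H$values))
    }
    Hd <- subset_heteroplasmy(H, cells = dcells, variants = vars)
    if (all(is.na(Hd$coverage))) {
      Hd$coverage[] <- Inf  # no coverage information: keep all cells
    }
    Hd <- suppressWarnings(filter_cells_by_coverage(Hd, params$min_coverage))
    empty <- function() {
      warning("donor ", d, ": no retained variants; empty clone set")
      clone_set(donor = d, clones = stats::setNames(list(), character()),
                assignment = data.frame(
                  cell_id = rownames(Hd$values),
                  clone_id = rep(NA_character_, nrow(Hd$values)),
                  status = rep("unassigned", nrow(Hd$values)),
                  stringsAsFactors = FALSE),
                params = params)
    }
    if (ncol(Hd$values) == 0L) return(empty())
    B <- binarize(Hd, threshold = params$threshold, donor = d)
    samples <- if (identical(params$prevalence_scope, "sample")) {
      ann_d <- annotation[match(rownames(B$calls), annotation$cell_id), ]
      droplevels(ann_d$sample)
    }
    B <- filter_variants_by_prevalence(B, max_frac = params$max_prevalence,
                                       min_cells = params$min_variant_cells,
                                       samples = samples)
    if (ncol(B$calls) == 0L) return(empty())
    G <- build_variant_graph(B)
    defs <- merge_variants(G, edge_min = params$edge_min)
    assign_cells(B, defs, donor = d, params = params)
  }), donors)
  out[order(names(out))]
}
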