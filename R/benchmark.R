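#' Ground-truth clonal labels
#'
#' @param cell_id Character vector of cell barcodes.
#' @param clone Parallel vector of true clone labels (opaque).
#' @param source `"simulation"` or `"external"`.
#' @return A data.frame of class `truth_labels`.
#' @export
truth_labels <- function(cell_id, clone, source = c("simulation", "external")) {
  source <- match.arg(source)
  if (anyDuplicated(cell_id)) stop("duplicate cell ids in truth labels")
  structure(data.frame(cell_id = as.character(cell_id),
                       clone = as.character(clone), stringsAsFactors = FALSE),
            source = source, class = c("truth_labels", "data.frame"))
}

gather_assignments <- function(clones) {
  if (inherits(clones, "clone_set")) clones <- list(clones)
  do.call(rbind, lapply(clones, function(cs) cs$assignment))
}

#' Map ground-truth clones to predicted clones by modal vote
#'
#' For each truth clone with at least one assigned cell, the predicted label
#' is the mode of the called clones among its assigned cells; ties are broken
#' by the lexicographically smallest clone id and recorded.
#'
#' @param clones A `clone_set` or list of `clone_set`s.
#' @param truth A [truth_labels()] table.
#' @return Data.frame `truth_clone`, `predicted_clone`, `n_assigned`, `tie`;
#'   truth clones with zero assigned cells are excluded (attribute
#'   `n_unmapped` counts them).
#' @export
map_predicted_to_truth <- function(clones, truth) {
  assign <- gather_assignments(clones)
  assign <- assign[assign$status == "assigned", , drop = FALSE]
  m <- merge(assign, truth, by = "cell_id")
  groups <- split(m$clone_id, m$clone)
  rows <- lapply(names(groups), function(tc) {
    tab <- sort(table(groups[[tc]]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    data.frame(truth_clone = tc, predicted_clone = min(top),
               n_assigned = length(groups[[tc]]), tie = length(top) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(truth_clone = character(), predicted_clone = character(),
                      n_assigned = integer(), tie = logical())
  }
  attr(out, "n_unmapped") <- length(setdiff(unique(truth$clone), names(groups)))
  out
}

#' Clone assignment accuracy against ground truth
#'
#' Accuracy is the fraction of assigned, truth-labeled cells whose predicted
#' clone equals the modal predicted clone of their truth clone (from
#' [map_predicted_to_truth()]). Unassigned and discarded cells are excluded
#' from the denominator — they contribute to the assignment rate instead.
#' The adjusted Rand index between truth and predicted labels over the same
#' cells is reported as a mapping-free secondary metric.
#'
#' @param clones A `clone_set` or list of `clone_set`s.
#' @param truth A [truth_labels()] table.
#' @return List with `accuracy` (`NA` if no assigned labeled cell), `n`
#'   (denominator), `ari`, and the `mapping` table.
#' @export
assignment_accuracy <- function(clones, truth) {
  mapping <- map_predicted_to_truth(clones, truth)
  assign <- gather_assignments(clones)
  assign <- assign[assign$status == "assigned", , drop = FALSE]
  m <- merge(assign, truth, by = "cell_id")
  if (!nrow(m)) {
    return(list(accuracy = NA_real_, n = 0L, ari = NA_real_, mapping = mapping))
  }
  expected <- mapping$predicted_clone[match(m$clone, mapping$truth_clone)]
  list(accuracy = mean(m$clone_id == expected), n = nrow(m),
       ari = mclust::adjustedRandIndex(m$clone, m$clone_id),
       mapping = mapping)
}

#' Clone assignment rate
#'
#' The fraction of coverage-passing cells placed into a clone:
#' `assigned / (assigned + unassigned + discarded_multi)`.
#'
#' @param clones A `clone_set` or list of `clone_set`s.
#' @return A fraction in `[0, 1]`.
#' @export
assignment_rate <- function(clones) {
  assign <- gather_assignments(clones)
  if (!nrow(assign)) return(NA_real_)
  mean(assign$status == "assigned")
}

#' Sweep the binarization threshold and score against ground truth
#'
#' Re-runs the full clone-calling pipeline at each threshold and reports the
#' assignment rate and mode-mapped accuracy, plus the rate-maximizing
#' threshold (the conventional operating point).
#'
#' @param H A `heteroplasmy_matrix`.
#' @param annotation A `cell_annotation`.
#' @param truth A [truth_labels()] table.
#' @param thresholds Numeric vector of cutoffs, each strictly in (0, 1);
#'   default `seq(0.01, 0.15, by = 0.01)`.
#' @param params Parameter list; the `threshold` entry is overridden per run.
#' @param donor_variants Optional donor-valid variant sets (see
#'   [call_clones()]).
#' @return Data.frame `threshold`, `rate`, `accuracy`, `n_clones`, with
#'   attribute `best_threshold` (argmax of rate, first on ties).
#' @export
threshold_sweep <- function(H, annotation, truth,
                            thresholds = seq(0.01, 0.15, by = 0.01),
                            params = default_params(), donor_variants = NULL) {
  if (!length(thresholds)) stop("empty threshold list")
  stopifnot(all(thresholds > 0 & thresholds < 1))
  rows <- lapply(thresholds, function(th) {
    p <- params; p$threshold <- th
    cl <- suppressWarnings(call_clones(H, annotation, p,
                                       donor_variants = donor_variants))
    acc <- assignment_accuracy(cl, truth)
    data.frame(threshold = th, rate = assignment_rate(cl),
               accuracy = acc$accuracy,
               n_clones = sum(vapply(cl, function(x) length(x$clones), 0L)))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_threshold") <- out$threshold[which.max(out$rate)]
  out
}
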