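#' Strand-resolved allele counts
#'
#' Container for per-cell, per-variant alternate-allele and coverage counts
#' split by sequencing strand — the raw material for heteroplasmy estimation
#' and for the strand-concordance quality filter.
#'
#' @param alt_fwd,alt_rev,cov_fwd,cov_rev Integer matrices (cells x variants,
#'   matching dimnames) of alternate-allele and total coverage counts on the
#'   forward and reverse strand. `alt <= cov` entrywise, all counts >= 0.
#' @param cell_coverage Optional named numeric vector of per-cell mean
#'   mitochondrial genome coverage; defaults to the per-cell mean of
#'   `cov_fwd + cov_rev` over variants.
#' @return An object of class `strand_counts`.
#' @export
strand_counts <- function(alt_fwd, alt_rev, cov_fwd, cov_rev,
                          cell_coverage = NULL) {
  mats <- list(alt_fwd = alt_fwd, alt_rev = alt_rev,
               cov_fwd = cov_fwd, cov_rev = cov_rev)
  dn <- dimnames(alt_fwd)
  if (is.null(dn[[1L]]) || is.null(dn[[2L]])) {
    stop("count matrices must carry cell and variant dimnames")
  }
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!identical(dim(m), dim(alt_fwd)) || !identical(dimnames(m), dn)) {
      stop("count matrix dimension/dimnames mismatch in ", nm)
    }
    if (any(m < 0)) stop("negative counts in ", nm)
  }
  if (any(alt_fwd > cov_fwd) || any(alt_rev > cov_rev)) {
    stop("alt counts exceed strand coverage")
  }
  if (is.null(cell_coverage)) {
    cell_coverage <- rowMeans(cov_fwd + cov_rev)
  }
  cell_coverage <- stats::setNames(as.numeric(cell_coverage[dn[[1L]]]), dn[[1L]])
  structure(c(mats, list(cell_coverage = cell_coverage)),
            class = "strand_counts")
}

#' @export
print.strand_counts <- function(x, ...) {
  cat(sprintf("strand_counts: %d cells x %d variants\n",
              nrow(x$alt_fwd), ncol(x$alt_fwd)))
  invisible(x)
}

#' Compute per-cell heteroplasmy from strand counts
#'
#' Heteroplasmy is the strand-pooled allele fraction
#' `(alt_fwd + alt_rev) / (cov_fwd + cov_rev)`. Entries with zero total
#' coverage get heteroplasmy 0 and are flagged in the missing-data mask,
#' keeping "not covered" distinct from an observed 0.
#'
#' @param counts A [strand_counts()] object.
#' @return A [heteroplasmy_matrix()] with a populated `missing` mask.
#' @export
compute_heteroplasmy <- function(counts) {
  stopifnot(inherits(counts, "strand_counts"))
  alt <- counts$alt_fwd + counts$alt_rev
  cov <- counts$cov_fwd + counts$cov_rev
  h <- matrix(0, nrow(alt), ncol(alt), dimnames = dimnames(alt))
  pos <- cov > 0
  h[pos] <- alt[pos] / cov[pos]
  heteroplasmy_matrix(h, coverage = counts$cell_coverage,
                      missing = Matrix::Matrix(!pos, sparse = TRUE))
}

#' Filter cells by mean mitochondrial coverage
#'
#' Retains cells whose mean mitochondrial genome coverage is at least
#' `min_cov` (inclusive), preserving order. The conventional floor is 10x for
#' mitochondrial scATAC data and 100x for full-length scRNA genotypes.
#'
#' @param H A `heteroplasmy_matrix` with known coverage.
#' @param min_cov Positive coverage threshold (default 10).
#' @return The filtered `heteroplasmy_matrix`; a warning (not an error) is
#'   raised if no cell survives.
#' @export
filter_cells_by_coverage <- function(H, min_cov = 10) {
  stopifnot(inherits(H, "heteroplasmy_matrix"), min_cov > 0)
  keep <- !is.na(H$coverage) & H$coverage >= min_cov
  if (!any(keep)) warning("no cells pass the coverage filter")
  subset_heteroplasmy(H, cells = rownames(H$values)[keep])
}

#' Per-variant, per-sample quality metrics
#'
#' For every variant within every sample, computes the strand correlation
#' (Pearson correlation across cells between forward- and reverse-strand
#' alternate counts, restricted to cells with nonzero total coverage at the
#' variant) and the variance-mean ratio (VMR) of per-cell heteroplasmy across
#' covered cells. Undefined correlations (fewer than two covered cells, or a
#' constant strand vector) are reported as `NA` and fail the downstream
#' quality filter; a zero mean heteroplasmy yields VMR 0.
#'
#' @param counts A [strand_counts()] object.
#' @param annotation A `cell_annotation` covering the counted cells.
#' @return A data.frame with one row per variant per sample: `variant_id`,
#'   `sample`, `donor`, `strand_correlation`, `vmr`, `n_cells_detected`.
#' @export
variant_metrics <- function(counts, annotation) {
  stopifnot(inherits(counts, "strand_counts"))
  annotation <- annotation[match(rownames(counts$alt_fwd), annotation$cell_id), ]
  if (anyNA(annotation$cell_id)) stop("annotation does not cover all counted cells")
  alt <- counts$alt_fwd + counts$alt_rev
  cov <- counts$cov_fwd + counts$cov_rev
  variants <- colnames(alt)
  res <- lapply(split(seq_len(nrow(alt)), droplevels(annotation$sample)), function(rows) {
    donor <- as.character(annotation$donor[rows[1L]])
    sc <- vmr <- rep(NA_real_, length(variants))
    ndet <- integer(length(variants))
    for (j in seq_along(variants)) {
      covered <- rows[cov[rows, j] > 0]
      if (length(covered) >= 2L) {
        af <- counts$alt_fwd[covered, j]
        ar <- counts$alt_rev[covered, j]
        if (stats::sd(af) > 0 && stats::sd(ar) > 0) {
          sc[j] <- stats::cor(af, ar)
        }
        h <- alt[covered, j] / cov[covered, j]
        m <- mean(h)
        vmr[j] <- if (m > 0) stats::var(h) / m else 0
      }
      ndet[j] <- sum(alt[rows, j] > 0 & cov[rows, j] > 0)
    }
    data.frame(variant_id = variants,
               sample = as.character(annotation$sample[rows[1L]]),
               donor = donor, strand_correlation = sc, vmr = vmr,
               n_cells_detected = ndet, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Apply the per-sample variant quality filter
#'
#' A variant passes in a sample iff `strand_correlation > strand_corr_min`
#' AND `vmr > vmr_min` — strict inequalities. Undefined metrics fail.
#'
#' @param metrics Output of [variant_metrics()].
#' @param strand_corr_min Strand correlation floor (default 0.65).
#' @param vmr_min Variance-mean ratio floor (default 0.01).
#' @return `metrics` with a logical `pass` column appended.
#' @export
call_quality_variants <- function(metrics, strand_corr_min = 0.65,
                                  vmr_min = 0.01) {
  metrics$pass <- !is.na(metrics$strand_correlation) & !is.na(metrics$vmr) &
    metrics$strand_correlation > strand_corr_min & metrics$vmr > vmr_min
  metrics
}

#' Donor-level union of per-sample variant validity
#'
#' A variant is donor-valid iff it passes the quality filter in at least one
#' of the donor's samples; donor-valid variants are then considered in all of
#' that donor's samples. This union approach recovers sensitivity lost to
#' per-sample filtering while keeping the per-sample filter conservative.
#'
#' @param metrics Output of [call_quality_variants()] (must have `pass`).
#' @param donor Optional donor id; if given, returns that donor's valid
#'   variant ids (error if the donor has no samples in `metrics`).
#' @return With `donor = NULL`, a data.frame `variant_id` x `donor` with
#'   `pass_donor_union`; otherwise a character vector of variant ids.
#' @export
union_across_samples <- function(metrics, donor = NULL) {
  if (is.null(metrics$pass)) stop("run call_quality_variants() first")
  agg <- stats::aggregate(pass ~ variant_id + donor, data = metrics, FUN = any)
  names(agg)[names(agg) == "pass"] <- "pass_donor_union"
  if (is.null(donor)) return(agg)
  rows <- agg$donor == donor
  if (!any(rows)) stop("donor has no samples: ", donor)
  sort(agg$variant_id[rows & agg$pass_donor_union])
}

#' Pseudobulk variant allele frequency
#'
#' Aggregates per-variant allele frequency over all cells of a donor (or
#' sample). The default is read-weighted: total alternate reads divided by
#' total reads across the scope's cells; `method = "cellmean"` instead
#' averages per-cell heteroplasmy over covered cells.
#'
#' @param counts A [strand_counts()] object.
#' @param annotation A `cell_annotation` covering the counted cells.
#' @param scope `"donor"` (default) or `"sample"`.
#' @param method `"reads"` (default) or `"cellmean"`.
#' @return Data.frame with `variant_id`, the scope column, and
#'   `pseudobulk_frequency`.
#' @export
pseudobulk_frequency <- function(counts, annotation,
                                 scope = c("donor", "sample"),
                                 method = c("reads", "cellmean")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  annotation <- annotation[match(rownames(counts$alt_fwd), annotation$cell_id), ]
  alt <- counts$alt_fwd + counts$alt_rev
  cov <- counts$cov_fwd + counts$cov_rev
  groups <- droplevels(annotation[[scope]])
  idx <- split(seq_len(nrow(alt)), groups)
  res <- Map(function(rows, grp) {
    if (method == "reads") {
      num <- colSums(alt[rows, , drop = FALSE])
      den <- colSums(cov[rows, , drop = FALSE])
      f <- ifelse(den > 0, num / den, 0)
    } else {
      f <- vapply(seq_len(ncol(alt)), function(j) {
        covered <- rows[cov[rows, j] > 0]
        if (!length(covered)) return(0)
        mean(alt[covered, j] / cov[covered, j])
      }, 0)
    }
    out <- data.frame(variant_id = colnames(alt), pseudobulk_frequency = f,
                      stringsAsFactors = FALSE)
    out[[scope]] <- grp
    out
  }, idx, names(idx))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("variant_id", scope, "pseudobulk_frequency")]
}

#' Pseudobulk frequency ceiling
#'
#' Variants whose pseudobulk frequency exceeds `max_freq` (strict `>`) are
#' excluded — they typically reflect zygotic/homoplasmic mutations that are
#' uninformative for recent lineage relationships. A frequency of exactly
#' `max_freq` is retained.
#'
#' @param pb Output of [pseudobulk_frequency()].
#' @param max_freq Ceiling (default 0.01, i.e. 1%).
#' @return `pb` restricted to retained rows.
#' @export
apply_pseudobulk_filter <- function(pb, max_freq = 0.01) {
  pb[pb$pseudobulk_frequency <= max_freq, , drop = FALSE]
}

#' Remove variants falling in blacklisted mitochondrial regions
#'
#' Drops variants whose 1-based position lies inside any of the inclusive
#' intervals in `regions`. The default masks the polymorphic, highly
#' homologous homopolymer region at chrM 307-314 which generates spurious
#' clonal linkages.
#'
#' @param variants Character vector of variant ids.
#' @param regions List of inclusive `c(start, end)` integer intervals.
#' @return The retained variant ids, in input order.
#' @export
apply_blacklist <- function(variants, regions = list(c(307L, 314L))) {
  if (!length(variants)) return(variants)
  pos <- parse_variant_id(variants)$position
  bad <- rep(FALSE, length(pos))
  for (r in regions) bad <- bad | (pos >= r[1L] & pos <= r[2L])
  variants[!bad]
}

#' Select donor-valid variants from strand counts
#'
#' Convenience orchestrator for the variant-selection stage: computes
#' per-sample quality metrics, applies the quality filter, takes the donor
#' union, applies the pseudobulk ceiling and the blacklist.
#'
#' @param counts A [strand_counts()] object.
#' @param annotation A `cell_annotation`.
#' @param params Parameter list as from [default_params()].
#' @return List with `catalog` (the per-sample metric table with pass flags)
#'   and `donor_variants` (named list: donor -> valid variant ids).
#' @export
select_variants <- function(counts, annotation, params = default_params()) {
  metrics <- variant_metrics(counts, annotation)
  metrics <- call_quality_variants(metrics,
                                   strand_corr_min = params$strand_corr_min,
                                   vmr_min = params$vmr_min)
  pb <- pseudobulk_frequency(counts, annotation,
                             scope = params$pseudobulk_scope,
                             method = params$pseudobulk_method)
  pb_ok <- apply_pseudobulk_filter(pb, max_freq = params$pseudobulk_max)
  donors <- unique(as.character(annotation$donor))
  donor_variants <- stats::setNames(lapply(donors, function(d) {
    v <- union_across_samples(metrics, donor = d)
    if (params$pseudobulk_scope == "donor") {
      v <- intersect(v, pb_ok$variant_id[pb_ok$donor == d])
    } else {
      v <- intersect(v, unique(pb_ok$variant_id))
    }
    apply_blacklist(sort(v), regions = params$blacklist)
  }), donors)
  list(catalog = metrics, donor_variants = donor_variants)
}
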