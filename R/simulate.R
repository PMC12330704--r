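MT_GENOME_LENGTH <- 16569L

#' Simulation configuration
#'
#' Parameters of the synthetic single-cell mtDNA genotype generator. Clones
#' are donor-scoped and marked by 1-3 founder variants; per-cell heteroplasmy
#' evolves from the founder value by Wright-Fisher resampling of
#' `effective_mito_copies` genome copies over `divisions` cell divisions
#' (random genetic drift); observed counts are drawn at each cell's coverage
#' and split across sequencing strands. Noise layers: ambient variants
#' (low-level heteroplasmy shared across a random fraction of unrelated
#' cells), cross-clone ambient contamination (a fraction of cells takes up
#' the founder variant sets of `contam_sources` other clones at very low
#' heteroplasmy), high-frequency zygotic variants, and doublets carrying the
#' unioned founder variant sets of two clones.
#'
#' @param n_donors Number of donors.
#' @param clones_per_donor Clones per donor.
#' @param cells_per_clone Cells per clone.
#' @param background_cells_per_donor Cells belonging to no tracked clone.
#' @param variants_per_clone Integer vector sampled uniformly per clone.
#' @param founder_heteroplasmy `c(min, max)` of the uniform founder
#'   heteroplasmy distribution.
#' @param effective_mito_copies Wright-Fisher population size (>= 1).
#' @param divisions Number of drift generations (0 = no drift).
#' @param ambient_variant_count,ambient_cell_fraction,ambient_heteroplasmy
#'   Dedicated ambient variants: how many, the fraction of all cells each
#'   one hits, and the `c(min, max)` uniform per-cell heteroplasmy.
#' @param contam_cell_fraction,contam_sources,contam_heteroplasmy
#'   Cross-clone contamination: fraction of cells receiving the founder sets
#'   of `contam_sources` distinct other clones at `c(min, max)` uniform
#'   heteroplasmy.
#' @param zygotic_variant_count,zygotic_cell_fraction,zygotic_heteroplasmy
#'   High-frequency zygotic variants (assigned round-robin to donors),
#'   present in most of the donor's cells at high heteroplasmy, subject to
#'   the same drift.
#' @param doublets_per_donor Doublet cells carrying the union of two clones'
#'   founder variants at founder heteroplasmy.
#' @param coverage_mean,coverage_size Negative-binomial per-cell mean
#'   mitochondrial coverage (mean / size parameterization).
#' @param strand_balance Probability a read maps to the forward strand.
#' @param tissues Tissue labels; each donor gets one sample per tissue and
#'   cells are spread uniformly across them.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 3L,
                       clones_per_donor = 10L,
                       cells_per_clone = 20L,
                       background_cells_per_donor = 0L,
                       variants_per_clone = 1:3,
                       founder_heteroplasmy = c(0.25, 0.45),
                       effective_mito_copies = 100L,
                       divisions = 0L,
                       ambient_variant_count = 0L,
                       ambient_cell_fraction = 0.10,
                       ambient_heteroplasmy = c(0.05, 0.25),
                       contam_cell_fraction = 0,
                       contam_sources = 2L,
                       contam_heteroplasmy = c(0.01, 0.05),
                       zygotic_variant_count = 0L,
                       zygotic_cell_fraction = 0.95,
                       zygotic_heteroplasmy = c(0.5, 0.8),
                       doublets_per_donor = 0L,
                       coverage_mean = 50,
                       coverage_size = 15,
                       strand_balance = 0.5,
                       tissues = c("tumor", "NILT"),
                       seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(seed)) stop("seed is mandatory")
  cfg$seed <- as.integer(seed)
  for (f in c("ambient_cell_fraction", "contam_cell_fraction",
              "zygotic_cell_fraction", "strand_balance")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("founder_heteroplasmy", "ambient_heteroplasmy",
              "contam_heteroplasmy", "zygotic_heteroplasmy")) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1L] > r[2L]) {
      stop(f, " must be an increasing pair in [0, 1]")
    }
  }
  if (cfg$effective_mito_copies < 1L) stop("effective_mito_copies must be >= 1")
  if (cfg$divisions < 0L) stop("divisions must be >= 0")
  if (cfg$clones_per_donor < 1L) stop("need at least one clone per donor")
  if (cfg$doublets_per_donor > 0L && cfg$clones_per_donor < 2L) {
    stop("doublets require at least two clones per donor")
  }
  if (cfg$contam_cell_fraction > 0 && cfg$clones_per_donor <= cfg$contam_sources) {
    stop("contam_sources must be smaller than clones_per_donor")
  }
  structure(cfg, class = "sim_config")
}

wf_drift <- function(h, copies, divisions) {
  # Wright-Fisher drift: iterated binomial resampling of variant copies
  # among a fixed number of mitochondrial genomes per division. Preserves
  # the expectation; variance grows with divisions / copies.
  for (i in seq_len(divisions)) {
    h <- stats::rbinom(length(h), copies, h) / copies
  }
  h
}

#' Simulate single-cell mtDNA genotypes with known clonal truth
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` ([strand_counts()]), `H`
#'   ([heteroplasmy_matrix()]), `truth` (class `sim_truth`: `cells` with the
#'   true clone per cell, `variants` with each variant's origin, `true_h`
#'   the pre-sampling heteroplasmy matrix) and `annotation`
#'   (a `cell_annotation` with placeholder cell types).
#' @export
simulate_heteroplasmy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  donors <- sprintf("D%d", seq_len(cfg$n_donors))

  # -- variant universe -------------------------------------------------
  n_founders <- cfg$n_donors * cfg$clones_per_donor * max(cfg$variants_per_clone)
  n_var_max <- n_founders + cfg$ambient_variant_count + cfg$zygotic_variant_count
  bl <- 307:314
  pos_pool <- setdiff(seq_len(MT_GENOME_LENGTH), bl)
  positions <- sample(pos_pool, n_var_max)
  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, n_var_max, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1L), "")
  vid_pool <- variant_id(positions, refs, alts)
  next_vid <- 0L
  take_vids <- function(n) {
    out <- vid_pool[next_vid + seq_len(n)]
    next_vid <<- next_vid + n
    out
  }

  # -- clones, cells ----------------------------------------------------
  clone_tab <- list(); cell_tab <- list(); var_tab <- list()
  for (d in donors) {
    for (k in seq_len(cfg$clones_per_donor)) {
      lab <- sprintf("%s:clone%02d", d, k)
      nv <- if (length(cfg$variants_per_clone) == 1L) cfg$variants_per_clone else
        sample(cfg$variants_per_clone, 1L)
      vids <- take_vids(nv)
      h0 <- stats::runif(nv, cfg$founder_heteroplasmy[1L], cfg$founder_heteroplasmy[2L])
      clone_tab[[lab]] <- list(donor = d, variants = vids, h0 = h0)
      var_tab[[length(var_tab) + 1L]] <- data.frame(
        variant_id = vids, origin = "founder", clone = lab,
        stringsAsFactors = FALSE)
    }
  }
  ambient_vids <- take_vids(cfg$ambient_variant_count)
  if (length(ambient_vids)) {
    var_tab[[length(var_tab) + 1L]] <- data.frame(
      variant_id = ambient_vids, origin = "ambient", clone = NA_character_,
      stringsAsFactors = FALSE)
  }
  zygotic_vids <- take_vids(cfg$zygotic_variant_count)
  zygotic_donor <- if (length(zygotic_vids)) {
    donors[(seq_along(zygotic_vids) - 1L) %% cfg$n_donors + 1L]
  } else character()
  if (length(zygotic_vids)) {
    var_tab[[length(var_tab) + 1L]] <- data.frame(
      variant_id = zygotic_vids, origin = "zygotic", clone = NA_character_,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_tab)
  all_vids <- variants$variant_id

  per_donor <- cfg$clones_per_donor * cfg$cells_per_clone +
    cfg$background_cells_per_donor + cfg$doublets_per_donor
  cells <- list()
  for (d in donors) {
    idx <- 0L
    mk <- function(n) {
      out <- sprintf("%s_cell%05d", d, idx + seq_len(n))
      idx <<- idx + n
      out
    }
    for (k in seq_len(cfg$clones_per_donor)) {
      lab <- sprintf("%s:clone%02d", d, k)
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = mk(cfg$cells_per_clone), donor = d, clone = lab,
        is_doublet = FALSE, doublet_clones = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (cfg$background_cells_per_donor > 0L) {
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = mk(cfg$background_cells_per_donor), donor = d,
        clone = NA_character_, is_doublet = FALSE,
        doublet_clones = NA_character_, stringsAsFactors = FALSE)
    }
    if (cfg$doublets_per_donor > 0L) {
      pair <- replicate(cfg$doublets_per_donor,
                        sort(sample(cfg$clones_per_donor, 2L)))
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = mk(cfg$doublets_per_donor), donor = d, clone = NA_character_,
        is_doublet = TRUE,
        doublet_clones = sprintf("%s:clone%02d+%s:clone%02d",
                                 d, pair[1L, ], d, pair[2L, ]),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  n_cells <- nrow(cells)

  # -- true heteroplasmy -------------------------------------------------
  true_h <- matrix(0, n_cells, length(all_vids),
                   dimnames = list(cells$cell_id, all_vids))
  for (lab in names(clone_tab)) {
    cl <- clone_tab[[lab]]
    rows <- which(cells$clone %in% lab)
    for (i in seq_along(cl$variants)) {
      true_h[rows, cl$variants[i]] <-
        wf_drift(rep(cl$h0[i], length(rows)), cfg$effective_mito_copies,
                 cfg$divisions)
    }
  }
  dbl <- which(cells$is_doublet)
  for (r in dbl) {
    labs <- strsplit(cells$doublet_clones[r], "+", fixed = TRUE)[[1L]]
    for (lab in labs) {
      cl <- clone_tab[[lab]]
      true_h[r, cl$variants] <- pmax(true_h[r, cl$variants], cl$h0)
    }
  }
  for (v in ambient_vids) {
    hit <- which(stats::runif(n_cells) < cfg$ambient_cell_fraction)
    true_h[hit, v] <- pmax(true_h[hit, v],
                           stats::runif(length(hit), cfg$ambient_heteroplasmy[1L],
                                        cfg$ambient_heteroplasmy[2L]))
  }
  for (i in seq_along(zygotic_vids)) {
    rows <- which(cells$donor == zygotic_donor[i] &
                    stats::runif(n_cells) < cfg$zygotic_cell_fraction)
    base <- stats::runif(1L, cfg$zygotic_heteroplasmy[1L], cfg$zygotic_heteroplasmy[2L])
    true_h[rows, zygotic_vids[i]] <-
      wf_drift(rep(base, length(rows)), cfg$effective_mito_copies, cfg$divisions)
  }
  if (cfg$contam_cell_fraction > 0) {
    contam <- which(stats::runif(n_cells) < cfg$contam_cell_fraction)
    for (r in contam) {
      d <- cells$donor[r]
      own <- cells$clone[r]
      pool <- names(clone_tab)[vapply(clone_tab, function(x) x$donor == d, TRUE)]
      pool <- setdiff(pool, own)
      src <- sample(pool, cfg$contam_sources)
      for (lab in src) {
        cl <- clone_tab[[lab]]
        h <- stats::runif(length(cl$variants), cfg$contam_heteroplasmy[1L],
                          cfg$contam_heteroplasmy[2L])
        true_h[r, cl$variants] <- pmax(true_h[r, cl$variants], h)
      }
    }
  }

  # -- observed counts ---------------------------------------------------
  cell_cov <- stats::rnbinom(n_cells, mu = cfg$coverage_mean,
                             size = cfg$coverage_size)
  nm <- n_cells * length(all_vids)
  depth <- matrix(stats::rpois(nm, rep(cell_cov, times = length(all_vids))),
                  n_cells, length(all_vids))
  cov_fwd <- matrix(stats::rbinom(nm, depth, cfg$strand_balance),
                    n_cells, length(all_vids))
  cov_rev <- depth - cov_fwd
  alt_fwd <- matrix(stats::rbinom(nm, cov_fwd, true_h), n_cells, length(all_vids))
  alt_rev <- matrix(stats::rbinom(nm, cov_rev, true_h), n_cells, length(all_vids))
  dn <- list(cells$cell_id, all_vids)
  dimnames(alt_fwd) <- dimnames(alt_rev) <- dn
  dimnames(cov_fwd) <- dimnames(cov_rev) <- dn
  counts <- strand_counts(alt_fwd, alt_rev, cov_fwd, cov_rev,
                          cell_coverage = stats::setNames(cell_cov, cells$cell_id))

  tissue <- sample(cfg$tissues, n_cells, replace = TRUE)
  annotation <- cell_annotation(data.frame(
    cell_id = cells$cell_id, donor = cells$donor,
    sample = paste(cells$donor, tissue, sep = "_"), tissue = tissue,
    cell_type = "unlabeled", mean_mito_coverage = cell_cov,
    stringsAsFactors = FALSE))

  truth <- structure(list(cells = cells, variants = variants, true_h = true_h),
                     class = "sim_truth")
  list(counts = counts, H = compute_heteroplasmy(counts), truth = truth,
       annotation = annotation)
}

#' Draw cell-type (and optionally tissue) labels with planted clone biases
#'
#' Cells of unbiased clones (and cells outside any clone) draw their type
#' from a global background multinomial; clones named in `bias_spec` draw
#' from their own multinomial, and may also redraw tissue (the sample id is
#' updated accordingly). Enables planted-structure tests of the composition,
#' enrichment and lineage-bias statistics.
#'
#' @param truth A `sim_truth` (for the cell-to-clone map).
#' @param annotation The `cell_annotation` to relabel.
#' @param cell_types Character vector of type labels.
#' @param background Background type probabilities (default uniform); must
#'   sum to 1 within 1e-9.
#' @param bias_spec Named list: true clone label -> list with `cell_type`
#'   (named probability vector over `cell_types`) and optional `tissue`
#'   (named probability vector).
#' @param seed RNG seed.
#' @return The updated `cell_annotation`.
#' @export
simulate_celltype_labels <- function(truth, annotation,
                                     cell_types = c("CD14_mono", "CD16_mono",
                                                    "MoMac1", "MoMac2", "DC3",
                                                    "cDC2", "CD8_T", "B"),
                                     background = NULL, bias_spec = list(),
                                     seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(background)) background <- rep(1 / length(cell_types), length(cell_types))
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9) stop(what, " probabilities must sum to 1")
  }
  check_probs(background, "background")
  set.seed(seed)
  ann <- as.data.frame(annotation)
  ann$cell_type <- as.character(ann$cell_type)
  ann$tissue <- as.character(ann$tissue)
  ann$sample <- as.character(ann$sample)
  clone_of <- truth$cells$clone[match(ann$cell_id, truth$cells$cell_id)]
  ann$cell_type <- sample(cell_types, nrow(ann), replace = TRUE, prob = background)
  for (lab in names(bias_spec)) {
    spec <- bias_spec[[lab]]
    rows <- which(!is.na(clone_of) & clone_of == lab)
    if (!length(rows)) next
    if (!is.null(spec$cell_type)) {
      check_probs(spec$cell_type, lab)
      ann$cell_type[rows] <- sample(names(spec$cell_type), length(rows),
                                    replace = TRUE, prob = spec$cell_type)
    }
    if (!is.null(spec$tissue)) {
      check_probs(spec$tissue, lab)
      ann$tissue[rows] <- sample(names(spec$tissue), length(rows),
                                 replace = TRUE, prob = spec$tissue)
      ann$sample[rows] <- paste(ann$donor[rows], ann$tissue[rows], sep = "_")
    }
  }
  cell_annotation(ann)
}

#' Packaged fixture configurations
#'
#' Two generation configs used throughout the test suite (fixtures are
#' shipped as configs, not data files). `"easy"`: 3 donors x 10 clones x 20
#' cells, founder heteroplasmy U(0.25, 0.45), no drift, no ambient, no
#' zygotic variants, seed 1 — every cell belongs to a clone, so the paired
#' pipeline parameters disable the pseudobulk ceiling (there are no
#' high-frequency variants for it to remove and clone variants necessarily
#' exceed 1% of a fixture this small). `"hard"`: Wright-Fisher drift (100
#' effective copies, 20 divisions), 1800 background cells per donor (so
#' founders stay below the 1% pseudobulk ceiling, which is left at its
#' default), 3 ambient variants each hitting 10% of cells, 2 zygotic
#' variants, 15% cross-clone contamination, 10 doublets per donor, seed 1.
#'
#' @param name `"easy"` or `"hard"`.
#' @return List with `sim` (a [sim_config()]) and `params` (pipeline
#'   parameters).
#' @export
fixture_config <- function(name = c("easy", "hard")) {
  name <- match.arg(name)
  if (name == "easy") {
    list(sim = sim_config(n_donors = 3L, clones_per_donor = 10L,
                          cells_per_clone = 20L, variants_per_clone = 1:3,
                          founder_heteroplasmy = c(0.25, 0.45),
                          divisions = 0L, seed = 1L),
         params = default_params(pseudobulk_max = 1))
  } else {
    list(sim = sim_config(n_donors = 3L, clones_per_donor = 8L,
                          cells_per_clone = 25L,
                          background_cells_per_donor = 1800L,
                          variants_per_clone = 1:3,
                          founder_heteroplasmy = c(0.3, 0.5),
                          effective_mito_copies = 100L, divisions = 20L,
                          ambient_variant_count = 3L,
                          ambient_cell_fraction = 0.10,
                          zygotic_variant_count = 2L,
                          contam_cell_fraction = 0.15,
                          doublets_per_donor = 10L, seed = 1L),
         params = default_params())
  }
}
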