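#' Default pipeline parameters
#'
#' The out-of-the-box parameterization of the clone-calling pipeline:
#' heteroplasmy detection threshold 0.07, prevalence ceiling 20% with a
#' 3-cell floor, co-occurrence edge floor 0.5, minimum mitochondrial
#' coverage 10x, pseudobulk ceiling 1%, quality floors (strand correlation
#' 0.65, VMR 0.01) and the chrM 307-314 blacklist.
#'
#' @param ... Named overrides of any default; unknown names are rejected.
#' @return A named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(
    threshold = 0.07,
    max_prevalence = 0.20,
    min_variant_cells = 3L,
    edge_min = 0.5,
    min_coverage = 10,
    pseudobulk_max = 0.01,
    pseudobulk_scope = "donor",
    pseudobulk_method = "reads",
    strand_corr_min = 0.65,
    vmr_min = 0.01,
    prevalence_scope = "donor",
    blacklist = list(c(307L, 314L))
  )
  override_params(p, list(...))
}

override_params <- function(params, overrides) {
  if (!length(overrides)) return(params)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(overrides)] <- overrides
  params
}

#' Read pipeline parameters from a YAML config file
#'
#' The file may contain any subset of the [default_params()] keys (blacklist
#' intervals as a list of two-integer vectors); unknown keys are rejected
#' with their names.
#'
#' @param path YAML file path.
#' @return A full parameter list (defaults filled in).
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$blacklist)) {
    cfg$blacklist <- lapply(cfg$blacklist, as.integer)
  }
  override_params(default_params(), cfg)
}

#' Run the full clone-calling pipeline from strand counts
#'
#' Executes the fixed stage order: cell coverage filter, per-sample variant
#' quality metrics with donor-union validity, pseudobulk ceiling, blacklist,
#' binarization, prevalence filter, co-occurrence graph, component merging,
#' and conservative assignment.
#'
#' @param counts A [strand_counts()] object.
#' @param annotation A `cell_annotation`.
#' @param params Parameter list as from [default_params()].
#' @return List with `clones` (named list of [clone_set()]), `catalog`
#'   (variant quality table), `donor_variants`, `H` (the heteroplasmy
#'   matrix) and `params`.
#' @export
mt_pipeline <- function(counts, annotation, params = default_params()) {
  H <- compute_heteroplasmy(counts)
  sel <- select_variants(counts, annotation, params)
  clones <- call_clones(H, annotation, params, donor_variants = sel$donor_variants)
  list(clones = clones, catalog = sel$catalog,
       donor_variants = sel$donor_variants, H = H, params = params)
}

#' Build a run manifest
#'
#' Provenance stamp embedded alongside every pipeline output: package
#' version, parameter snapshot, input file digests, seed and timestamp.
#' Result files rerun with the same config and seed are byte-identical;
#' the manifest's timestamp field is the one intentionally volatile entry.
#'
#' @param params Parameter list.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Integer seed used for any stochastic stage (`NA` if none).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params, inputs = character(), seed = NA_integer_) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(
    tool = "mtlineage",
    version = as.character(utils::packageVersion("mtlineage")),
    parameters = params,
    input_digests = digests,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @rdname run_manifest
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the pipeline from a config and write outputs
#'
#' Config is a list (or YAML path) with elements `matrix`, `cells`,
#' `variants` (heteroplasmy inputs), `annot` (annotation TSV), optional
#' `params` (parameter overrides) and `outdir`. Writes `clones.tsv`,
#' `catalog.tsv` and `manifest.json` into `outdir`. Stage outputs already
#' written are left intact if a later stage fails.
#'
#' @param config List or YAML file path.
#' @return Invisibly, the list returned by the calling stage plus output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("matrix", "cells", "variants", "annot", "params", "outdir", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("matrix", "cells", "variants", "annot", "outdir")) {
    if (is.null(config[[k]])) stop("config is missing required key: ", k)
  }
  params <- override_params(default_params(), as.list(config$params))
  H <- read_heteroplasmy(config$matrix, config$cells, config$variants)
  annotation <- read_cell_annotation(config$annot)
  clones <- call_clones(H, annotation, params)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  clones_path <- file.path(config$outdir, "clones.tsv")
  write_clone_assignments(clones, clones_path)
  manifest <- run_manifest(params,
                           inputs = c(config$matrix, config$cells,
                                      config$variants, config$annot),
                           seed = if (is.null(config$seed)) NA_integer_ else as.integer(config$seed))
  write_manifest(manifest, file.path(config$outdir, "manifest.json"))
  invisible(list(clones = clones, params = params, clones_path = clones_path))
}
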