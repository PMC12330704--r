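#' Canonical mitochondrial variant identifiers
#'
#' Variants are identified as `"<pos><ref>><alt>"` with 1-based mitochondrial
#' coordinates, e.g. `"3068G>A"`. `parse_variant_id()` also accepts the
#' underscore dialect `"3068G_A"` found in some genotyping outputs and
#' canonicalizes it.
#'
#' @param position Integer 1-based position on the mitochondrial genome.
#' @param ref,alt Single reference/alternate bases.
#' @return `variant_id()` returns a character vector of canonical ids;
#'   `parse_variant_id()` a data.frame with columns `variant_id` (canonical),
#'   `position`, `ref`, `alt`.
#' @examples
#' variant_id(3068, "G", "A")
#' parse_variant_id(c("3068G>A", "9321T_C"))
#' @export
variant_id <- function(position, ref, alt) {
  sprintf("%d%s>%s", as.integer(position), ref, alt)
}

#' @param x Character vector of variant ids in either dialect.
#' @rdname variant_id
#' @export
parse_variant_id <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)([ACGTN])[>_]([ACGTN])$", as.character(x)))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    stop("malformed variant id(s): ",
         paste(utils::head(x[bad], 5L), collapse = ", "))
  }
  pos <- as.integer(vapply(m, `[`, "", 2L))
  ref <- vapply(m, `[`, "", 3L)
  alt <- vapply(m, `[`, "", 4L)
  data.frame(variant_id = variant_id(pos, ref, alt),
             position = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Construct a heteroplasmy matrix object
#'
#' A cells-by-variants allele-fraction matrix with per-cell mean mitochondrial
#' coverage and an optional missing-data mask marking entries where the cell
#' had zero coverage at the variant position (distinct from an observed 0).
#'
#' @param values Numeric matrix (dense or `Matrix` sparse), cells in rows,
#'   variants in columns, entries in `[0, 1]`; dimnames required.
#' @param coverage Named numeric vector of per-cell mean mitochondrial
#'   coverage; defaults to `NA` for all cells.
#' @param missing Optional logical/pattern matrix of the same shape marking
#'   zero-coverage entries.
#' @return An object of class `heteroplasmy_matrix` with elements `values`
#'   (a `dgCMatrix`), `coverage`, `missing`.
#' @export
heteroplasmy_matrix <- function(values, coverage = NULL, missing = NULL) {
  if (!methods::is(values, "Matrix")) values <- Matrix::Matrix(values, sparse = TRUE)
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("values must carry cell (row) and variant (column) names")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    dimnames(values) <- list(
      if (is.null(rownames(values))) character() else rownames(values),
      if (is.null(colnames(values))) character() else colnames(values))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(values))) stop("duplicate variant ids")
  v <- values@x
  if (length(v) && (anyNA(v) || min(v) < 0 || max(v) > 1)) {
    stop("heteroplasmy values must lie in [0, 1]")
  }
  if (is.null(coverage)) {
    coverage <- stats::setNames(rep(NA_real_, nrow(values)), rownames(values))
  }
  coverage <- coverage[rownames(values)]
  names(coverage) <- rownames(values)
  if (any(!is.na(coverage) & coverage < 0)) stop("coverage must be non-negative")
  if (!is.null(missing)) {
    missing <- methods::as(methods::as(missing, "lMatrix"), "CsparseMatrix")
    if (!identical(dim(missing), dim(values))) stop("missing mask dimension mismatch")
    dimnames(missing) <- dimnames(values)
  }
  structure(list(values = values, coverage = coverage, missing = missing),
            class = "heteroplasmy_matrix")
}

#' @export
print.heteroplasmy_matrix <- function(x, ...) {
  cat(sprintf("heteroplasmy_matrix: %d cells x %d variants, %d nonzero entries\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.heteroplasmy_matrix <- function(x) dim(x$values)

#' Subset a heteroplasmy matrix by cells and/or variants
#'
#' @param H A `heteroplasmy_matrix`.
#' @param cells,variants Character vectors of ids to retain (order preserved
#'   as given); `NULL` keeps all.
#' @return A `heteroplasmy_matrix`.
#' @export
subset_heteroplasmy <- function(H, cells = NULL, variants = NULL) {
  stopifnot(inherits(H, "heteroplasmy_matrix"))
  if (is.null(cells)) cells <- rownames(H$values)
  if (is.null(variants)) variants <- colnames(H$values)
  vals <- H$values[cells, variants, drop = FALSE]
  miss <- if (!is.null(H$missing)) H$missing[cells, variants, drop = FALSE]
  heteroplasmy_matrix(vals, coverage = H$coverage[cells], missing = miss)
}

read_label_file <- function(path, header_name) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(data.frame(stats::setNames(list(character()), header_name),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  if (identical(fields[1L], header_name)) {
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                      colClasses = "character")
  } else {
    data.frame(stats::setNames(list(readLines(path)), header_name),
               stringsAsFactors = FALSE)
  }
}

read_mtx_file <- function(path, index_base = 1L) {
  if (index_base == 1L) return(Matrix::readMM(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  con <- textConnection(lines)
  on.exit(close(con))
  hdr <- scan(con, what = numeric(), n = 3, quiet = TRUE)
  body <- matrix(scan(con, what = numeric(), quiet = TRUE), ncol = 3, byrow = TRUE)
  Matrix::sparseMatrix(i = body[, 1] + 1L, j = body[, 2] + 1L, x = body[, 3],
                       dims = hdr[1:2])
}

#' Read a heteroplasmy matrix from MatrixMarket/TSV files
#'
#' Reads a sparse MatrixMarket (`.mtx`) file, or a dense tab-separated matrix,
#' together with sidecar row (cell) and column (variant) label files. Label
#' files may be headerless one-column lists or TSVs with a `cell_id` /
#' `variant_id` header; the cell table may carry a `mean_mito_coverage` column.
#'
#' @param matrix_path Path to the `.mtx` or dense TSV matrix (cells x variants).
#' @param cells_path Path to the cell label file.
#' @param variants_path Path to the variant label file.
#' @param index_base MatrixMarket index base; `1` (the MatrixMarket standard,
#'   default) or `0` for zero-based dialects.
#' @return A validated [heteroplasmy_matrix()].
#' @export
read_heteroplasmy <- function(matrix_path, cells_path, variants_path,
                              index_base = 1L) {
  stopifnot(index_base %in% c(0L, 1L))
  if (grepl("\\.mtx$", matrix_path)) {
    m <- read_mtx_file(matrix_path, index_base = as.integer(index_base))
  } else {
    tab <- utils::read.delim(matrix_path, header = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric entries in dense matrix: parse error")
  }
  cells <- read_label_file(cells_path, "cell_id")
  variants <- read_label_file(variants_path, "variant_id")
  if (nrow(m) != nrow(cells) || ncol(m) != nrow(variants)) {
    stop(sprintf("dimension mismatch: matrix is %d x %d but sidecars give %d cells, %d variants",
                 nrow(m), ncol(m), nrow(cells), nrow(variants)))
  }
  dimnames(m) <- list(cells$cell_id,
                      parse_variant_id(variants$variant_id)$variant_id)
  coverage <- NULL
  if ("mean_mito_coverage" %in% names(cells)) {
    coverage <- stats::setNames(as.numeric(cells$mean_mito_coverage), cells$cell_id)
  }
  heteroplasmy_matrix(m, coverage = coverage)
}

#' Write a heteroplasmy matrix to MatrixMarket/TSV files
#'
#' Inverse of [read_heteroplasmy()]; writes `matrix.mtx`, `cells.tsv`
#' (with coverage when known) and `variants.tsv` into `dir`.
#'
#' @param H A `heteroplasmy_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths written.
#' @export
write_heteroplasmy <- function(H, dir) {
  stopifnot(inherits(H, "heteroplasmy_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "cells.tsv", "variants.tsv"))
  Matrix::writeMM(H$values, paths[1L])
  cells <- data.frame(cell_id = rownames(H$values), stringsAsFactors = FALSE)
  if (!all(is.na(H$coverage))) cells$mean_mito_coverage <- H$coverage
  utils::write.table(cells, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant_id = colnames(H$values)), paths[3L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

TISSUE_CANONICAL <- c(tumor = "tumor", nilt = "NILT", pbmc = "PBMC")

#' Read a cell annotation table
#'
#' Tab-separated with header; required columns `cell_id`, `donor`, `sample`,
#' `tissue`, `cell_type` (optionally `mean_mito_coverage`). Tissue labels are
#' matched case-insensitively against `tumor`, `NILT`, `PBMC`; anything else is
#' mapped to `"other"` with a warning. Every sample must map to exactly one
#' donor and barcodes must be unique.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `cell_annotation` with factor columns whose
#'   levels preserve file order.
#' @export
read_cell_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  cell_annotation(df)
}

#' Validate a cell annotation data.frame
#'
#' @param df data.frame with columns `cell_id`, `donor`, `sample`, `tissue`,
#'   `cell_type`.
#' @return The validated data.frame, classed `cell_annotation`.
#' @export
cell_annotation <- function(df) {
  required <- c("cell_id", "donor", "sample", "tissue", "cell_type")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id: ", df$cell_id[duplicated(df$cell_id)][1L])
  }
  s2d <- unique(df[, c("sample", "donor")])
  if (anyDuplicated(s2d$sample)) {
    stop("sample mapped to more than one donor: ",
         s2d$sample[duplicated(s2d$sample)][1L])
  }
  tis <- as.character(df$tissue)
  canon <- TISSUE_CANONICAL[tolower(tis)]
  unknown <- is.na(canon)
  if (any(unknown)) {
    warning("unknown tissue label(s) mapped to 'other': ",
            paste(unique(tis[unknown]), collapse = ", "))
    canon[unknown] <- "other"
  }
  df$tissue <- factor(canon, levels = unique(canon))
  for (col in c("donor", "sample", "cell_type")) {
    df[[col]] <- factor(df[[col]], levels = unique(as.character(df[[col]])))
  }
  if ("mean_mito_coverage" %in% names(df)) {
    df$mean_mito_coverage <- as.numeric(df$mean_mito_coverage)
    if (any(df$mean_mito_coverage < 0, na.rm = TRUE)) {
      stop("mean_mito_coverage must be non-negative")
    }
  }
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Write clone assignments to a TSV file
#'
#' One row per cell with columns `cell_id`, `donor`, `clone_id`,
#' `clone_variants` (semicolon-joined variant ids of the cell's clone),
#' `assignment_status` in `assigned` / `unassigned` / `discarded_multi`.
#' Round-trips losslessly through [read_clone_assignments()].
#'
#' @param clones A `clone_set` or (possibly named) list of `clone_set`s.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_clone_assignments <- function(clones, path) {
  if (inherits(clones, "clone_set")) clones <- list(clones)
  tab <- do.call(rbind, lapply(clones, function(cs) {
    stopifnot(inherits(cs, "clone_set"))
    a <- cs$assignment
    cv <- vapply(a$clone_id, function(id) {
      if (is.na(id)) "" else paste(sort(cs$clones[[id]]), collapse = ";")
    }, "")
    data.frame(cell_id = a$cell_id, donor = cs$donor,
               clone_id = ifelse(is.na(a$clone_id), "", a$clone_id),
               clone_variants = cv, assignment_status = as.character(a$status),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clone assignments written by [write_clone_assignments()]
#'
#' @param path TSV path.
#' @return A named list of `clone_set` objects, one per donor.
#' @export
read_clone_assignments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  need <- c("cell_id", "donor", "clone_id", "clone_variants", "assignment_status")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab$clone_id[is.na(tab$clone_id)] <- ""
  tab$clone_variants[is.na(tab$clone_variants)] <- ""
  out <- lapply(split(tab, tab$donor), function(d) {
    defs <- unique(d[d$clone_id != "", c("clone_id", "clone_variants")])
    clones <- stats::setNames(
      lapply(defs$clone_variants, function(s) sort(strsplit(s, ";", fixed = TRUE)[[1L]])),
      defs$clone_id)
    clones <- clones[order(names(clones))]
    clone_set(
      donor = d$donor[1L],
      clones = clones,
      assignment = data.frame(
        cell_id = d$cell_id,
        clone_id = ifelse(d$clone_id == "", NA_character_, d$clone_id),
        status = factor(d$assignment_status,
                        levels = c("assigned", "unassigned", "discarded_multi")),
        stringsAsFactors = FALSE))
  })
  out[order(names(out))]
}
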