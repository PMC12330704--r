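# Small in-code fixtures shared across test files.

# A tiny strand-count object with hand-set counts.
toy_counts <- function() {
  cells <- sprintf("c%d", 1:4)
  vars <- c("100A>T", "200C>G")
  mk <- function(x) matrix(x, 4, 2, dimnames = list(cells, vars))
  strand_counts(
    alt_fwd = mk(c(3, 0, 0, 2, 0, 5, 0, 0)),
    alt_rev = mk(c(2, 0, 0, 1, 0, 4, 0, 0)),
    cov_fwd = mk(c(10, 8, 0, 6, 10, 10, 0, 5)),
    cov_rev = mk(c(10, 12, 0, 6, 10, 10, 0, 5)))
}

# A binary call matrix built directly from a 0/1 matrix.
toy_binary <- function(m, threshold = 0.07, donor = "D1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("%dA>T", 100 + seq_len(ncol(m)))
  H <- heteroplasmy_matrix(m * 0.5,
                           coverage = stats::setNames(rep(50, nrow(m)), rownames(m)))
  binarize(H, threshold = threshold, donor = donor)
}

# Assignment table builder for the analysis statistics.
toy_assign <- function(clone_id, donor = "D1", cell_type = "T", tissue = "tumor",
                       sample = NULL) {
  n <- length(clone_id)
  if (is.null(sample)) sample <- paste(donor, tissue, sep = "_")
  sample <- rep_len(sample, n)
  data.frame(cell_id = sprintf("cell%04d", seq_len(n)),
             clone_id = clone_id, status = rep_len("assigned", n),
             donor = rep_len(donor, n), sample = rep_len(sample, n),
             tissue = rep_len(tissue, n), cell_type = rep_len(cell_type, n),
             stringsAsFactors = FALSE)
}

# Cached fixture simulations (generated once per test run).
easy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_config("easy")
      sim <- simulate_heteroplasmy(fx$sim)
      res <- mt_pipeline(sim$counts, sim$annotation, fx$params)
      cache <<- list(fx = fx, sim = sim, res = res)
    }
    cache
  }
})

hard_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_config("hard")
      sim <- simulate_heteroplasmy(fx$sim)
      res <- mt_pipeline(sim$counts, sim$annotation, fx$params)
      cache <<- list(fx = fx, sim = sim, res = res)
    }
    cache
  }
})

sim_truth_labels <- function(sim) {
  keep <- !is.na(sim$truth$cells$clone)
  truth_labels(sim$truth$cells$cell_id[keep], sim$truth$cells$clone[keep])
}
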