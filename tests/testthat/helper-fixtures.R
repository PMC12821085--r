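# Shared fixtures, built in code. The full synthetic dataset (and the ABCC
# derivatives computed from it) is expensive, so it is memoised across test
# files in a package-local environment.

.fixture_cache <- new.env(parent = emptyenv())

# 3 chromosomes x 2000 fragments, 200 genes, 20 planted enhancer pairs,
# 10 planted GWAS causals -- the default study conditions.
cached_dataset <- function(seed = 101) {
  key <- paste0("ds_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ds <- simulate_dataset(seed)
  els <- candidate_elements(ds$peaks$atac, ds$peaks$h3k27ac, ds$genome$map)
  pairs <- abc_scores(els, ds$genome$promoters, ds$chicago$interactions,
                      ds$chicago$params, ds$genome$map)
  cons <- merge_consensus(ds$chicago$interactions, ds$chicago$binned,
                          ds$genome$map)
  out <- list(ds = ds, elements = els, pairs = pairs, consensus = cons)
  .fixture_cache[[key]] <- out
  out
}

# ten fragments of 100 bp on chr1, five of 200 bp on chr2
tiny_map <- function() {
  fragment_map(tibble::tibble(
    chrom = c(rep("chr1", 10), rep("chr2", 5)),
    start = c(seq(0, 900, by = 100), seq(0, 800, by = 200)),
    end = c(seq(100, 1000, by = 100), seq(200, 1000, by = 200))
  ))
}

tiny_params <- function(bmean = 5, ids = 0:14) {
  chicago_params(
    bmean = bmean,
    s_i = stats::setNames(rep(1, length(ids)), ids),
    s_j = stats::setNames(rep(1, length(ids)), ids),
    f_d = tibble::tibble(distance = c(100, 1000, 10000, 1e5, 1e6),
                         count = c(50, 5, 0.5, 0.05, 0.005))
  )
}

# interactions tibble at fragment grain from a compact spec matrix
tiny_interactions <- function(map, bait, oe, n = 1, reads = 1, score = 6) {
  k <- length(bait)
  capcogs:::build_interactions(as.integer(bait), as.integer(oe),
                               as.integer(oe),
                               rep_len(n, k), rep_len(reads, k),
                               rep_len(score, k), rep("fragment", k), map)
}
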