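test_that("expected contact is the Brownian level scaled by both factors", {
  p <- chicago_params(bmean = 5, s_i = c(`1` = 2), s_j = c(`2` = 1),
                      f_d = tibble::tibble(distance = 1, count = 1))
  expect_equal(expected_contact(p, 1, 2), 2.5)
  p1 <- chicago_params(bmean = 5, s_i = c(`1` = 1), s_j = c(`2` = 1),
                       f_d = tibble::tibble(distance = 1, count = 1))
  expect_equal(expected_contact(p1, 1, 2), 5)
  # the alternative order-of-operations reading is available behind a flag
  expect_equal(expected_contact(p, 1, 2, divide_both = FALSE), 2.5 * 1)
  expect_error(expected_contact(p, 99, 2), "missing bait scaling factor")
})

test_that("expected contact agrees with independent formula evaluation on random triples", {
  set.seed(11)
  ids <- as.character(1:100)
  si <- stats::setNames(exp(rnorm(100, 0, 0.3)), ids)
  sj <- stats::setNames(exp(rnorm(100, 0, 0.3)), ids)
  bm <- runif(1, 1, 10)
  p <- chicago_params(bm, si, sj, tibble::tibble(distance = 1, count = 1))
  b <- sample(1:100, 100, replace = TRUE)
  o <- sample(1:100, 100, replace = TRUE)
  got <- expected_contact(p, b, o)
  for (k in 1:100) {
    expect_equal(got[k], bm / si[[as.character(b[k])]] / sj[[as.character(o[k])]])
  }
})

test_that("distance function interpolates log-log and extrapolates end slopes", {
  p <- tiny_params() # knots are an exact power law f = 5000/d
  expect_equal(distance_function(p, 1000), 5)
  expect_equal(distance_function(p, 3162.2776), 5000 / 3162.2776,
               tolerance = 1e-6)
  # beyond the knots, continue with the end slope (power law -> exact)
  expect_equal(distance_function(p, 1e7), 5e-4, tolerance = 1e-9)
  expect_equal(distance_function(p, 10), 500, tolerance = 1e-9)
  d <- sort(runif(100, 50, 2e6))
  expect_true(all(diff(distance_function(p, d)) <= 1e-12))
  expect_error(distance_function(p, 0), "positive")
})

test_that("baited-promoter contact is the max of observed count and Brownian floor", {
  m <- tiny_map()
  p <- tiny_params()
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 51,
                         baited = TRUE, fragment_id = 0L)
  el <- assign_to_fragments(tibble::tibble(chrom = "chr1", start = 500, end = 600), m)
  ints <- tiny_interactions(m, bait = 0, oe = 5, n = 10)
  expect_equal(impute_contact(prom, el, ints, p, m), 10)
  # pair absent from the table: floor at N_exp
  ints0 <- tiny_interactions(m, bait = 0, oe = 9, n = 10)
  expect_equal(impute_contact(prom, el, ints0, p, m), 5)
  # observed below the floor: floor wins
  ints_lo <- tiny_interactions(m, bait = 0, oe = 5, n = 2)
  expect_equal(impute_contact(prom, el, ints_lo, p, m), 5)
  # trans pair is a domain error
  el2 <- assign_to_fragments(tibble::tibble(chrom = "chr2", start = 0, end = 100), m)
  expect_error(impute_contact(prom, el2, ints, p, m), "trans")
})

test_that("unbaited promoters use f(d), capped at f(median length) near the bait", {
  m <- tiny_map() # median fragment length 100
  p <- tiny_params()
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 51,
                         baited = FALSE, fragment_id = 0L)
  ints <- tiny_interactions(m, bait = 0, oe = 5, n = 10)
  # element on the adjacent fragment: capped at f(median fragment length)
  el_adj <- assign_to_fragments(tibble::tibble(chrom = "chr1", start = 110, end = 180), m)
  expect_equal(impute_contact(prom, el_adj, ints, p, m),
               distance_function(p, median_fragment_length(m)))
  # distal element: f(midpoint distance), ignoring any observed count
  el_far <- assign_to_fragments(tibble::tibble(chrom = "chr1", start = 500, end = 600), m)
  expect_equal(impute_contact(prom, el_far, ints, p, m),
               distance_function(p, abs(550 - 50)))
})

test_that("unbaited contact is non-increasing in distance beyond one fragment", {
  cd <- cached_dataset()
  m <- cd$ds$genome$map; p <- cd$ds$chicago$params
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = m$end[3],
                         baited = FALSE, fragment_id = 3L)
  starts <- seq(m$start[10], m$start[10] + 5e5, length.out = 40)
  cs <- vapply(starts, function(s) {
    el <- assign_to_fragments(tibble::tibble(chrom = "chr1", start = s, end = s + 500), m)
    impute_contact(prom, el, cd$ds$chicago$interactions[0, ], p, m)
  }, numeric(1))
  expect_true(all(diff(cs) <= 1e-12))
})

test_that("element activity is the geometric mean with pseudocount policy", {
  expect_equal(element_activity(4, 9), 6)
  expect_equal(element_activity(0, 9), 0) # zero absorbs at pc = 0
  cc <- c(0.5, 1, 7, 100)
  expect_equal(element_activity(cc, cc), cc) # idempotence
  expect_equal(element_activity(0, 9, pseudocount = 1), sqrt(10) - 1)
  expect_error(element_activity(-1, 2), "negative")
})

test_that("per-gene ABC scores normalise numerators over the window", {
  cd <- cached_dataset()
  pairs <- cd$pairs
  sums <- tapply(pairs$abc_score[!pairs$zero_denominator],
                 pairs$gene_id[!pairs$zero_denominator], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pairs$abc_score >= 0 & pairs$abc_score <= 1))
  # two elements with numerators {3, 1} score {0.75, 0.25}
  expect_equal(c(3, 1) / sum(c(3, 1)), c(0.75, 0.25))
  g <- pairs[pairs$gene_id == pairs$gene_id[1], ]
  expect_equal(g$abc_score, g$numerator / sum(g$numerator))
})

test_that("ABC scores match brute-force evaluation of the equation on a small locus", {
  m <- tiny_map()
  p <- tiny_params()
  prom <- tibble::tibble(gene_id = paste0("g", 1:5), chrom = "chr1",
                         tss = c(51, 151, 251, 351, 451), baited = TRUE,
                         fragment_id = 0:4)
  atac <- tibble::tibble(chrom = "chr1", start = c(520, 720, 820),
                         end = c(580, 780, 880), read_count = c(4, 9, 16),
                         assay = "ATAC")
  k27 <- tibble::tibble(chrom = "chr1", start = c(525, 725, 825),
                        end = c(575, 775, 875), read_count = c(9, 4, 25),
                        assay = "H3K27ac")
  els <- candidate_elements(atac, k27, m)
  ints <- tiny_interactions(m, bait = c(0, 0, 1), oe = c(5, 7, 8),
                            n = c(20, 8, 12))
  pairs <- abc_scores(els, prom, ints, p, m)
  # brute force for gene g1 (bait fragment 0): A = geometric means of the
  # assay counts; C = max(N_obs, bmean) since all scaling factors are 1, and
  # g1 observes counts 20 and 8 on fragments 5 and 7, nothing on 8
  A <- c(sqrt(4 * 9), sqrt(9 * 4), sqrt(16 * 25))
  C <- c(max(20, 5), max(8, 5), max(0, 5))
  num <- A * C
  g1 <- pairs[pairs$gene_id == "g1", ]
  expect_equal(g1$numerator, num)
  expect_equal(g1$abc_score, num / sum(num))
})

test_that("elements on the gene's own baited promoter fragment are excluded", {
  m <- tiny_map(); p <- tiny_params()
  prom <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 51,
                         baited = TRUE, fragment_id = 0L)
  atac <- tibble::tibble(chrom = "chr1", start = c(10, 520), end = c(90, 580),
                         read_count = c(5, 5), assay = "ATAC")
  k27 <- tibble::tibble(chrom = "chr1", start = c(12, 522), end = c(88, 578),
                        read_count = c(5, 5), assay = "H3K27ac")
  els <- candidate_elements(atac, k27, m)
  pairs <- abc_scores(els, prom, tiny_interactions(m, 0, 5, n = 1), p, m)
  expect_equal(nrow(pairs), 1L)
  expect_true(pairs$start == 520)
})

test_that("cutoff selection recovers a planted optimum and honours ties and degenerate grids", {
  cd <- cached_dataset()
  genes <- unique(cd$pairs$gene_id)
  expr <- make_expression(cd$pairs, genes, true_cutoff = 0.02, noise_sd = 0,
                          seed = 1)
  sel <- select_cutoff(cd$pairs, expr, grid = seq(0, 0.1, by = 0.002))
  expect_lte(abs(sel$cutoff - 0.02), 0.002)
  one <- select_cutoff(cd$pairs, expr, grid = 0.05)
  expect_equal(one$cutoff, 0.05)
  const <- expr; const$expression <- 1
  expect_error(select_cutoff(cd$pairs, const), "constant")
})

test_that("the cutoff-selection result tidies, glances and plots", {
  cd <- cached_dataset()
  genes <- unique(cd$pairs$gene_id)
  expr <- make_expression(cd$pairs, genes, true_cutoff = 0.02, seed = 1)
  sel <- select_cutoff(cd$pairs, expr, grid = seq(0, 0.05, by = 0.01))
  expect_named(tidy(sel), c("cutoff", "correlation", "n_genes"))
  expect_equal(nrow(glance(sel)), 1L)
  expect_s3_class(autoplot(sel), "ggplot")
})

test_that("pair calling filters at the cutoff and sorts by gene then score", {
  pairs <- tibble::tibble(gene_id = c("a", "a", "a"), element_id = 1:3,
                          numerator = c(3, 1, 0.04),
                          abc_score = c(0.75, 0.25, 0.01))
  called <- call_enhancer_pairs(pairs, 0.023)
  expect_equal(called$element_id, c(1L, 2L))
  expect_equal(nrow(call_enhancer_pairs(pairs, 0)), 3L)
  expect_equal(nrow(call_enhancer_pairs(pairs, 1.5)), 0L)
})

test_that("called pairs recover planted enhancers at the deployed cutoff", {
  cd <- cached_dataset()
  called <- call_enhancer_pairs(cd$pairs, 0.023)
  tr <- cd$ds$truth$planted_pairs
  rec <- vapply(seq_len(nrow(tr)), function(i) {
    el <- cd$elements$element_id[
      vapply(cd$elements$fragment_ids, function(f) tr$oe_frag[i] %in% f,
             logical(1))]
    any(called$gene_id == tr$gene_id[i] & called$element_id %in% el)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("baited contacts never fall below the Brownian floor", {
  cd <- cached_dataset()
  p <- cd$ds$chicago$params
  sub <- cd$pairs[sample(nrow(cd$pairs), 500), ]
  prom <- cd$ds$genome$promoters
  anchors <- prom[prom$baited, ]
  for (i in seq_len(nrow(sub))) {
    b <- anchors$fragment_id[match(sub$gene_id[i], anchors$gene_id)]
    if (is.na(b)) next
    floor_val <- min(expected_contact(p, b, cd$elements$fragment_ids[[
      match(sub$element_id[i], cd$elements$element_id)]]))
    expect_gte(sub$contact[i] + 1e-12, floor_val)
  }
})

test_that("precision and recall follow the labelled universe", {
  truth <- tibble::tibble(gene_id = c("a", "a", "b", "b"),
                          element_id = c(1, 2, 1, 2),
                          label = c("positive", "negative", "positive",
                                    "negative"))
  perfect <- truth[truth$label == "positive", c("gene_id", "element_id")]
  expect_equal(evaluate_pairs(perfect, truth)$precision, 1)
  expect_equal(evaluate_pairs(perfect, truth)$recall, 1)
  none <- truth[0, c("gene_id", "element_id")]
  expect_true(is.na(evaluate_pairs(none, truth)$precision))
  expect_equal(evaluate_pairs(none, truth)$recall, 0)
  # hand-counted toy: predict a1 (tp), b2 (fp), plus an out-of-universe pair
  pred <- tibble::tibble(gene_id = c("a", "b", "z"), element_id = c(1, 2, 9))
  res <- evaluate_pairs(pred, truth)
  expect_equal(res$precision, 1 / 2)
  expect_equal(res$recall, 1 / 2)
  expect_error(evaluate_pairs(pred, truth[0, ]), "empty truth")
})
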