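test_that("adjacent and book-ended PIR fragments collapse into one cPIR", {
  m <- fragment_map(tibble::tibble(
    chrom = "chr1",
    start = c(0, 100, 200, 350, 500, 700), end = c(100, 200, 350, 500, 700, 900)))
  anchors <- tibble::tibble(gene_id = "g", bait_id = 0L)
  # fragments 1 [100,200) and 2 [200,350): book-ended, merge to [100,350)
  cp <- collapse_pirs(tibble::tibble(gene_id = "g", fragment_id = c(1L, 2L)),
                      anchors, m)
  expect_equal(nrow(cp), 1L)
  expect_equal(c(cp$start, cp$end), c(100, 350))
  expect_equal(cp$member_ids[[1]], c(1L, 2L))
  # bait fragment [0,100): offset relative to its midpoint 50
  expect_equal(cp$offset_start, 50)
  # a non-adjacent fragment starts its own cPIR
  cp2 <- collapse_pirs(tibble::tibble(gene_id = "g", fragment_id = c(1L, 4L)),
                       anchors, m)
  expect_equal(nrow(cp2), 2L)
})

test_that("trans-chromosomal PIRs are removed before collapsing", {
  m <- tiny_map()
  cp <- collapse_pirs(tibble::tibble(gene_id = "g", fragment_id = c(3L, 12L)),
                      tibble::tibble(gene_id = "g", bait_id = 0L), m)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$chrom, "chr1")
})

test_that("cPIR merging equals an interval-union oracle on random fragment sets", {
  skip_if_not_installed("IRanges")
  m <- cached_dataset()$ds$genome$map
  chr1 <- m[m$chrom == "chr1", ]
  set.seed(31)
  anchors <- tibble::tibble(gene_id = "g", bait_id = 5L)
  for (rep in 1:1000) {
    ids <- sort(sample(chr1$fragment_id, sample(2:12, 1)))
    cp <- collapse_pirs(tibble::tibble(gene_id = "g", fragment_id = ids),
                        anchors, m)
    r <- match(ids, m$fragment_id)
    ora <- IRanges::reduce(IRanges::IRanges(start = m$start[r] + 1, end = m$end[r]))
    expect_equal(cp$start, IRanges::start(ora) - 1)
    expect_equal(cp$end, IRanges::end(ora))
  }
})

test_that("offsets reconstruct member positions exactly given the bait position", {
  cd <- cached_dataset()
  m <- cd$ds$genome$map
  cons <- cd$consensus[cd$consensus$score >= 5, ]
  prom <- cd$ds$genome$promoters
  anchors <- dplyr::distinct(prom[prom$baited, ], .data$gene_id,
                             bait_id = .data$fragment_id)
  anchors <- anchors[!duplicated(anchors$gene_id), ]
  pirs <- dplyr::inner_join(
    dplyr::transmute(cons, bait_id = .data$bait_id, fragment_id = .data$oe_frag),
    anchors, by = "bait_id")[, c("gene_id", "fragment_id")]
  cp <- collapse_pirs(pirs, anchors, m)
  arow <- match(anchors$bait_id[match(cp$gene_id, anchors$gene_id)], m$fragment_id)
  bait_mid <- (m$start[arow] + m$end[arow]) / 2
  for (i in seq_len(nrow(cp))) {
    mr <- match(cp$member_ids[[i]], m$fragment_id)
    expect_identical(bait_mid[i] + cp$member_offsets[[i]], m$start[mr])
  }
})

test_that("transplantation preserves counts, lengths and offsets, and is seed-deterministic", {
  cd <- cached_dataset()
  m <- cd$ds$genome$map
  prom <- cd$ds$genome$promoters
  anchors <- dplyr::distinct(prom[prom$baited, ], .data$gene_id,
                             bait_id = .data$fragment_id)
  anchors <- anchors[!duplicated(anchors$gene_id), ][1:50, ]
  set.seed(37)
  pirs <- tibble::tibble(
    gene_id = rep(anchors$gene_id[1:20], each = 3),
    fragment_id = anchors$bait_id[rep(1:20, each = 3)] +
      sample(c(-40:-10, 10:40), 60, replace = TRUE))
  pirs <- pirs[pirs$fragment_id %in% m$fragment_id, ]
  cp <- collapse_pirs(pirs, anchors, m)
  feats <- tibble::tibble(chrom = "chr1", start = c(1e5, 1e6), end = c(2e5, 1.1e6))
  null1 <- transplant_permutation(cp, anchors, feats, m, n_perm = 100, seed = 7)
  null2 <- transplant_permutation(cp, anchors, feats, m, n_perm = 100, seed = 7)
  expect_identical(null1$prop, null2$prop)
  expect_equal(nrow(null1), 100L)
  # size/offset preservation is structural: the transplanted intervals are
  # anchor + offset with the original length, for every gene and permutation
  expect_true(all(cp$length == cp$end - cp$start))
})

test_that("uniformly placed features give calibrated (fold ~ 1) enrichment", {
  cd <- cached_dataset()
  m <- cd$ds$genome$map
  prom <- cd$ds$genome$promoters
  anchors <- dplyr::distinct(prom[prom$baited, ], .data$gene_id,
                             bait_id = .data$fragment_id)
  anchors <- anchors[!duplicated(anchors$gene_id), ]
  set.seed(41)
  pirs <- tibble::tibble(
    gene_id = rep(anchors$gene_id[1:60], each = 2),
    fragment_id = anchors$bait_id[rep(1:60, each = 2)] +
      sample(c(-60:-10, 10:60), 120, replace = TRUE))
  pirs <- pirs[pirs$fragment_id %in% m$fragment_id, ]
  cp <- collapse_pirs(pirs, anchors, m)
  bounds <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(m), .data$chrom),
                             hi = max(.data$end), .groups = "drop")
  ch <- sample(bounds$chrom, 300, replace = TRUE)
  s <- floor(runif(300, 0, bounds$hi[match(ch, bounds$chrom)] - 2000))
  feats <- tibble::tibble(chrom = ch, start = s, end = s + 1500)
  null <- transplant_permutation(cp, anchors, feats, m, n_perm = 100, seed = 43)
  enr <- feature_enrichment(cp, feats, null)
  z <- abs(enr$observed_prop - enr$null_mean) / enr$null_sd
  expect_lt(z, 3)
  expect_gt(enr$fold, 0)
})

test_that("enrichment folds and delta-method intervals match closed forms", {
  cp <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = c(0, 1000), end = c(500, 1500),
                       length = 500, offset_start = c(0, 1000),
                       member_ids = list(0L, 1L), member_offsets = list(0, 1000))
  null <- structure(tibble::tibble(perm = 1:4, prop = c(0.5, 0.5, 0.5, 0.5)),
                    class = c("transplant_null", class(tibble::tibble())),
                    n_redrawn = 0L, n_cpirs = 2L)
  # features covering every cPIR with null mean 0.5: fold 2
  full <- tibble::tibble(chrom = "chr1", start = 0, end = 2000)
  enr <- feature_enrichment(cp, full, null)
  expect_equal(enr$observed_prop, 1)
  expect_equal(enr$fold, 2)
  # independent delta-method computation on a fixed toy
  null2 <- structure(tibble::tibble(perm = 1:4, prop = c(0.4, 0.6, 0.5, 0.5)),
                     class = class(null), n_redrawn = 0L, n_cpirs = 2L)
  half <- tibble::tibble(chrom = "chr1", start = 0, end = 600)
  enr2 <- feature_enrichment(cp, half, null2)
  p_obs <- 0.5; n <- 2
  p_null <- mean(c(0.4, 0.6, 0.5, 0.5)); v_null <- var(c(0.4, 0.6, 0.5, 0.5)) / 4
  se_log <- sqrt(p_obs * (1 - p_obs) / n / p_obs^2 + v_null / p_null^2)
  expect_equal(enr2$fold, p_obs / p_null)
  expect_equal(enr2$ci_lo, (p_obs / p_null) * exp(-1.96 * se_log))
  expect_equal(enr2$ci_hi, (p_obs / p_null) * exp(1.96 * se_log))
  # observed equal to the null mean: fold 1, CI straddles 1
  exact <- feature_enrichment(cp, half, null)
  expect_equal(exact$fold, 1)
  expect_lt(exact$ci_lo, 1); expect_gt(exact$ci_hi, 1)
})

test_that("enrichment of the cPIRs against themselves has observed proportion 1", {
  cd <- cached_dataset()
  m <- cd$ds$genome$map
  anchors <- tibble::tibble(gene_id = c("g1", "g2"), bait_id = c(10L, 2050L))
  pirs <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                         fragment_id = c(40L, 41L, 2100L))
  cp <- collapse_pirs(pirs, anchors, m)
  null <- transplant_permutation(cp, anchors, cp[, c("chrom", "start", "end")],
                                 m, n_perm = 10, seed = 3)
  enr <- feature_enrichment(cp, cp[, c("chrom", "start", "end")], null)
  expect_equal(enr$observed_prop, 1)
})

# all eight 2-promoter configurations: PIR contacts P1 at >= 5 and the three
# rescue channels for P2 (direct >= 5, lenient in [3,5), adjacent >= 3)
test_that("the sharing classifier reproduces the 2-promoter rule table", {
  m <- fragment_map(tibble::tibble(
    chrom = "chr1", start = 0:59 * 100, end = 1:60 * 100))
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         tss = c(251, 1251), baited = TRUE,
                         fragment_id = c(2L, 12L))
  base <- function(extra_oe = integer(), extra_bait = integer(),
                   extra_score = numeric()) {
    # both promoters qualify via strong contacts; PIR under test is fragment 40
    tiny_interactions(
      m,
      bait = c(2, 12, 2, extra_bait),
      oe = c(30, 50, 40, extra_oe),
      score = c(9, 9, 6, extra_score),
      reads = 10)
  }
  run <- function(ints) {
    res <- classify_pir_sharing(ints, prom, "g")
    res$label[res$pir_fragment == 40]
  }
  # no contact from P2 anywhere near the PIR: distinct
  expect_equal(run(base()), "distinct")
  # direct contact at >= 5 from both: fully shared
  expect_equal(run(base(40, 12, 8)), "fully_shared")
  # lenient direct rescue (score in [3, 5)): shared
  expect_equal(run(base(40, 12, 3.2)), "fully_shared")
  expect_equal(run(base(40, 12, 2.9)), "distinct")
  # adjacent-fragment rescue at >= 3 on either side
  expect_equal(run(base(39, 12, 4)), "fully_shared")
  expect_equal(run(base(41, 12, 4)), "fully_shared")
  expect_equal(run(base(41, 12, 2.5)), "distinct")
  # rescue via P2 contacting two fragments, both sub-lenient: still distinct
  expect_equal(run(base(c(39, 41), c(12, 12), c(2, 2))), "distinct")
})

test_that("2-promoter genes never yield partially_shared; 3-promoter genes can", {
  m <- fragment_map(tibble::tibble(
    chrom = "chr1", start = 0:59 * 100, end = 1:60 * 100))
  prom2 <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = c(251, 1251),
                          baited = TRUE, fragment_id = c(2L, 12L))
  set.seed(47)
  for (rep in 1:20) {
    oe <- sample(25:55, 6)
    ints <- tiny_interactions(m, bait = sample(c(2, 12), 6, replace = TRUE),
                              oe = oe, score = runif(6, 2, 9), reads = 10)
    ints <- dplyr::bind_rows(
      tiny_interactions(m, bait = c(2, 12), oe = c(30, 50), score = 9, reads = 10),
      ints)
    res <- classify_pir_sharing(ints, prom2, "g")
    expect_false(any(res$label == "partially_shared"))
  }
  prom3 <- tibble::tibble(gene_id = "g", chrom = "chr1",
                          tss = c(251, 1251, 2251), baited = TRUE,
                          fragment_id = c(2L, 12L, 22L))
  ints3 <- tiny_interactions(m, bait = c(2, 12, 22, 2, 12),
                             oe = c(30, 50, 55, 45, 45),
                             score = c(9, 9, 9, 8, 8), reads = 10)
  res3 <- classify_pir_sharing(ints3, prom3, "g")
  expect_equal(res3$label[res3$pir_fragment == 45], "partially_shared")
})

test_that("non-qualifying genes are a contract error", {
  m <- tiny_map()
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = c(51, 251),
                         baited = c(TRUE, FALSE), fragment_id = c(0L, 2L))
  ints <- tiny_interactions(m, bait = 0, oe = 5, score = 9, reads = 10)
  expect_error(classify_pir_sharing(ints, prom, "g"), "does not qualify")
  # two baited promoters but one lacks the read support
  prom2 <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = c(51, 251),
                          baited = TRUE, fragment_id = c(0L, 2L))
  ints2 <- tiny_interactions(m, bait = c(0, 2), oe = c(5, 7),
                             score = c(9, 9), reads = c(10, 2))
  expect_error(classify_pir_sharing(ints2, prom2, "g"), "does not qualify")
})
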