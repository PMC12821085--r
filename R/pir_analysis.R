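# Collapsed-PIR construction, the transplantation permutation test for
# epigenomic feature enrichment, and the alternative-promoter PIR-sharing
# classifier.
#
# The transplantation null preserves, for each gene, the number, sizes and
# bait-relative spatial arrangement of its collapsed PIRs: the whole cPIR
# set is re-anchored at a randomly chosen gene's baited fragment, so the
# distance-from-bait structure of real data is kept intact under the null.

#' Collapse a gene's PIRs into contiguous blocks (cPIRs)
#'
#' Trans-chromosomal PIRs are removed; overlapping or book-ended
#' (adjacent-fragment) PIR fragments are merged per gene. Each cPIR records
#' its member fragments and its signed bp offset from the gene's baited
#' fragment midpoint, so the set can be transplanted to another anchor
#' exactly.
#'
#' @param pirs Tibble `gene_id`, `fragment_id` of PIR fragments (one row per
#'   PIR fragment), e.g. the other ends of significant consensus
#'   interactions.
#' @param anchors Tibble `gene_id`, `bait_id` giving each gene's baited
#'   anchor fragment.
#' @param map The `fragment_map`.
#' @return Tibble of cPIRs: `gene_id`, `chrom`, `start`, `end`, `length`,
#'   `offset_start` (start minus bait midpoint, bp), `member_ids`
#'   (list-column), `member_offsets` (list-column of member start offsets).
#' @export
collapse_pirs <- function(pirs, anchors, map) {
  stopifnot(all(c("gene_id", "fragment_id") %in% names(pirs)),
            all(c("gene_id", "bait_id") %in% names(anchors)))
  pirs <- dplyr::distinct(dplyr::as_tibble(pirs), .data$gene_id, .data$fragment_id)
  rows <- match(pirs$fragment_id, map$fragment_id)
  if (any(is.na(rows))) stop("PIR fragment absent from the map")
  pirs$chrom <- map$chrom[rows]
  arow <- match(anchors$bait_id[match(pirs$gene_id, anchors$gene_id)],
                map$fragment_id)
  if (any(is.na(arow))) stop("gene without a baited anchor fragment")
  pirs$bait_chrom <- map$chrom[arow]
  pirs$bait_mid <- (map$start[arow] + map$end[arow]) / 2
  pirs <- pirs[pirs$chrom == pirs$bait_chrom, , drop = FALSE] # drop trans PIRs
  if (nrow(pirs) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = double(), end = double(), length = double(),
                          offset_start = double(), member_ids = list(),
                          member_offsets = list()))
  }
  pirs <- dplyr::arrange(pirs, .data$gene_id, .data$fragment_id)
  purrr::map_dfr(split(seq_len(nrow(pirs)), pirs$gene_id), function(ix) {
    ids <- pirs$fragment_id[ix]
    runs <- cumsum(c(1L, diff(ids) > 1L)) # book-ended = adjacent fragment ids
    bait_mid <- pirs$bait_mid[ix][1]
    purrr::map_dfr(split(ids, runs), function(mem) {
      r <- match(mem, map$fragment_id)
      tibble::tibble(
        gene_id = pirs$gene_id[ix][1], chrom = map$chrom[r][1],
        start = min(map$start[r]), end = max(map$end[r]),
        length = max(map$end[r]) - min(map$start[r]),
        offset_start = min(map$start[r]) - bait_mid,
        member_ids = list(mem),
        member_offsets = list(map$start[r] - bait_mid)
      )
    })
  })
}

#' Transplantation permutation null for cPIR feature overlap
#'
#' Each permutation re-anchors every gene's complete cPIR set at the baited
#' fragment of a randomly selected gene (targets drawn uniformly without
#' replacement within a permutation, the source gene being an eligible
#' target of itself), preserving every cPIR's size and bait-relative offset
#' exactly. Transplants that would exceed chromosome bounds are re-drawn
#' (count logged as an attribute). The per-permutation statistic is the
#' proportion of transplanted cPIRs overlapping at least one feature bp.
#'
#' @param cpirs cPIR tibble from [collapse_pirs()].
#' @param gene_universe Tibble `gene_id`, `bait_id` of candidate target
#'   genes (>= 2 genes).
#' @param features Tibble of feature intervals `chrom`, `start`, `end`
#'   (0-based half-open), e.g. ATAC or H3K27ac peaks.
#' @param map The `fragment_map` (supplies anchor positions and chromosome
#'   bounds).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed; a fixed seed gives a bit-identical null vector.
#' @param keep_transplants If `TRUE`, every transplanted interval is retained
#'   in attribute `transplants` (`perm`, `gene_id`, `target_gene`, `chrom`,
#'   `start`, `end`, `length`, `offset_start`) so preservation of sizes and
#'   offsets can be audited.
#' @return Object of class `transplant_null`: tibble `perm`, `prop`, with
#'   attributes `n_redrawn` and `n_cpirs`.
#' @export
transplant_permutation <- function(cpirs, gene_universe, features, map,
                                   n_perm = 100, seed = 1,
                                   keep_transplants = FALSE) {
  if (nrow(gene_universe) < 2L) stop("gene universe must contain >= 2 genes")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  arow <- match(gene_universe$bait_id, map$fragment_id)
  if (any(is.na(arow))) stop("universe gene without anchor fragment in map")
  anchor_mid <- (map$start[arow] + map$end[arow]) / 2
  anchor_chrom <- map$chrom[arow]
  bounds <- chrom_bounds(map)
  blo <- bounds$chrom_start[match(anchor_chrom, bounds$chrom)]
  bhi <- bounds$chrom_end[match(anchor_chrom, bounds$chrom)]
  src <- split(seq_len(nrow(cpirs)), cpirs$gene_id)
  src_genes <- names(src)
  n_redrawn <- 0L
  kept <- if (keep_transplants) vector("list", n_perm) else NULL
  props <- vapply(seq_len(n_perm), function(p) {
    targets <- sample.int(nrow(gene_universe), length(src_genes),
                          replace = FALSE)
    n_overlap <- 0L; n_total <- 0L
    rows <- if (keep_transplants) vector("list", length(src_genes)) else NULL
    for (k in seq_along(src_genes)) {
      ix <- src[[src_genes[k]]]
      tg <- targets[k]
      for (try in seq_len(1000L)) {
        new_start <- anchor_mid[tg] + cpirs$offset_start[ix]
        new_end <- new_start + cpirs$length[ix]
        if (all(new_start >= blo[tg]) && all(new_end <= bhi[tg])) break
        n_redrawn <<- n_redrawn + 1L
        tg <- sample.int(nrow(gene_universe), 1L)
      }
      ch <- anchor_chrom[tg]
      ov <- overlaps_any(ch, new_start, new_end, features)
      n_overlap <- n_overlap + sum(ov)
      n_total <- n_total + length(ov)
      if (keep_transplants) {
        rows[[k]] <- tibble::tibble(
          perm = p, gene_id = src_genes[k],
          target_gene = gene_universe$gene_id[tg], chrom = ch,
          start = new_start, end = new_end,
          length = cpirs$length[ix], offset_start = cpirs$offset_start[ix])
      }
    }
    if (keep_transplants) kept[[p]] <<- dplyr::bind_rows(rows)
    n_overlap / n_total
  }, numeric(1))
  structure(tibble::tibble(perm = seq_len(n_perm), prop = props),
            class = c("transplant_null", class(tibble::tibble())),
            n_redrawn = n_redrawn, n_cpirs = nrow(cpirs), seed = seed,
            transplants = if (keep_transplants) dplyr::bind_rows(kept))
}

# >=1 bp overlap of query half-open intervals with any feature interval
overlaps_any <- function(chrom, start, end, features) {
  chrom <- rep_len(chrom, length(start))
  out <- rep(FALSE, length(start))
  for (ch in unique(chrom)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    q <- which(chrom == ch)
    if (nrow(f) == 0L || length(q) == 0L) next
    for (i in seq_len(nrow(f))) {
      out[q] <- out[q] | (start[q] < f$end[i] & end[q] > f$start[i])
    }
  }
  out
}

#' Feature enrichment of observed cPIRs against a transplantation null
#'
#' Fold enrichment is the observed proportion of cPIRs overlapping at least
#' one feature bp, divided by the permutation-null mean proportion. The 95%
#' confidence interval propagates both error sources on the log-fold scale
#' (delta method): the binomial standard error of the observed proportion
#' and the standard error of the null mean.
#'
#' @param cpirs cPIR tibble from [collapse_pirs()].
#' @param features Feature interval tibble `chrom`, `start`, `end`.
#' @param null A `transplant_null` from [transplant_permutation()].
#' @return Object of class `enrichment_result`: one-row tibble
#'   `observed_prop`, `null_mean`, `null_sd`, `fold`, `ci_lo`, `ci_hi`,
#'   `n_cpirs`, `n_perm`. Has [tidy()], [glance()] and autoplot methods.
#' @export
feature_enrichment <- function(cpirs, features, null) {
  n <- nrow(cpirs)
  if (n == 0L) stop("no cPIRs")
  obs <- mean(overlaps_any(cpirs$chrom, cpirs$start, cpirs$end, features))
  null_mean <- mean(null$prop)
  null_sd <- stats::sd(null$prop)
  if (null_mean == 0) stop("null mean overlap is 0; fold undefined")
  fold <- obs / null_mean
  var_obs <- obs * (1 - obs) / n
  var_null_mean <- null_sd^2 / nrow(null)
  se_log <- sqrt(var_obs / max(obs, .Machine$double.eps)^2 +
                   var_null_mean / null_mean^2)
  res <- tibble::tibble(
    observed_prop = obs, null_mean = null_mean, null_sd = null_sd,
    fold = fold, ci_lo = fold * exp(-1.96 * se_log),
    ci_hi = fold * exp(1.96 * se_log),
    n_cpirs = n, n_perm = nrow(null)
  )
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Classify PIR sharing between a gene's alternative promoters
#'
#' For genes with more than one baited promoter, each with at least one
#' significant interaction (CHiCAGO score >= `score_sig` and >=
#' `min_reads` reads), each significant PIR is labelled: `fully_shared` if
#' it contacts all qualifying promoters at score >= `score_sig` (after
#' rescue, see below); `partially_shared` if a strict subset of more than
#' one (only possible with > 2 promoters); `distinct` otherwise. A
#' candidate-distinct PIR is rescued to shared if it, or either fragment
#' adjacent to it, contacts another promoter at the lenient score >=
#' `score_lenient`.
#'
#' @param interactions Interaction tibble at fragment grain (`bait_id`,
#'   `oe_first`, `score`, `raw_reads`).
#' @param promoters Promoter tibble; only baited promoters of `gene_id`
#'   participate.
#' @param gene_id Gene to classify.
#' @param score_sig Significant-contact score threshold (default 5).
#' @param min_reads Minimum raw reads for a promoter to qualify (default 5).
#' @param score_lenient Lenient rescue threshold (default 3).
#' @return Tibble `gene_id`, `pir_fragment`, `n_promoters`,
#'   `n_contacted`, `label` in
#'   `{"fully_shared","partially_shared","distinct"}`.
#' @export
classify_pir_sharing <- function(interactions, promoters, gene_id,
                                 score_sig = 5, min_reads = 5,
                                 score_lenient = 3) {
  pf <- promoters$fragment_id[promoters$gene_id == gene_id & promoters$baited]
  pf <- unique(pf)
  ints <- interactions[interactions$bait_id %in% pf, , drop = FALSE]
  qualifies <- vapply(pf, function(f) {
    any(ints$bait_id == f & ints$score >= score_sig & ints$raw_reads >= min_reads)
  }, logical(1))
  pf <- pf[qualifies]
  if (length(pf) < 2L) {
    stop(sprintf("gene %s does not qualify: needs > 1 baited promoter with a significant interaction (score >= %g, >= %g reads)",
                 gene_id, score_sig, min_reads))
  }
  ints <- ints[ints$bait_id %in% pf, , drop = FALSE]
  sig_pirs <- sort(unique(ints$oe_first[ints$score >= score_sig]))
  purrr::map_dfr(sig_pirs, function(pir) {
    contacted <- pf[vapply(pf, function(f) {
      any(ints$bait_id == f & ints$oe_first == pir & ints$score >= score_sig)
    }, logical(1))]
    others <- setdiff(pf, contacted)
    # rescue: the PIR itself, or either adjacent fragment, contacts another
    # promoter at the lenient threshold
    rescued <- others[vapply(others, function(f) {
      any(ints$bait_id == f & ints$oe_first %in% c(pir - 1L, pir, pir + 1L) &
            ints$score >= score_lenient)
    }, logical(1))]
    eff <- union(contacted, rescued)
    label <- if (length(eff) == length(pf)) "fully_shared"
             else if (length(eff) > 1L) "partially_shared"
             else "distinct"
    tibble::tibble(gene_id = gene_id, pir_fragment = pir,
                   n_promoters = length(pf), n_contacted = length(eff),
                   label = label)
  })
}
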