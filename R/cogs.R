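# Gene prioritisation from fine-mapped GWAS signals through promoter
# contacts. Per-gene feature sets combine four categories of genomic loci:
# coding SNPs, promoter-proximal fragments (TSS fragment +/- 5), CHiCAGO
# PIRs (score >= 5) and ABCC enhancers (score >= 0.04). A signal's score for
# a gene is the posterior mass falling in any feature; multiCOGS combines
# signals as 1 - prod(1 - s).

COGS_CATEGORIES <- c("coding", "promoter_proximal", "pchic_pir", "abcc_enhancer")

#' The major histocompatibility complex exclusion interval
#'
#' GRCh38 6:28510120-33480577, as a 1-based closed interval on variant
#' positions. Variants inside it are removed before scoring because the
#' region's extreme LD breaks fine-mapping assumptions.
#'
#' @return Tibble `chrom`, `start`, `end` (1-based closed).
#' @export
mhc_region <- function() {
  tibble::tibble(chrom = "6", start = 28510120, end = 33480577)
}

norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Remove variants falling inside an exclusion region
#'
#' @param x Tibble with `chrom` and `pos` (1-based), e.g. summary statistics
#'   or a signals table.
#' @param region One-row-per-region tibble `chrom`, `start`, `end`
#'   (1-based closed); default the MHC interval. `chr` prefixes are ignored
#'   when matching chromosomes. An empty region table is the identity.
#' @return `x` without the rows inside any region.
#' @export
exclude_region <- function(x, region = mhc_region()) {
  if (is.null(region) || nrow(region) == 0L) return(x)
  drop <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(region))) {
    drop <- drop | (norm_chrom(x$chrom) == norm_chrom(region$chrom[i]) &
                      x$pos >= region$start[i] & x$pos <= region$end[i])
  }
  x[!drop, , drop = FALSE]
}

#' Assemble a gene's COGS feature set
#'
#' Features are the union over all the gene's promoters of (i) the gene's
#' coding variant positions, (ii) the TSS fragment plus `proximal_fragments`
#' fragments on each side, (iii) other-end fragments of consensus
#' interactions with CHiCAGO score >= `chicago_score_min` anchored at the
#' gene's baited promoter fragments, and (iv) fragments of ABCC elements
#' paired to the gene at `abc_score >= abcc_cogs_min`. Unbaited promoters
#' contribute (i) and (ii) only. Promoters are included irrespective of
#' whether they were baited in the capture design.
#'
#' @param gene_id Gene identifier.
#' @param promoters Promoter tibble ([read_promoters()]).
#' @param map The `fragment_map`.
#' @param consensus Consensus interaction tibble ([merge_consensus()]), or a
#'   fragment-grain interaction table with `bait_id`, `oe_frag`, `score`.
#' @param abcc_pairs ABCC pair tibble ([abc_scores()]).
#' @param coding_snps Tibble `gene_id`, `variant`, `chrom`, `pos` mapping
#'   coding variants to genes (external annotation, e.g. a VEP export).
#' @param chicago_score_min CHiCAGO score threshold for PIR features
#'   (default 5).
#' @param abcc_cogs_min ABCC score threshold for enhancer features
#'   (default 0.04).
#' @param proximal_fragments Half-width of the promoter-proximal window in
#'   fragments (default 5).
#' @return Feature tibble: `gene_id`, `category`, `chrom`, `start`, `end`
#'   (0-based half-open; coding features are the 1-bp interval of the
#'   variant position), `fragment_id` (`NA` for coding).
#' @export
build_gene_features <- function(gene_id, promoters, map, consensus = NULL,
                                abcc_pairs = NULL, coding_snps = NULL,
                                chicago_score_min = 5, abcc_cogs_min = 0.04,
                                proximal_fragments = 5L) {
  pr <- promoters[promoters$gene_id == gene_id, , drop = FALSE]
  if (nrow(pr) == 0L) stop(sprintf("gene %s has no annotated TSS", gene_id))
  feats <- list()

  frag_rows <- function(ids, category) {
    ids <- unique(ids[!is.na(ids)])
    if (length(ids) == 0L) return(NULL)
    r <- match(ids, map$fragment_id)
    tibble::tibble(gene_id = gene_id, category = category,
                   chrom = map$chrom[r], start = map$start[r],
                   end = map$end[r], fragment_id = ids)
  }

  # (ii) promoter-proximal: TSS fragment +/- proximal_fragments, clipped to
  # the fragment's chromosome
  prox <- unlist(lapply(seq_len(nrow(pr)), function(i) {
    fid <- pr$fragment_id[i]
    r <- match(fid, map$fragment_id)
    cand <- (fid - proximal_fragments):(fid + proximal_fragments)
    keep <- cand[cand %in% map$fragment_id]
    keep[map$chrom[match(keep, map$fragment_id)] == map$chrom[r]]
  }))
  feats$prox <- frag_rows(prox, "promoter_proximal")

  # (i) coding SNPs for the gene
  if (!is.null(coding_snps)) {
    cs <- coding_snps[coding_snps$gene_id == gene_id, , drop = FALSE]
    if (nrow(cs) > 0L) {
      feats$coding <- tibble::tibble(
        gene_id = gene_id, category = "coding", chrom = as.character(cs$chrom),
        start = cs$pos - 1, end = cs$pos, fragment_id = NA_integer_)
    }
  }

  # (iii) PIRs of the gene's baited promoters at score >= threshold
  if (!is.null(consensus) && nrow(consensus) > 0L) {
    baited <- pr$fragment_id[pr$baited]
    oe_col <- if ("oe_frag" %in% names(consensus)) "oe_frag" else "oe_first"
    sel <- consensus$bait_id %in% baited & consensus$score >= chicago_score_min
    feats$pir <- frag_rows(consensus[[oe_col]][sel], "pchic_pir")
  }

  # (iv) ABCC enhancer fragments at COGS-input threshold
  if (!is.null(abcc_pairs) && nrow(abcc_pairs) > 0L) {
    ap <- abcc_pairs[abcc_pairs$gene_id == gene_id &
                       abcc_pairs$abc_score >= abcc_cogs_min, , drop = FALSE]
    if (nrow(ap) > 0L) {
      ids <- if ("fragment_ids" %in% names(ap)) unlist(ap$fragment_ids)
             else unlist(assign_to_fragments(ap, map)$fragment_ids)
      feats$abcc <- frag_rows(ids, "abcc_enhancer")
    }
  }

  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(gene_id = character(), category = character(),
                          chrom = character(), start = double(),
                          end = double(), fragment_id = integer())
  }
  dplyr::distinct(out)
}

# which signal variants (1-based pos) fall inside any feature interval
variants_in_features <- function(features, chrom, pos) {
  if (nrow(features) == 0L || length(pos) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  fch <- norm_chrom(features$chrom)
  vch <- norm_chrom(chrom)
  for (ch in unique(fch)) {
    f <- features[fch == ch, , drop = FALSE]
    v <- which(vch == ch)
    if (length(v) == 0L) next
    p0 <- pos[v] - 1
    for (i in seq_len(nrow(f))) {
      hit[v] <- hit[v] | (p0 >= f$start[i] & p0 < f$end[i])
    }
  }
  hit
}

#' Score one fine-mapped signal for a gene
#'
#' The sum of posterior inclusion probabilities over the unique variants
#' falling inside any of the gene's features; a variant lying in several
#' features (e.g. both a PIR and the proximal window) counts once. The sum
#' is clipped to [0, 1] (clipping events are messaged).
#'
#' @param features Feature tibble from [build_gene_features()], optionally
#'   restricted to a category.
#' @param signal Tibble of one signal's variants: `variant`, `chrom`, `pos`,
#'   `pip`.
#' @param on_unknown_position `"drop"` (default, with a warning) or
#'   `"error"` for pip-carrying variants with missing positions.
#' @return Scalar score in [0, 1].
#' @export
score_signal_for_gene <- function(features, signal,
                                  on_unknown_position = c("drop", "error")) {
  on_unknown_position <- match.arg(on_unknown_position)
  bad <- is.na(signal$pos) | is.na(signal$chrom)
  if (any(bad)) {
    if (on_unknown_position == "error") stop("unknown variant position(s) in signal")
    warning(sprintf("%d variant(s) with unknown position dropped", sum(bad)))
    signal <- signal[!bad, , drop = FALSE]
  }
  signal <- dplyr::distinct(signal, .data$variant, .keep_all = TRUE)
  hit <- variants_in_features(features, signal$chrom, signal$pos)
  s <- sum(signal$pip[hit])
  if (s > 1) {
    message(sprintf("per-signal score %.6f clipped to 1", s))
    s <- 1
  }
  s
}

#' Combine per-signal scores into a multiCOGS gene score
#'
#' The probability that at least one fine-mapped signal is linked to the
#' gene: \eqn{1 - \prod_k (1 - s_k)} over all (LD block, credible set)
#' signals.
#'
#' @param scores Numeric vector of per-signal scores, each in [0, 1].
#' @return Scalar in [0, 1]; 0 for no signals.
#' @export
multicogs_score <- function(scores) {
  if (length(scores) == 0L) return(0)
  if (any(scores < 0 | scores > 1)) stop("per-signal score outside [0, 1]")
  1 - prod(1 - scores)
}

#' Standard (single-causal) COGS gene score
#'
#' The same combination machinery as [multicogs_score()] applied to
#' single-causal posterior vectors: exactly one credible set per LD block is
#' required.
#'
#' @param scores Numeric vector of per-block scores.
#' @param block_ids Block identifier per score; duplicates are a contract
#'   error.
#' @return Scalar in [0, 1].
#' @export
standard_cogs_score <- function(scores, block_ids) {
  if (anyDuplicated(block_ids)) {
    stop("standard COGS takes exactly one credible set per LD block")
  }
  multicogs_score(scores)
}

#' Compute multiCOGS gene scores with per-category decomposition
#'
#' Runs [score_signal_for_gene()] for every gene against every signal, then
#' combines per-signal scores with [multicogs_score()]; category scores
#' rerun the same machinery with features restricted to one category at a
#' time (so a category score is not bounded by the full score).
#'
#' @param genes Character vector of gene IDs to score.
#' @param signals Signals tibble (`block_id`, `credset_id`, `variant`,
#'   `chrom`, `pos`, `pip`), e.g. from [ingest_credible_sets()] or
#'   [single_causal_signals()], after [exclude_region()].
#' @param promoters,map,consensus,abcc_pairs,coding_snps Passed to
#'   [build_gene_features()].
#' @param ... Thresholds passed to [build_gene_features()].
#' @return Gene-score tibble: `gene_id`, `multicogs`, one column per
#'   category, `n_signals_contributing` (signals with positive score).
#' @export
compute_cogs <- function(genes, signals, promoters, map, consensus = NULL,
                         abcc_pairs = NULL, coding_snps = NULL, ...) {
  sig_split <- split(seq_len(nrow(signals)),
                     paste(signals$block_id, signals$credset_id, sep = "\r"))
  purrr::map_dfr(genes, function(g) {
    feats <- build_gene_features(g, promoters, map, consensus, abcc_pairs,
                                 coding_snps, ...)
    per_signal <- vapply(sig_split, function(ix) {
      score_signal_for_gene(feats, signals[ix, , drop = FALSE])
    }, numeric(1))
    cat_scores <- vapply(COGS_CATEGORIES, function(cat) {
      f <- feats[feats$category == cat, , drop = FALSE]
      multicogs_score(vapply(sig_split, function(ix) {
        score_signal_for_gene(f, signals[ix, , drop = FALSE])
      }, numeric(1)))
    }, numeric(1))
    tibble::tibble(gene_id = g, multicogs = multicogs_score(per_signal),
                   coding = cat_scores[["coding"]],
                   promoter_proximal = cat_scores[["promoter_proximal"]],
                   pchic_pir = cat_scores[["pchic_pir"]],
                   abcc_enhancer = cat_scores[["abcc_enhancer"]],
                   n_signals_contributing = sum(per_signal > 0))
  })
}

#' Per-category multiCOGS decomposition for one gene
#'
#' Reruns the scoring with features restricted to one category at a time,
#' revealing whether a gene is prioritised through coding variants, promoter
#' proximity, PCHi-C PIRs or ABCC enhancers.
#'
#' @inheritParams compute_cogs
#' @param gene_id One gene ID.
#' @return One-row tibble with the four category scores.
#' @export
decompose_by_category <- function(gene_id, signals, promoters, map,
                                  consensus = NULL, abcc_pairs = NULL,
                                  coding_snps = NULL, ...) {
  res <- compute_cogs(gene_id, signals, promoters, map, consensus,
                      abcc_pairs, coding_snps, ...)
  res[, c("gene_id", COGS_CATEGORIES)]
}

#' Rank and flag prioritised genes
#'
#' @param scores Gene-score tibble with `gene_id` and `multicogs`.
#' @param cutoff Prioritisation cutoff (default 0.5).
#' @param strict If `TRUE` (default) a gene is prioritised when
#'   `multicogs > cutoff`; `FALSE` uses `>=`.
#' @return The table ranked by descending score (ties broken by `gene_id`)
#'   with a logical `prioritised` column.
#' @export
prioritise <- function(scores, cutoff = 0.5, strict = TRUE) {
  scores <- dplyr::as_tibble(scores)
  if (nrow(scores) == 0L) {
    return(dplyr::mutate(scores, prioritised = logical(0)))
  }
  scores$prioritised <- if (strict) scores$multicogs > cutoff
                        else scores$multicogs >= cutoff
  dplyr::arrange(scores, dplyr::desc(.data$multicogs), .data$gene_id)
}
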