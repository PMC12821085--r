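# Activity-by-Captured-Contact (ABCC): enhancer-gene scoring on
# CHiCAGO-normalised Promoter Capture Hi-C counts. Contact is imputed as the
# maximum of the observed normalised count and the Brownian background floor
# for baited promoters, or read off the CHiCAGO distance function for
# unbaited/QC-failed promoters; Activity is the geometric mean of ATAC and
# H3K27ac peak read counts; the score is the activity-contact product
# normalised over a 5 Mb window around the TSS.

#' Expected (Brownian-floor) contact for a fragment pair
#'
#' The background contact level from random polymer collision, transported
#' into CHiCAGO-normalised count space:
#' \eqn{N_{exp} = B_{mean} / (s_i \, s_j)} with \eqn{s_i} the bait and
#' \eqn{s_j} the other-end scaling factor.
#'
#' @param params A `chicago_params` object.
#' @param bait_id,oe_id Fragment IDs (vectorised, recycled to common length).
#' @param divide_both If `TRUE` (default) both scaling factors divide
#'   `bmean`; if `FALSE` the alternative reading `(bmean / s_i) * s_j` is
#'   used.
#' @return Numeric vector of expected normalised counts.
#' @export
expected_contact <- function(params, bait_id, oe_id, divide_both = TRUE) {
  si <- params$s_i[as.character(bait_id)]
  sj <- params$s_j[as.character(oe_id)]
  if (any(is.na(si))) stop("missing bait scaling factor s_i for fragment ",
                           paste(bait_id[is.na(si)], collapse = ","))
  if (any(is.na(sj))) stop("missing other-end scaling factor s_j for fragment ",
                           paste(oe_id[is.na(sj)], collapse = ","))
  if (divide_both) unname(params$bmean / (si * sj))
  else unname(params$bmean / si * sj)
}

#' Evaluate the CHiCAGO distance function f(d)
#'
#' Piecewise linear interpolation in log-distance / log-count space over the
#' tabulated knots; beyond the first/last knot the end slope is extrapolated.
#' Zero-count knots are floored at a tiny positive value before taking logs.
#'
#' @param params A `chicago_params` object.
#' @param d Distances in bp (vectorised, must be > 0).
#' @return Expected normalised counts f(d), non-increasing in d.
#' @export
distance_function <- function(params, d) {
  if (any(d <= 0)) stop("distance must be positive")
  kx <- log(params$f_d$distance)
  ky <- log(pmax(params$f_d$count, 1e-300))
  x <- log(d)
  if (length(kx) == 1L) return(rep(exp(ky), length(x)))
  y <- stats::approx(kx, ky, xout = pmin(pmax(x, min(kx)), max(kx)))$y
  lo <- x < min(kx)
  hi <- x > max(kx)
  if (any(lo)) {
    s <- (ky[2] - ky[1]) / (kx[2] - kx[1])
    y[lo] <- ky[1] + s * (x[lo] - kx[1])
  }
  if (any(hi)) {
    n <- length(kx)
    s <- (ky[n] - ky[n - 1]) / (kx[n] - kx[n - 1])
    y[hi] <- ky[n] + s * (x[hi] - kx[n])
  }
  exp(y)
}

#' Impute contact frequency between a promoter and a candidate element
#'
#' For a baited promoter the contact is `max(N_obs, N_exp)` where `N_obs` is
#' the CHiCAGO-normalised observed count for the fragment pair (0 when the
#' pair is absent from the interaction table) and `N_exp` the Brownian floor
#' from [expected_contact()]. For promoters that could not be baited (or
#' failed QC) the contact is read off the distance function `f(d)`; elements
#' whose nearest fragment is the bait itself or an adjacent fragment get the
#' short-range cap `f(median fragment length)` instead, so sub-fragment
#' distances do not dominate.
#'
#' @param promoter One-row tibble as in [read_promoters()] (fields
#'   `fragment_id`, `baited`, `chrom`, `tss`).
#' @param element One-row element tibble (fields `chrom`, `start`, `end`,
#'   `fragment_ids` list-column).
#' @param interactions Interaction tibble at fragment grain (consensus or
#'   fragment resolution) with `bait_id`, `oe_first`, `n_obs`.
#' @param params A `chicago_params` object.
#' @param map The `fragment_map` (supplies the median fragment length).
#' @param divide_both Passed to [expected_contact()].
#' @return Imputed normalised contact (scalar). Element-level contact over a
#'   multi-fragment element is the maximum per-fragment imputed contact.
#' @export
impute_contact <- function(promoter, element, interactions, params, map,
                           divide_both = TRUE) {
  if (promoter$chrom != element$chrom) {
    stop("trans promoter-element pair: contact imputation is cis-only")
  }
  frags <- element$fragment_ids[[1]]
  if (length(frags) == 0L) stop("element overlaps no fragment")
  if (isTRUE(promoter$baited)) {
    obs <- interactions[interactions$bait_id == promoter$fragment_id &
                          interactions$oe_first %in% frags, , drop = FALSE]
    n_obs <- vapply(frags, function(f) {
      v <- obs$n_obs[obs$oe_first == f]
      if (length(v) == 0L) 0 else max(v)
    }, numeric(1))
    n_exp <- expected_contact(params, promoter$fragment_id, frags, divide_both)
    max(pmax(n_obs, n_exp))
  } else {
    med <- median_fragment_length(map)
    near <- min(abs(frags - promoter$fragment_id)) <= 1L
    if (near) {
      distance_function(params, med)
    } else {
      row <- match(promoter$fragment_id, map$fragment_id)
      bait_mid <- (map$start[row] + map$end[row]) / 2
      d <- abs((element$start + element$end) / 2 - bait_mid)
      distance_function(params, max(d, 1))
    }
  }
}

#' Element activity from chromatin accessibility and H3K27ac
#'
#' Geometric mean of the two assay read counts with an optional pseudocount:
#' `sqrt((atac + pc) * (k27 + pc)) - pc`, clipped at 0. With the default
#' pseudocount of 0 a zero in either assay zeroes the element.
#'
#' @param atac_count,h3k27ac_count Non-negative read counts (vectorised).
#' @param pseudocount Pseudocount added to both assays before the geometric
#'   mean and subtracted after (default 0).
#' @return Activity values, >= 0.
#' @export
element_activity <- function(atac_count, h3k27ac_count, pseudocount = 0) {
  if (any(atac_count < 0) || any(h3k27ac_count < 0)) stop("negative read count")
  pmax(sqrt((atac_count + pseudocount) * (h3k27ac_count + pseudocount)) - pseudocount, 0)
}

#' Build the candidate element universe from peak tracks
#'
#' Candidate elements are the union of ATAC and H3K27ac peaks, with
#' overlapping peaks merged; each element carries the summed read count of the
#' overlapping peaks per assay and the geometric-mean activity.
#'
#' @param atac,h3k27ac Peak tibbles from [read_peaks()].
#' @param map The `fragment_map`.
#' @param pseudocount Passed to [element_activity()].
#' @return Tibble `element_id`, `chrom`, `start`, `end`, `atac`, `h3k27ac`,
#'   `activity`, and list-column `fragment_ids`.
#' @export
candidate_elements <- function(atac, h3k27ac, map, pseudocount = 0) {
  peaks <- dplyr::bind_rows(atac, h3k27ac)
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(element_id = integer(), chrom = character(),
                          start = double(), end = double(), atac = double(),
                          h3k27ac = double(), activity = double(),
                          fragment_ids = list()))
  }
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
  # merge overlapping peaks into elements per chromosome
  grp <- integer(nrow(peaks))
  g <- 0L
  cur_end <- -Inf; cur_chrom <- ""
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != cur_chrom || peaks$start[i] >= cur_end) {
      g <- g + 1L
      cur_chrom <- peaks$chrom[i]; cur_end <- peaks$end[i]
    } else {
      cur_end <- max(cur_end, peaks$end[i])
    }
    grp[i] <- g
  }
  els <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(peaks, .grp = grp), .data$.grp),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    atac = sum(.data$read_count[.data$assay == "ATAC"]),
    h3k27ac = sum(.data$read_count[.data$assay == "H3K27ac"]),
    .groups = "drop"
  )
  els$element_id <- seq_len(nrow(els))
  els$activity <- element_activity(els$atac, els$h3k27ac, pseudocount)
  els <- assign_to_fragments(els, map)
  els[, c("element_id", "chrom", "start", "end", "atac", "h3k27ac",
          "activity", "fragment_ids")]
}

#' ABCC scores for all gene-element pairs
#'
#' For each gene, the numerator of a candidate element is
#' \eqn{A_E \times C_{E,G}} (activity times imputed contact) and the ABC
#' score is the numerator divided by the sum of numerators over all elements
#' within the window around the gene's TSS. Elements overlapping the gene's
#' own baited promoter fragment are excluded from its candidate list.
#'
#' @param elements Element tibble from [candidate_elements()].
#' @param promoters Promoter tibble from [read_promoters()]. One anchor
#'   promoter per gene is used: the first baited promoter in input order, or
#'   the first promoter when none is baited (distance-function imputation).
#' @param interactions Fragment-grain interaction tibble.
#' @param params A `chicago_params` object.
#' @param map The `fragment_map`.
#' @param window_bp Window width around the TSS; an element belongs to a
#'   gene's window when its midpoint is within `window_bp/2` of the TSS
#'   (default 5 Mb total).
#' @param pseudocount,divide_both Passed through.
#' @return Tibble of gene-element pairs: `gene_id`, `element_id`, `chrom`,
#'   `start`, `end`, `activity`, `contact`, `numerator`, `abc_score`,
#'   `zero_denominator` flag. Scores for a gene sum to 1 whenever any
#'   numerator is positive.
#' @export
abc_scores <- function(elements, promoters, interactions, params, map,
                       window_bp = 5e6, pseudocount = 0, divide_both = TRUE) {
  anchors <- dplyr::slice(
    dplyr::group_by(promoters, .data$gene_id),
    if (any(.data$baited)) which(.data$baited)[1] else 1L
  ) |> dplyr::ungroup()
  res <- purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
    pr <- anchors[i, ]
    el <- elements[elements$chrom == pr$chrom, , drop = FALSE]
    if (nrow(el) == 0L) return(NULL)
    mid <- (el$start + el$end) / 2
    el <- el[abs(mid - pr$tss) <= window_bp / 2, , drop = FALSE]
    if (nrow(el) == 0L) return(NULL)
    # exclude elements touching the gene's own baited promoter fragment
    if (isTRUE(pr$baited)) {
      own <- vapply(el$fragment_ids, function(f) pr$fragment_id %in% f, logical(1))
      el <- el[!own, , drop = FALSE]
    }
    if (nrow(el) == 0L) return(NULL)
    contact <- vapply(seq_len(nrow(el)), function(j) {
      impute_contact(pr, el[j, ], interactions, params, map, divide_both)
    }, numeric(1))
    numerator <- el$activity * contact
    denom <- sum(numerator)
    tibble::tibble(
      gene_id = pr$gene_id, element_id = el$element_id, chrom = el$chrom,
      start = el$start, end = el$end, activity = el$activity,
      contact = contact, numerator = numerator,
      abc_score = if (denom > 0) numerator / denom else rep(0, nrow(el)),
      zero_denominator = denom <= 0
    )
  })
  if (is.null(res)) res <- tibble::tibble()
  res
}

#' Select the ABCC score cutoff against gene expression
#'
#' For each cutoff on the grid, the per-gene statistic is the sum of
#' numerators of elements with `abc_score >= cutoff`; the selected cutoff
#' maximises the Pearson correlation of this statistic with gene expression
#' (ties broken toward the smallest cutoff). The deployed default cutoff
#' downstream is 0.023.
#'
#' @param pairs Pair tibble from [abc_scores()].
#' @param expression Tibble `gene_id`, `expression`; at least 20 genes must
#'   have both scores and expression.
#' @param grid Numeric vector of candidate cutoffs.
#' @return An object of class `abcc_cutoff`: a list with `cutoff`, the
#'   correlation `curve` tibble (`cutoff`, `correlation`, `n_genes`), and
#'   `n_genes`. Has [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @export
select_cutoff <- function(pairs, expression, grid = seq(0, 0.1, by = 0.002)) {
  genes <- intersect(unique(pairs$gene_id), expression$gene_id)
  if (length(genes) < 20L) stop("need >= 20 genes with expression for cutoff selection")
  expr <- expression$expression[match(genes, expression$gene_id)]
  if (stats::sd(expr) == 0) stop("expression vector is constant; correlation undefined")
  gi <- match(pairs$gene_id, genes)
  keep <- !is.na(gi)
  gi <- gi[keep]; num <- pairs$numerator[keep]; sc <- pairs$abc_score[keep]
  curve <- purrr::map_dfr(sort(grid), function(ct) {
    sel <- sc >= ct
    stat <- numeric(length(genes))
    agg <- tapply(num[sel], gi[sel], sum)
    stat[as.integer(names(agg))] <- agg
    r <- if (stats::sd(stat) == 0) NA_real_ else stats::cor(stat, expr)
    tibble::tibble(cutoff = ct, correlation = r, n_genes = length(genes))
  })
  ok <- which(!is.na(curve$correlation))
  if (length(ok) == 0L) stop("correlation undefined at every grid cutoff")
  best <- ok[which.max(curve$correlation[ok])] # which.max returns first max: smallest cutoff
  structure(list(cutoff = curve$cutoff[best], curve = curve,
                 n_genes = length(genes)),
            class = "abcc_cutoff")
}

#' @export
print.abcc_cutoff <- function(x, ...) {
  cat(sprintf("ABCC cutoff selection over %d genes\n", x$n_genes))
  cat(sprintf("  selected cutoff: %g (Pearson r = %.4f)\n", x$cutoff,
              x$curve$correlation[match(x$cutoff, x$curve$cutoff)]))
  invisible(x)
}

#' Call enhancer-gene pairs at a score cutoff
#'
#' @param pairs Pair tibble from [abc_scores()].
#' @param cutoff ABCC score cutoff; the deployed default is 0.023.
#' @return Pairs with `abc_score >= cutoff`, sorted by gene then score
#'   descending.
#' @export
call_enhancer_pairs <- function(pairs, cutoff = 0.023) {
  dplyr::arrange(pairs[pairs$abc_score >= cutoff & pairs$numerator > 0, , drop = FALSE],
                 .data$gene_id, dplyr::desc(.data$abc_score))
}

#' Precision and recall of predicted pairs against a labelled truth set
#'
#' @param predicted Tibble with `gene_id`, `element_id` of called pairs.
#' @param truth Tibble with `gene_id`, `element_id`, `label` in
#'   `{"positive","negative"}` defining the labelled universe.
#' @return One-row tibble `precision`, `recall`, `n_predicted`,
#'   `n_positive`. Precision is `NA` when nothing in the labelled universe
#'   was predicted.
#' @export
evaluate_pairs <- function(predicted, truth) {
  if (nrow(truth) == 0L) stop("empty truth set")
  stopifnot(all(truth$label %in% c("positive", "negative")))
  key <- function(d) paste(d$gene_id, d$element_id, sep = "\r")
  pred <- key(predicted) ; tk <- key(truth)
  in_universe <- pred[pred %in% tk]
  pos <- tk[truth$label == "positive"]
  tp <- sum(in_universe %in% pos)
  tibble::tibble(
    precision = if (length(in_universe) == 0L) NA_real_ else tp / length(in_universe),
    recall = if (length(pos) == 0L) NA_real_ else tp / length(pos),
    n_predicted = length(in_universe), n_positive = length(pos)
  )
}
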