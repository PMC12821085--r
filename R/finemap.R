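# Per-block fine-mapped signal preparation: block partition of summary
# statistics, conditional-Gaussian z-score imputation, triage of blocks by
# association strength, single-causal-variant posteriors (Wakefield
# approximate Bayes factors), and ingestion of externally computed
# multivariate credible sets (SuSiE-style PIP tables).

#' Partition GWAS summary statistics into LD blocks
#'
#' @param stats Tibble with at least `variant`, `chrom`, `pos` (1-based).
#' @param blocks Tibble `block_id`, `chrom`, `start`, `end`
#'   (0-based half-open, non-overlapping).
#' @return The input rows with a `block_id` column, restricted to variants
#'   falling inside a block; the number of dropped (outside-all-blocks)
#'   variants is attached as attribute `n_dropped` and messaged.
#' @export
partition_into_blocks <- function(stats, blocks) {
  blocks <- dplyr::arrange(dplyr::as_tibble(blocks), .data$chrom, .data$start)
  ovl <- blocks$chrom[-1] == blocks$chrom[-nrow(blocks)] &
    blocks$start[-1] < blocks$end[-nrow(blocks)]
  if (nrow(blocks) > 1L && any(ovl)) stop("overlapping LD blocks")
  bid <- rep(NA_character_, nrow(stats))
  for (ch in unique(blocks$chrom)) {
    bsel <- blocks$chrom == ch
    vsel <- which(stats$chrom == ch)
    if (length(vsel) == 0L) next
    p0 <- stats$pos[vsel] - 1 # 0-based
    j <- findInterval(p0, blocks$start[bsel])
    ok <- j >= 1L & p0 < blocks$end[bsel][pmax(j, 1L)]
    bid[vsel[ok]] <- as.character(blocks$block_id[bsel][j[ok]])
  }
  n_dropped <- sum(is.na(bid))
  if (n_dropped > 0L) {
    message(sprintf("%d variant(s) outside all LD blocks dropped", n_dropped))
  }
  out <- dplyr::mutate(dplyr::as_tibble(stats), block_id = bid)
  out <- out[!is.na(out$block_id), , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Impute missing z-scores within an LD block
#'
#' Conditional-mean Gaussian imputation from the block LD matrix:
#' \eqn{\hat z_m = R_{mo} (R_{oo} + \lambda I)^{-1} z_o}, with a per-variant
#' imputation-quality score \eqn{r^2 = \mathrm{diag}(R_{mo}(R_{oo}+\lambda
#' I)^{-1} R_{om})}. Observed variants keep their input z unchanged.
#'
#' @param R Correlation matrix between the block's variants (unit diagonal).
#' @param z_obs Numeric vector of observed z-scores.
#' @param observed_idx Integer indices (into `R`'s rows) of the observed
#'   variants, in the order of `z_obs`.
#' @param lambda Ridge regularisation added to the observed-observed LD
#'   submatrix (default 0.1).
#' @return Tibble with one row per variant in the block: `index`, `z`,
#'   `observed`, `r2` (1 for observed variants).
#' @export
impute_z <- function(R, z_obs, observed_idx, lambda = 0.1) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R),
            length(z_obs) == length(observed_idx),
            length(observed_idx) >= 1L)
  n <- nrow(R)
  miss <- setdiff(seq_len(n), observed_idx)
  z <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  z[observed_idx] <- z_obs
  r2[observed_idx] <- 1
  if (length(miss) > 0L) {
    Roo <- R[observed_idx, observed_idx, drop = FALSE] +
      diag(lambda, length(observed_idx))
    Rmo <- R[miss, observed_idx, drop = FALSE]
    W <- tryCatch(solve(Roo, t(Rmo)),
                  error = function(e) stop(
                    "singular regularised LD matrix; use lambda > 0 ",
                    "(duplicate variants at lambda = 0)", call. = FALSE))
    z[miss] <- as.numeric(Rmo %*% solve(Roo, z_obs))
    r2[miss] <- rowSums(Rmo * t(W))
  }
  tibble::tibble(index = seq_len(n), z = z,
                 observed = seq_len(n) %in% observed_idx, r2 = r2)
}

#' Route blocks to multivariate fine-mapping or the single-causal fallback
#'
#' Blocks with appreciable association signal (minimum p below the threshold)
#' are routed to multivariate fine-mapping ingestion; the rest take the
#' single-causal-variant fallback. For imputed variants p is the plain
#' two-sided normal tail of z.
#'
#' @param stats Tibble with `block_id` and either `p` or `z` (p recomputed
#'   from z where missing).
#' @param p_threshold Routing threshold on the block-minimum p (default 1e-6).
#' @return Tibble `block_id`, `min_p`, `route` in
#'   `{"fine_map","fallback"}`; blocks with no variants route to fallback
#'   with `min_p = NA`.
#' @export
triage_blocks <- function(stats, p_threshold = 1e-6) {
  p <- if ("p" %in% names(stats) && !all(is.na(stats$p))) {
    ifelse(is.na(stats$p), 2 * stats::pnorm(-abs(stats$z)), stats$p)
  } else {
    2 * stats::pnorm(-abs(stats$z))
  }
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(dplyr::as_tibble(stats), .p = p), .data$block_id),
    min_p = if (dplyr::n() == 0L) NA_real_ else min(.data$.p, na.rm = TRUE),
    .groups = "drop"
  ) |>
    dplyr::mutate(route = ifelse(!is.na(.data$min_p) & .data$min_p < p_threshold,
                                 "fine_map", "fallback"))
}

#' Single-causal-variant posteriors by Wakefield approximate Bayes factors
#'
#' Under a single causal variant per block, the approximate Bayes factor for
#' each variant is \eqn{ABF = \sqrt{V/(V+W)}\,\exp(z^2 W / (2(V+W)))} with
#' \eqn{V = se^2} and prior effect variance \eqn{W}; posterior probabilities
#' of association are the ABFs normalised to sum to 1 over the block
#' (computed on the log scale for stability).
#'
#' @param z Signed z-scores (finite).
#' @param se Standard errors (positive; recycled).
#' @param W Prior variance of the effect size (default 0.04, i.e. prior sd
#'   0.2 on the log-odds scale).
#' @return Tibble `index`, `log_abf`, `ppa`; `ppa` sums to 1.
#' @export
single_causal_ppa <- function(z, se = 1, W = 0.04) {
  stopifnot(all(is.finite(z)))
  se <- rep_len(se, length(z))
  V <- se^2
  if (all(V == 0)) stop("all-zero variance")
  log_abf <- 0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))
  m <- max(log_abf)
  ppa <- exp(log_abf - m) / sum(exp(log_abf - m))
  tibble::tibble(index = seq_along(z), log_abf = log_abf, ppa = ppa)
}

#' Turn single-causal posteriors into a per-block signal table
#'
#' @param stats Block-partitioned summary statistics with `block_id`,
#'   `variant`, `chrom`, `pos`, `z` and `se` (or a `se` default of 1).
#' @param W Prior effect variance for [single_causal_ppa()].
#' @return A signals tibble (`block_id`, `credset_id`, `variant`, `chrom`,
#'   `pos`, `pip`) with one credible set (`"single"`) per block and
#'   per-block pips summing to 1.
#' @export
single_causal_signals <- function(stats, W = 0.04) {
  se <- if ("se" %in% names(stats)) stats$se else rep(1, nrow(stats))
  purrr::map_dfr(split(seq_len(nrow(stats)), stats$block_id), function(ix) {
    pp <- single_causal_ppa(stats$z[ix], se[ix], W = W)
    tibble::tibble(block_id = stats$block_id[ix], credset_id = "single",
                   variant = stats$variant[ix], chrom = stats$chrom[ix],
                   pos = stats$pos[ix], pip = pp$ppa)
  })
}

#' Read externally computed credible sets (PIP table)
#'
#' One signal is one (LD block, credible set) pair with per-variant posterior
#' inclusion probabilities, e.g. a SuSiE export. PIPs are authoritative:
#' variants absent from the summary statistics are retained.
#'
#' @param path TSV with columns `block_id`, `credset_id`, `variant`,
#'   `chrom`, `pos`, `pip`.
#' @return Validated signals tibble; per-signal pip sums may not exceed
#'   1 + 1e-6.
#' @export
ingest_credible_sets <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("block_id", "credset_id", "variant", "chrom", "pos", "pip")
                %in% names(x)))
  validate_signals(dplyr::as_tibble(x))
}

validate_signals <- function(x) {
  if (any(x$pip < 0 | x$pip > 1)) stop("pip outside [0, 1]")
  dup <- duplicated(x[, c("block_id", "credset_id", "variant")])
  if (any(dup)) stop("duplicate (signal, variant) record")
  sums <- dplyr::summarise(dplyr::group_by(x, .data$block_id, .data$credset_id),
                           s = sum(.data$pip), .groups = "drop")
  if (any(sums$s > 1 + 1e-6)) stop("per-signal pip mass exceeds 1")
  x
}

#' Write a signals table
#' @param signals Signals tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  readr::write_tsv(signals, path)
  invisible(path)
}
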