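# Coordinate backbone: restriction-fragment maps, interaction tables and the
# readers/writers for every tabular format the toolkit touches.
#
# Conventions: fragment maps, peaks and all BED-derived intervals are 0-based
# half-open; variant positions in GWAS tables are 1-based (summary-statistic
# convention). A 1-based position p falls in half-open [start, end) iff
# start < p <= end.

#' Construct a fragment map from an interval table
#'
#' A fragment map is the ordered set of restriction fragments (e.g. DpnII
#' fragments) tiling each chromosome. It is the coordinate backbone for all
#' fragment-grain features: baits, promoter-proximal windows,
#' promoter-interacting regions (PIRs) and candidate enhancers.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). Rows may be unsorted; they are sorted into genome
#'   order and assigned integer `fragment_id`s starting at 0.
#' @return A tibble of class `fragment_map` with columns `chrom`, `start`,
#'   `end`, `fragment_id`, carrying the realised median fragment length as
#'   attribute `median_length`.
#' @details Fragments must tile each chromosome contiguously: any gap or
#'   overlap between consecutive fragments is a format error naming the
#'   offending pair. Chromosome order follows first appearance in the sorted
#'   input.
#' @export
fragment_map <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x <- dplyr::as_tibble(x)[, c("chrom", "start", "end")]
  if (nrow(x) == 0L) stop("fragment map is empty")
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(x$chrom == "" | is.na(x$chrom))) {
    stop("fragment map has missing coordinates or empty chromosome names")
  }
  if (any(x$start < 0) || any(x$end <= x$start)) {
    stop("fragment intervals must satisfy 0 <= start < end")
  }
  x$chrom <- as.character(x$chrom)
  x <- dplyr::arrange(x, match(.data$chrom, unique(.data$chrom)), .data$start)
  bad <- which(x$chrom[-1] == x$chrom[-nrow(x)] &
                 x$start[-1] != x$end[-nrow(x)])
  if (length(bad) > 0L) {
    i <- bad[1]
    stop(sprintf(
      "fragments %s:%d-%d and %s:%d-%d are not contiguous (gap or overlap)",
      x$chrom[i], x$start[i], x$end[i], x$chrom[i + 1], x$start[i + 1], x$end[i + 1]
    ))
  }
  x$fragment_id <- seq_len(nrow(x)) - 1L
  attr(x, "median_length") <- stats::median(x$end - x$start)
  class(x) <- c("fragment_map", class(x))
  x
}

#' Median fragment length of a fragment map
#' @param map A `fragment_map`.
#' @return Median fragment length in bp.
#' @export
median_fragment_length <- function(map) {
  attr(map, "median_length") %||% stats::median(map$end - map$start)
}

#' Read a restriction-fragment map from BED
#'
#' @param path Path to a 3+ column BED file (no header), sorted or sortable.
#' @return A [fragment_map()].
#' @export
read_fragment_map <- function(path) {
  x <- read_bed(path, n_cols = 3L)
  names(x)[1:3] <- c("chrom", "start", "end")
  fragment_map(x)
}

#' Write a fragment map to BED
#' @param map A `fragment_map`.
#' @param path Output path; columns chrom, start, end, fragment_id, tab-separated.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(map, path) {
  readr::write_tsv(map[, c("chrom", "start", "end", "fragment_id")], path,
                   col_names = FALSE)
  invisible(path)
}

# minimal BED reader: tab-separated, no header, comment lines start with '#'
read_bed <- function(path, n_cols = 3L) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", rep(NA, 20))[seq_len(n_cols)],
                         fill = TRUE)
  if (ncol(x) < n_cols) stop(sprintf("BED file %s has fewer than %d columns", path, n_cols))
  dplyr::as_tibble(x)
}

chrom_bounds <- function(map) {
  dplyr::summarise(dplyr::group_by(dplyr::as_tibble(map), .data$chrom),
                   chrom_start = min(.data$start), chrom_end = max(.data$end),
                   .groups = "drop")
}

fragment_midpoints <- function(map) (map$start + map$end) / 2

#' Map intervals onto the fragments they overlap
#'
#' An interval maps to every fragment it overlaps by at least 1 bp
#' (half-open arithmetic).
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param map A `fragment_map`.
#' @return The input tibble with a list-column `fragment_ids` of integer
#'   vectors (empty when the interval falls outside the fragment span of a
#'   known chromosome).
#' @export
assign_to_fragments <- function(intervals, map) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- dplyr::as_tibble(intervals)
  if (nrow(intervals) > 0L && any(intervals$end <= intervals$start)) {
    stop("empty or inverted interval (end <= start)")
  }
  unknown <- setdiff(unique(intervals$chrom), unique(map$chrom))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  by_chrom <- split(seq_len(nrow(map)), map$chrom)
  intervals$fragment_ids <- purrr::pmap(
    list(intervals$chrom, intervals$start, intervals$end),
    function(ch, s, e) {
      idx <- by_chrom[[ch]]
      # overlap by >= 1bp: fragment start < e AND fragment end > s
      hit <- idx[map$start[idx] < e & map$end[idx] > s]
      as.integer(map$fragment_id[hit])
    }
  )
  intervals
}

# fragment containing a 1-based position; NA_integer_ when outside the map
fragment_at_position <- function(map, chrom, pos1) {
  stopifnot(length(chrom) == length(pos1))
  out <- rep(NA_integer_, length(pos1))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    idx <- which(map$chrom == ch)
    if (length(idx) == 0L) next
    p0 <- pos1[sel] - 1 # 0-based
    j <- findInterval(p0, map$start[idx])
    ok <- j >= 1L & p0 < map$end[idx][pmax(j, 1L)]
    res <- rep(NA_integer_, sum(sel))
    res[ok] <- map$fragment_id[idx][j[ok]]
    out[sel] <- res
  }
  out
}

#' Read a CHiCAGO-style interaction table
#'
#' The dialect mirrors a CHiCAGO export at either single-fragment or binned
#' resolution: tab-separated with header columns `baitID`, `otherEndID`
#' (fragment resolution) or `oeFirstID`/`oeLastID` (a run of fragments forming
#' a bin), `N` (CHiCAGO-normalised count), `N.reads` (raw reads) and `score`.
#' An optional `resolution` column overrides the width-based inference.
#'
#' @param path Path to the TSV.
#' @param map The shared `fragment_map`; used to resolve fragment coordinates,
#'   midpoint distances and trans status.
#' @param resolution Optional `"fragment"` or `"bin5kb"` tag applied to all
#'   rows; by default inferred per row from the other-end width.
#' @return An interaction tibble with columns `bait_id`, `oe_first`, `oe_last`,
#'   `n_obs`, `raw_reads`, `score`, `distance` (bp between bait and other-end
#'   midpoints; `NA` for trans), `trans`, `resolution`. Trans-chromosomal rows
#'   are retained and flagged; any removal happens downstream.
#' @export
read_interactions <- function(path, map, resolution = NULL) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0L) {
    return(tibble::tibble(bait_id = integer(), oe_first = integer(),
                          oe_last = integer(), n_obs = double(),
                          raw_reads = double(), score = double(),
                          distance = double(), trans = logical(),
                          resolution = character()))
  }
  nm <- names(x)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (length(hit) == 0L) stop(sprintf("no column among {%s} in %s",
                                        paste(cands, collapse = ", "), path))
    x[[hit[1]]]
  }
  bait_id <- as.integer(pick(c("baitID", "bait_id")))
  if ("otherEndID" %in% nm) {
    oe_first <- as.integer(x$otherEndID); oe_last <- oe_first
  } else {
    oe_first <- as.integer(pick(c("oeFirstID", "oe_first")))
    oe_last <- as.integer(pick(c("oeLastID", "oe_last")))
  }
  n_obs <- as.numeric(pick(c("N", "n_obs")))
  raw_reads <- as.numeric(pick(c("N.reads", "raw_reads")))
  score <- as.numeric(pick(c("score")))
  if (any(n_obs < 0, na.rm = TRUE) || any(raw_reads < 0, na.rm = TRUE)) {
    stop("negative counts in interaction table")
  }
  known <- c(bait_id, oe_first, oe_last) %in% map$fragment_id
  if (!all(known)) stop("interaction table references fragment IDs absent from the map")
  res <- if ("resolution" %in% nm) as.character(x$resolution)
         else if (!is.null(resolution)) rep(resolution, nrow(x))
         else ifelse(oe_last > oe_first, "bin5kb", "fragment")
  build_interactions(bait_id, oe_first, oe_last, n_obs, raw_reads, score, res, map)
}

build_interactions <- function(bait_id, oe_first, oe_last, n_obs, raw_reads,
                               score, resolution, map) {
  row_of <- match(bait_id, map$fragment_id)
  rf <- match(oe_first, map$fragment_id)
  rl <- match(oe_last, map$fragment_id)
  bait_mid <- (map$start[row_of] + map$end[row_of]) / 2
  oe_mid <- (map$start[rf] + map$end[rl]) / 2
  trans <- map$chrom[row_of] != map$chrom[rf]
  if (any(map$chrom[rf] != map$chrom[rl])) stop("other-end bin spans chromosomes")
  tibble::tibble(
    bait_id = bait_id, oe_first = oe_first, oe_last = oe_last,
    n_obs = n_obs, raw_reads = raw_reads, score = score,
    distance = ifelse(trans, NA_real_, abs(bait_mid - oe_mid)),
    trans = trans, resolution = resolution
  )
}

#' Write an interaction table in the CHiCAGO-style dialect
#' @param ints Interaction tibble as returned by [read_interactions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(ints, path) {
  out <- tibble::tibble(baitID = ints$bait_id, oeFirstID = ints$oe_first,
                        oeLastID = ints$oe_last, N = ints$n_obs,
                        N.reads = ints$raw_reads, score = ints$score,
                        resolution = ints$resolution)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Merge fragment-resolution and binned interactions into a consensus set
#'
#' Builds the non-redundant union of (bait, other-end fragment) pairs across a
#' single-fragment run and a binned run in which other ends are runs of
#' fragments (baited fragments left unbinned). Bins are expanded to their
#' constituent fragments so downstream feature assembly is uniform at fragment
#' grain; a fragment supported at both resolutions counts once.
#'
#' @param frag_res Interaction tibble at fragment resolution.
#' @param binned Interaction tibble at binned resolution.
#' @param map The shared `fragment_map`; both tables must reference only its
#'   fragment IDs.
#' @return Tibble with one row per consensus (bait, fragment) pair: `bait_id`,
#'   `oe_frag`, `n_obs`, `raw_reads`, `score` (per-pair maxima across
#'   supporting records), `distance`, `trans`, and `provenance` in
#'   `{"fragment", "bin", "both"}`.
#' @export
merge_consensus <- function(frag_res, binned, map) {
  expand <- function(ints, tag) {
    if (nrow(ints) == 0L) {
      return(tibble::tibble(bait_id = integer(), oe_frag = integer(),
                            n_obs = double(), raw_reads = double(),
                            score = double(), provenance = character()))
    }
    ids <- c(ints$bait_id, ints$oe_first, ints$oe_last)
    if (!all(ids %in% map$fragment_id)) {
      stop("interaction table does not match the supplied fragment map")
    }
    tidyr::unnest(
      dplyr::mutate(ints,
                    oe_frag = purrr::map2(.data$oe_first, .data$oe_last, seq)),
      "oe_frag"
    ) |>
      dplyr::transmute(bait_id = .data$bait_id,
                       oe_frag = as.integer(.data$oe_frag),
                       n_obs = .data$n_obs, raw_reads = .data$raw_reads,
                       score = .data$score, provenance = tag)
  }
  all <- dplyr::bind_rows(expand(frag_res, "fragment"), expand(binned, "bin"))
  cons <- dplyr::summarise(
    dplyr::group_by(all, .data$bait_id, .data$oe_frag),
    n_obs = max(.data$n_obs), raw_reads = max(.data$raw_reads),
    score = max(.data$score),
    provenance = if (dplyr::n_distinct(.data$provenance) > 1L) "both"
                 else .data$provenance[1],
    .groups = "drop"
  )
  geo <- build_interactions(cons$bait_id, cons$oe_frag, cons$oe_frag,
                            cons$n_obs, cons$raw_reads, cons$score,
                            "consensus", map)
  dplyr::arrange(
    dplyr::mutate(geo, oe_frag = .data$oe_first, provenance = cons$provenance),
    .data$bait_id, .data$oe_frag
  )
}

#' Read promoter annotations
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `tss` (1-based
#'   position) and `baited` (logical or 0/1). A gene may own several promoters
#'   (alternative TSSs).
#' @param map The `fragment_map`; the containing fragment of each TSS is
#'   resolved against it.
#' @return Tibble `gene_id`, `chrom`, `tss`, `baited`, `fragment_id`.
#' @export
read_promoters <- function(path, map) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene_id", "chrom", "tss", "baited") %in% names(x)))
  x$baited <- as.logical(x$baited)
  x$fragment_id <- fragment_at_position(map, as.character(x$chrom), x$tss)
  if (any(is.na(x$fragment_id))) stop("promoter TSS outside the fragment map")
  dplyr::as_tibble(x[, c("gene_id", "chrom", "tss", "baited", "fragment_id")])
}

#' Read a peak track with read counts
#'
#' @param path BED file: chrom, start, end, read_count (4th column), no header.
#' @param assay Assay label, `"ATAC"` or `"H3K27ac"`.
#' @return Tibble `chrom`, `start`, `end`, `read_count`, `assay`.
#' @export
read_peaks <- function(path, assay = c("ATAC", "H3K27ac")) {
  assay <- match.arg(assay)
  x <- read_bed(path, n_cols = 4L)
  names(x)[1:4] <- c("chrom", "start", "end", "read_count")
  x$read_count <- as.numeric(x$read_count)
  if (any(x$read_count < 0)) stop("negative peak read count")
  dplyr::mutate(x[, 1:4], assay = assay)
}

#' Read CHiCAGO model parameters
#'
#' Expects a YAML file with scalar `bmean` (the Brownian noise level in
#' normalised-count units), maps `s_i` (bait scaling factors) and `s_j`
#' (other-end scaling factors) keyed by fragment ID, and `f_d`, the tabulated
#' distance function as parallel lists `distance` / `count` (knots, bp vs
#' expected normalised count, non-increasing in distance).
#'
#' @param path YAML path.
#' @return A `chicago_params` list: `bmean`, named numeric `s_i`, `s_j`, and
#'   tibble `f_d`.
#' @export
read_chicago_params <- function(path) {
  y <- yaml::read_yaml(path)
  chicago_params(bmean = y$bmean,
                 s_i = unlist(y$s_i), s_j = unlist(y$s_j),
                 f_d = tibble::tibble(distance = as.numeric(y$f_d$distance),
                                      count = as.numeric(y$f_d$count)))
}

#' Construct CHiCAGO model parameters
#' @param bmean Brownian noise level (normalised-count units), > 0.
#' @param s_i,s_j Named numeric vectors of positive scaling factors keyed by
#'   fragment ID (bait-side and other-end-side).
#' @param f_d Tibble of distance-function knots, columns `distance` (bp,
#'   increasing) and `count` (non-increasing).
#' @return A `chicago_params` object.
#' @export
chicago_params <- function(bmean, s_i, s_j, f_d) {
  stopifnot(is.numeric(bmean), bmean > 0,
            all(s_i > 0), all(s_j > 0),
            all(c("distance", "count") %in% names(f_d)))
  f_d <- dplyr::arrange(dplyr::as_tibble(f_d), .data$distance)
  if (any(diff(f_d$count) > 1e-12)) {
    stop("distance function f(d) must be non-increasing over its knots")
  }
  structure(list(bmean = bmean, s_i = s_i, s_j = s_j, f_d = f_d),
            class = "chicago_params")
}

#' Write CHiCAGO model parameters to YAML
#' @param params A `chicago_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chicago_params <- function(params, path) {
  yaml::write_yaml(list(
    bmean = params$bmean,
    s_i = as.list(params$s_i), s_j = as.list(params$s_j),
    f_d = list(distance = params$f_d$distance, count = params$f_d$count)
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
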