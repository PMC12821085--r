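# Seeded generators for every input the toolkit consumes, with planted
# ground truth for parameter-recovery tests: a fragment-tiled genome with
# genes and (mostly baited) promoters, CHiCAGO-style interaction tables with
# Brownian distance decay and planted true contacts, peak tracks whose
# activity is coupled to the planted elements, AR(1)-LD GWAS blocks with
# planted causal variants and SuSiE-like credible sets, and expression
# coupled to planted enhancer activity.
#
# All randomness flows from one integer seed. Defaults are sized so the
# full pipeline (genome -> contacts -> GWAS -> ABCC -> multiCOGS) runs in
# well under a minute: 3 chromosomes x 2,000 fragments (~3 Mb each at a
# 1.5 kb median fragment), 200 genes, 20 LD blocks x 100 variants.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fragment-tiled genome with genes and promoters
#'
#' Fragment lengths are log-normal around the requested median (so the
#' realised median fragment length tracks `median_len`); genes get 1-3
#' alternative TSSs in nearby fragments and ~90% of promoters are flagged
#' baited, mirroring a promoter-capture design with some QC dropout.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (default 3).
#' @param n_frag Fragments per chromosome (default 2000, >= 20).
#' @param median_len Target median fragment length in bp (default 1500).
#' @param n_genes Number of genes (default 200).
#' @return List with `map` (a [fragment_map()]) and `promoters`
#'   (`gene_id`, `chrom`, `tss`, `baited`, `fragment_id`).
#' @export
make_genome <- function(seed, n_chrom = 3, n_frag = 2000, median_len = 1500,
                        n_genes = 200) {
  if (n_frag < 20) stop("need >= 20 fragments per chromosome")
  with_seed(seed, {
    frags <- purrr::map_dfr(seq_len(n_chrom), function(c) {
      len <- pmax(round(exp(stats::rnorm(n_frag, log(median_len), 0.45))), 100)
      tibble::tibble(chrom = sprintf("chr%d", c),
                     start = cumsum(c(0, len[-n_frag])),
                     end = cumsum(len))
    })
    map <- fragment_map(frags)
    # one primary TSS fragment per gene, spread across the genome and kept
    # >= 15 fragments apart so promoter-proximal windows of neighbouring
    # genes do not collide
    per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    prom <- purrr::map_dfr(seq_len(n_chrom), function(c) {
      ng <- per_chrom[c]
      if (ng == 0L) return(NULL)
      base <- (c - 1L) * n_frag
      slots <- round(seq(20, n_frag - 20, length.out = ng))
      primary <- base + slots + sample(-2:2, ng, replace = TRUE)
      purrr::map_dfr(seq_len(ng), function(g) {
        gid <- sprintf("G%04d", sum(per_chrom[seq_len(c - 1)]) + g)
        n_tss <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
        tss_frags <- as.integer(unique(c(primary[g],
                              primary[g] + sample(c(-3:-1, 1:3), 2)))[seq_len(n_tss)])
        r <- match(tss_frags, map$fragment_id)
        tibble::tibble(gene_id = gid, chrom = map$chrom[r],
                       tss = floor((map$start[r] + map$end[r]) / 2) + 1,
                       baited = stats::runif(n_tss) < 0.9,
                       fragment_id = tss_frags)
      })
    })
    prom <- dplyr::arrange(prom, .data$fragment_id)
    list(map = map, promoters = prom)
  })
}

#' Choose planted enhancer-gene pairs for a synthetic genome
#'
#' For each selected target gene (one with a baited promoter), a distal
#' fragment 20-150 fragments away on the same chromosome is designated the
#' planted enhancer; planted fragments stay >= 10 fragments clear of every
#' TSS fragment so they never fall in a promoter-proximal window.
#'
#' @param genome Output of [make_genome()].
#' @param n_planted Number of planted pairs (default 20).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `bait_id`, `oe_frag`.
#' @export
plant_enhancers <- function(genome, n_planted = 20, seed = 1) {
  map <- genome$map; prom <- genome$promoters
  with_seed(seed + 1L, {
    baited <- dplyr::filter(prom, .data$baited)
    cand_genes <- unique(baited$gene_id)
    targets <- sort(sample(cand_genes, min(n_planted, length(cand_genes))))
    tss_frags <- unique(prom$fragment_id)
    used <- integer(0)
    purrr::map_dfr(targets, function(g) {
      b <- baited$fragment_id[baited$gene_id == g][1]
      bc <- map$chrom[match(b, map$fragment_id)]
      same <- map$fragment_id[map$chrom == bc]
      cand <- same[abs(same - b) >= 20 & abs(same - b) <= 150]
      cand <- cand[!cand %in% used &
                     vapply(cand, function(f) min(abs(f - tss_frags)) >= 10, logical(1))]
      if (length(cand) == 0L) return(NULL)
      oe <- sample(cand, 1)
      used <<- c(used, oe)
      tibble::tibble(gene_id = g, bait_id = b, oe_frag = oe)
    })
  })
}

#' Generate CHiCAGO-style interactions and model parameters
#'
#' Scaling factors are log-normal; the distance function is a tabulated
#' power-law decay \eqn{f(d) = c\,d^{-\alpha}} on a log-spaced grid;
#' background counts follow the decay with gamma noise and carry scores
#' whose significance rate is the stated false-positive rate. Planted
#' contacts receive a fold-boost over their expected level and a score
#' above the significance threshold; the returned `truth` records them.
#'
#' @param genome Output of [make_genome()].
#' @param planted Planted contacts tibble from [plant_enhancers()] (may be
#'   empty).
#' @param bmean Brownian noise level (default 5).
#' @param decay_exponent Power-law decay exponent of f(d) (default 1).
#' @param fold_boost Fold over the expected level for planted contacts
#'   (default 30).
#' @param n_background Background interactions per baited promoter
#'   (default 30).
#' @param fp_rate Probability that a background interaction scores above 5
#'   (default 0.01).
#' @param seed Integer seed.
#' @return List: `interactions` (fragment resolution), `binned` (~5 kb
#'   other-end bins, baits unbinned), `params` (a `chicago_params`),
#'   `truth` (the planted table with realised counts).
#' @export
make_chicago_data <- function(genome, planted = NULL, bmean = 5,
                              decay_exponent = 1, fold_boost = 30,
                              n_background = 30, fp_rate = 0.01, seed = 1) {
  map <- genome$map; prom <- genome$promoters
  with_seed(seed + 2L, {
    s_i <- stats::setNames(exp(stats::rnorm(nrow(map), 0, 0.25)),
                           as.character(map$fragment_id))
    s_j <- stats::setNames(exp(stats::rnorm(nrow(map), 0, 0.25)),
                           as.character(map$fragment_id))
    # f(1.5 kb) anchored at twice the Brownian level, power-law decay
    c0 <- 2 * bmean * 1500^decay_exponent
    knots <- 10^seq(log10(300), log10(5e6), length.out = 25)
    params <- chicago_params(
      bmean = bmean, s_i = s_i, s_j = s_j,
      f_d = tibble::tibble(distance = knots, count = c0 * knots^(-decay_exponent)))
    mids <- fragment_midpoints(map)
    baits <- unique(prom$fragment_id[prom$baited])
    score_rate <- -log(fp_rate) / 5
    bg <- purrr::map_dfr(baits, function(b) {
      bc <- map$chrom[match(b, map$fragment_id)]
      same <- map$fragment_id[map$chrom == bc]
      cand <- setdiff(same[abs(same - b) >= 2 & abs(same - b) <= 400], b)
      oe <- sample(cand, min(n_background, length(cand)))
      d <- abs(mids[match(oe, map$fragment_id)] - mids[match(b, map$fragment_id)])
      mu <- distance_function(params, d)
      n <- stats::rgamma(length(oe), shape = 4, rate = 4 / mu)
      tibble::tibble(bait_id = b, oe_first = oe, oe_last = oe, n_obs = n,
                     raw_reads = stats::rpois(length(oe),
                                              n * s_i[as.character(b)] * s_j[as.character(oe)]) + 1,
                     score = stats::rexp(length(oe), rate = score_rate))
    })
    if (!is.null(planted) && nrow(planted) > 0L) {
      d <- abs(mids[match(planted$oe_frag, map$fragment_id)] -
                 mids[match(planted$bait_id, map$fragment_id)])
      base <- pmax(distance_function(params, d),
                   bmean / (s_i[as.character(planted$bait_id)] *
                              s_j[as.character(planted$oe_frag)]))
      pl <- tibble::tibble(
        bait_id = planted$bait_id, oe_first = planted$oe_frag,
        oe_last = planted$oe_frag, n_obs = fold_boost * base,
        raw_reads = round(fold_boost * base *
                            s_i[as.character(planted$bait_id)] *
                            s_j[as.character(planted$oe_frag)]) + 5,
        score = 5 + stats::rexp(nrow(planted), 0.5))
      bg <- bg[!paste(bg$bait_id, bg$oe_first) %in%
                 paste(pl$bait_id, pl$oe_first), , drop = FALSE]
      bg <- dplyr::bind_rows(bg, pl)
      truth <- dplyr::mutate(planted, n_obs = pl$n_obs, score = pl$score)
    } else {
      truth <- tibble::tibble(gene_id = character(), bait_id = integer(),
                              oe_frag = integer())
    }
    ints <- build_interactions(bg$bait_id, bg$oe_first, bg$oe_last, bg$n_obs,
                               bg$raw_reads, bg$score, "fragment", map)
    # ~5 kb other-end bins: runs of consecutive fragments summing to ~5 kb
    lens <- map$end - map$start
    bin_of <- integer(nrow(map))
    for (ch in unique(map$chrom)) {
      i <- which(map$chrom == ch)
      acc <- 0; b <- 1L
      for (k in i) {
        if (acc >= 5000) { b <- b + 1L; acc <- 0 }
        bin_of[k] <- b * 1e6 + match(ch, unique(map$chrom))
        acc <- acc + lens[k]
      }
    }
    keyed <- dplyr::mutate(ints, .bin = bin_of[match(.data$oe_first, map$fragment_id)])
    binned <- dplyr::summarise(
      dplyr::group_by(keyed, .data$bait_id, .data$.bin),
      oe_first = min(.data$oe_first), oe_last = max(.data$oe_last),
      n_obs = sum(.data$n_obs), raw_reads = sum(.data$raw_reads),
      score = max(.data$score), .groups = "drop")
    # widen each bin to the full fragment run it belongs to
    binned$oe_first <- vapply(binned$.bin, function(b)
      map$fragment_id[min(which(bin_of == b))], integer(1))
    binned$oe_last <- vapply(binned$.bin, function(b)
      map$fragment_id[max(which(bin_of == b))], integer(1))
    binned <- build_interactions(binned$bait_id, binned$oe_first,
                                 binned$oe_last, binned$n_obs,
                                 binned$raw_reads, binned$score, "bin5kb", map)
    list(interactions = ints, binned = binned, params = params, truth = truth)
  })
}

#' Generate peak tracks coupled to planted enhancers
#'
#' Background peaks are scattered uniformly with moderate read counts;
#' every planted enhancer fragment gets a strong peak in both assays, so
#' planted elements carry high activity.
#'
#' @param genome Output of [make_genome()].
#' @param planted Planted contacts tibble (`oe_frag` column used); may be
#'   empty.
#' @param n_background Background peaks per assay (default 150).
#' @param seed Integer seed.
#' @return List `atac`, `h3k27ac` of peak tibbles ([read_peaks()] layout).
#' @export
make_peaks <- function(genome, planted = NULL, n_background = 150, seed = 1) {
  map <- genome$map
  with_seed(seed + 3L, {
    bounds <- chrom_bounds(map)
    bg <- function(assay) {
      ch <- sample(bounds$chrom, n_background, replace = TRUE)
      w <- round(stats::runif(n_background, 300, 1500))
      s <- floor(stats::runif(n_background,
                              bounds$chrom_start[match(ch, bounds$chrom)],
                              bounds$chrom_end[match(ch, bounds$chrom)] - w))
      tibble::tibble(chrom = ch, start = s, end = s + w,
                     read_count = stats::rgamma(n_background, 2, rate = 0.1),
                     assay = assay)
    }
    planted_peaks <- function(assay) {
      if (is.null(planted) || nrow(planted) == 0L) return(NULL)
      r <- match(planted$oe_frag, map$fragment_id)
      tibble::tibble(chrom = map$chrom[r], start = map$start[r],
                     end = map$end[r],
                     read_count = stats::rgamma(nrow(planted), 40, rate = 0.2),
                     assay = assay)
    }
    list(atac = dplyr::bind_rows(bg("ATAC"), planted_peaks("ATAC")),
         h3k27ac = dplyr::bind_rows(bg("H3K27ac"), planted_peaks("H3K27ac")))
  })
}

#' Generate GWAS summary statistics with AR(1) LD and planted causals
#'
#' The genome is partitioned into non-overlapping LD blocks; each block
#' carries `n_var` variants with AR(1) correlation `R[i,j] = rho^|i-j|`.
#' Z-scores are drawn from \eqn{MVN(R\lambda, R)} where \eqn{\lambda}
#' places the stated non-centrality on planted causal variants. For each
#' planted causal a SuSiE-like single-variant credible set with the stated
#' pip mass is emitted.
#'
#' @param genome Output of [make_genome()].
#' @param planted_causals Tibble `gene_id`, `chrom`, `pos` (1-based) of
#'   planted causal positions; each must fall inside a block. May be empty.
#' @param n_blocks Number of LD blocks (default 20, split across
#'   chromosomes).
#' @param n_var Variants per block (default 100).
#' @param rho AR(1) LD parameter (default 0.9).
#' @param nc Non-centrality placed on each planted causal (default 7).
#' @param pip_mass Credible-set pip mass on each planted causal
#'   (default 0.95).
#' @param seed Integer seed.
#' @return List: `stats` (variant, chrom, pos, beta, se, z, p, block_id),
#'   `blocks` (block_id, chrom, start, end; 0-based half-open), `ld`
#'   (named list of per-block correlation matrices), `credsets` (signals
#'   tibble), `truth` (planted causal variants).
#' @export
make_gwas <- function(genome, planted_causals = NULL, n_blocks = 20,
                      n_var = 100, rho = 0.9, nc = 7, pip_mass = 0.95,
                      seed = 1) {
  map <- genome$map
  with_seed(seed + 4L, {
    bounds <- chrom_bounds(map)
    per_chrom <- diff(round(seq(0, n_blocks, length.out = nrow(bounds) + 1)))
    blocks <- purrr::map_dfr(seq_len(nrow(bounds)), function(c) {
      nb <- per_chrom[c]
      if (nb == 0L) return(NULL)
      cuts <- round(seq(bounds$chrom_start[c], bounds$chrom_end[c],
                        length.out = nb + 1))
      tibble::tibble(block_id = sprintf("B%02d", sum(per_chrom[seq_len(c - 1)]) +
                                          seq_len(nb)),
                     chrom = bounds$chrom[c],
                     start = cuts[-(nb + 1)], end = cuts[-1])
    })
    ar1 <- rho^abs(outer(seq_len(n_var), seq_len(n_var), "-"))
    L <- chol(ar1)
    stats_l <- list(); ld <- list(); cred <- list(); truth <- list()
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      pos <- sort(sample(seq.int(b$start + 1, b$end), n_var))
      causal_idx <- integer(0)
      if (!is.null(planted_causals) && nrow(planted_causals) > 0L) {
        inb <- which(planted_causals$chrom == b$chrom &
                       planted_causals$pos > b$start &
                       planted_causals$pos <= b$end)
        for (j in inb) {
          # snap the nearest variant onto the planted position
          k <- which.min(abs(pos - planted_causals$pos[j]))
          pos[k] <- planted_causals$pos[j]
          causal_idx <- c(causal_idx, k)
          truth[[length(truth) + 1]] <- tibble::tibble(
            block_id = b$block_id, gene_id = planted_causals$gene_id[j],
            variant = sprintf("%s_v%03d", b$block_id, k),
            chrom = b$chrom, pos = planted_causals$pos[j])
        }
        pos <- sort(pos)
      }
      lam <- rep(0, n_var); lam[causal_idx] <- nc
      z <- as.numeric(ar1 %*% lam + t(L) %*% stats::rnorm(n_var))
      vid <- sprintf("%s_v%03d", b$block_id, seq_len(n_var))
      stats_l[[i]] <- tibble::tibble(
        variant = vid, chrom = b$chrom, pos = pos, beta = z, se = 1, z = z,
        p = 2 * stats::pnorm(-abs(z)), block_id = b$block_id)
      ld[[b$block_id]] <- ar1
      for (k in causal_idx) {
        cred[[length(cred) + 1]] <- tibble::tibble(
          block_id = b$block_id,
          credset_id = sprintf("L%d", match(k, causal_idx)),
          variant = vid[k], chrom = b$chrom, pos = pos[k], pip = pip_mass)
      }
    }
    list(stats = dplyr::bind_rows(stats_l), blocks = blocks, ld = ld,
         credsets = if (length(cred)) dplyr::bind_rows(cred) else
           tibble::tibble(block_id = character(), credset_id = character(),
                          variant = character(), chrom = character(),
                          pos = double(), pip = double()),
         truth = if (length(truth)) dplyr::bind_rows(truth) else
           tibble::tibble(block_id = character(), gene_id = character(),
                          variant = character(), chrom = character(),
                          pos = double()))
  })
}

#' Generate gene expression coupled to planted enhancer activity
#'
#' Expression is constructed as the per-gene sum of ABCC numerators over
#' elements with `abc_score >= true_cutoff`, plus Gaussian noise — the
#' configuration under which cutoff selection should recover
#' `true_cutoff`.
#'
#' @param pairs ABCC pair tibble ([abc_scores()]).
#' @param genes Character vector of gene IDs for the output table.
#' @param true_cutoff Score cutoff generating the expression (default
#'   0.02).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `expression`.
#' @export
make_expression <- function(pairs, genes, true_cutoff = 0.02, noise_sd = 0,
                            seed = 1) {
  with_seed(seed + 5L, {
    base <- vapply(genes, function(g) {
      sel <- pairs$gene_id == g & pairs$abc_score >= true_cutoff
      sum(pairs$numerator[sel])
    }, numeric(1))
    tibble::tibble(gene_id = genes,
                   expression = base + stats::rnorm(length(genes), 0, noise_sd))
  })
}

#' Generate coding-SNP annotations near gene TSSs
#'
#' @param genome Output of [make_genome()].
#' @param n_genes Number of genes given coding variants (default 30).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `variant`, `chrom`, `pos`.
#' @export
make_coding_snps <- function(genome, n_genes = 30, seed = 1) {
  prom <- genome$promoters
  with_seed(seed + 6L, {
    genes <- sample(unique(prom$gene_id), min(n_genes, dplyr::n_distinct(prom$gene_id)))
    purrr::map_dfr(genes, function(g) {
      p <- prom[prom$gene_id == g, ][1, ]
      k <- sample(1:3, 1)
      tibble::tibble(gene_id = g,
                     variant = sprintf("%s_cs%d", g, seq_len(k)),
                     chrom = p$chrom,
                     pos = p$tss + sample(-200:200, k))
    })
  })
}

#' Generate the complete synthetic dataset with planted ground truth
#'
#' Orchestrates all generators into a coherent study: planted enhancer
#' contacts carry strong peaks in both assays, and planted GWAS causal
#' variants sit inside the planted enhancer fragments of their target
#' genes, so the full pipeline (ABCC scoring, consensus PIRs, multiCOGS)
#' should recover the planted target genes.
#'
#' @param seed Integer seed driving every generator.
#' @param dir Optional directory; when given, the full fixture file set is
#'   written there in the formats the readers consume (see
#'   [write_dataset()]).
#' @param n_chrom,n_frag,median_len,n_genes Passed to [make_genome()].
#' @param n_planted Planted enhancer-gene pairs (default 20).
#' @param n_gwas_planted Planted GWAS causals among those pairs
#'   (default 10).
#' @param ... Further arguments to [make_chicago_data()] / [make_gwas()].
#' @return List: `genome`, `chicago`, `peaks`, `gwas`, `coding_snps`,
#'   `truth` (planted pairs and causals, generator parameters), and when
#'   `dir` is given, `paths`.
#' @export
simulate_dataset <- function(seed, dir = NULL, n_chrom = 3, n_frag = 2000,
                             median_len = 1500, n_genes = 200,
                             n_planted = 20, n_gwas_planted = 10, ...) {
  genome <- make_genome(seed, n_chrom, n_frag, median_len, n_genes)
  planted <- plant_enhancers(genome, n_planted, seed)
  chicago <- make_chicago_data(genome, planted, seed = seed, ...)
  peaks <- make_peaks(genome, planted, seed = seed)
  map <- genome$map
  with_seed(seed + 7L, {
    pick <- planted[sample(nrow(planted), min(n_gwas_planted, nrow(planted))), ]
  })
  r <- match(pick$oe_frag, map$fragment_id)
  causal_pos <- tibble::tibble(gene_id = pick$gene_id, chrom = map$chrom[r],
                               pos = floor((map$start[r] + map$end[r]) / 2) + 1)
  gwas <- make_gwas(genome, causal_pos, seed = seed)
  coding <- make_coding_snps(genome, seed = seed)
  out <- list(
    genome = genome, chicago = chicago, peaks = peaks, gwas = gwas,
    coding_snps = coding,
    truth = list(planted_pairs = chicago$truth, planted_causals = gwas$truth,
                 params = list(seed = seed, n_chrom = n_chrom, n_frag = n_frag,
                               median_len = median_len, n_genes = n_genes,
                               n_planted = n_planted,
                               n_gwas_planted = n_gwas_planted)))
  if (!is.null(dir)) out$paths <- write_dataset(out, dir)
  out
}

#' Write a simulated dataset to disk in the toolkit's file formats
#'
#' Every file starts with a `# seed: <seed>` comment so fixtures are
#' self-describing.
#'
#' @param ds A dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- ds$truth$params$seed
  hdr <- sprintf("# seed: %d", seed)
  p <- list()
  # write_tsv(append=TRUE) never writes a header; emit comment + header manually
  seeded_tsv <- function(x, path, col_names = TRUE) {
    con <- file(path, "w")
    writeLines(hdr, con)
    if (col_names) writeLines(paste(names(x), collapse = "\t"), con)
    close(con)
    readr::write_tsv(x, path, col_names = FALSE, append = TRUE)
    path
  }
  map <- ds$genome$map
  p$fragments <- seeded_tsv(map[, c("chrom", "start", "end", "fragment_id")],
                            file.path(dir, "fragments.bed"), col_names = FALSE)
  p$promoters <- seeded_tsv(ds$genome$promoters, file.path(dir, "promoters.tsv"))
  ints_out <- function(x) tibble::tibble(baitID = x$bait_id,
                                         oeFirstID = x$oe_first,
                                         oeLastID = x$oe_last, N = x$n_obs,
                                         N.reads = x$raw_reads,
                                         score = x$score,
                                         resolution = x$resolution)
  p$interactions_fragment <- seeded_tsv(ints_out(ds$chicago$interactions),
                                        file.path(dir, "interactions_fragment.tsv"))
  p$interactions_bin5kb <- seeded_tsv(ints_out(ds$chicago$binned),
                                      file.path(dir, "interactions_bin5kb.tsv"))
  p$chicago_params <- write_chicago_params(ds$chicago$params,
                                           file.path(dir, "chicago_params.yaml"))
  p$atac <- seeded_tsv(ds$peaks$atac[, c("chrom", "start", "end", "read_count")],
                       file.path(dir, "atac.bed"), col_names = FALSE)
  p$h3k27ac <- seeded_tsv(ds$peaks$h3k27ac[, c("chrom", "start", "end", "read_count")],
                          file.path(dir, "h3k27ac.bed"), col_names = FALSE)
  p$blocks <- seeded_tsv(ds$gwas$blocks[, c("chrom", "start", "end", "block_id")],
                         file.path(dir, "blocks.bed"), col_names = FALSE)
  p$gwas <- seeded_tsv(ds$gwas$stats, file.path(dir, "gwas.tsv"))
  p$credsets <- seeded_tsv(ds$gwas$credsets, file.path(dir, "credsets.tsv"))
  p$coding_snps <- seeded_tsv(ds$coding_snps, file.path(dir, "coding_snps.tsv"))
  ld_dir <- file.path(dir, "ld")
  dir.create(ld_dir, showWarnings = FALSE)
  p$ld <- vapply(names(ds$gwas$ld), function(b) {
    f <- file.path(ld_dir, paste0(b, ".ld.tsv"))
    utils::write.table(ds$gwas$ld[[b]], f, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    f
  }, character(1))
  p$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(planted_pairs = ds$truth$planted_pairs,
                            planted_causals = ds$truth$planted_causals,
                            params = ds$truth$params),
                       p$truth, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
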