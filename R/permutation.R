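#' Permutation configuration
#'
#' @param n_perm number of permutations (the screen analyses use 10,000 for
#'   region tests and 1,000 for TSS-window enrichment)
#' @param seed integer seed; \code{NULL} uses the current RNG stream
#' @param side tail of the test: \code{less} (depletion, default) or
#'   \code{greater} (enrichment)
#' @return object of class \code{PermConfig}
#' @export
perm_config <- function(n_perm = 10000L, seed = NULL, side = c("less", "greater")) {
  side <- match.arg(side)
  if (n_perm < 1) rs_abort("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = seed, side = side),
            class = "PermConfig")
}

#' Add-one-corrected empirical p-value
#'
#' \eqn{p = (1 + \#\{null \le obs\}) / (1 + N)} for \code{side = "less"}
#' (\eqn{\ge} for \code{"greater"}). The add-one correction counts the
#' observed statistic as one more draw from the null, so p is never 0 and its
#' floor is \eqn{1/(N+1)} — the convention behind reporting
#' "P < 0.001 based on 1,000 permutations".
#'
#' @param observed observed statistic
#' @param null_values numeric vector of null statistics (non-empty)
#' @param side \code{"less"} or \code{"greater"}
#' @return empirical p in \eqn{[1/(N+1), 1]}
#' @export
empirical_p <- function(observed, null_values, side = c("less", "greater")) {
  side <- match.arg(side)
  if (!length(null_values)) rs_abort("empty permutation null")
  hits <- if (side == "less") sum(null_values <= observed) else sum(null_values >= observed)
  (1 + hits) / (1 + length(null_values))
}

#' Region-level screen test with permutation empirical p-values
#'
#' The observed statistic per region is [region_depletion_score()] (top-m
#' depleted construct mean, averaged over groups). The null reassigns
#' region-targeting constructs to region labels uniformly at random,
#' preserving each region's construct count — the fold-change distribution is
#' held fixed and only the grouping into regions is broken — and recomputes
#' every region's statistic per permutation. Empirical p-values carry the
#' add-one correction; a Benjamini-Hochberg q-value column is appended.
#'
#' @param fc centred \code{fc_table}
#' @param library \code{GuideLibrary} with >= 2 region targets
#' @param cfg \code{ScoreConfig}
#' @param perm \code{PermConfig} (use \code{side = "less"} for depletion)
#' @return data.frame: \code{target_id}, \code{score}, \code{empirical_p},
#'   \code{q_value}, \code{null_mean}, \code{null_sd}, \code{n_perm}
#' @export
region_screen_test <- function(fc, library, cfg = score_config(),
                               perm = perm_config()) {
  stopifnot(inherits(perm, "PermConfig"))
  if (perm$n_perm < 100)
    warning("n_perm < 100 gives very coarse empirical p-values", call. = FALSE)
  obs <- region_depletion_score(fc, library, cfg)
  if (nrow(obs) < 2)
    rs_abort("permutation test needs >= 2 region targets")

  # construct-by-group matrix of mean centred log2fc, region assignment factor
  cons <- library$constructs
  keep <- fc$construct_id %in% cons$construct_id[cons$target_class == "region"]
  sub <- fc[keep, , drop = FALSE]
  agg <- stats::aggregate(log2fc ~ construct_id + group_id, data = sub, FUN = mean)
  groups <- sort(unique(agg$group_id))
  cids <- sort(unique(agg$construct_id))
  M <- matrix(NA_real_, length(cids), length(groups), dimnames = list(cids, groups))
  M[cbind(match(agg$construct_id, cids), match(agg$group_id, groups))] <- agg$log2fc
  region_of <- factor(setNames(cons$target_id, cons$construct_id)[cids],
                      levels = obs$target_id)

  stat_for <- function(assign) {
    s <- matrix(NA_real_, nlevels(assign), length(groups))
    for (g in seq_along(groups))
      s[, g] <- top_m_mean_by(M[, g], assign, cfg$m_region, tie = cids)$mean
    rowMeans(s)
  }
  observed <- stat_for(region_of)
  stopifnot(max(abs(observed - obs$score)) < 1e-9)  # two code paths must agree

  null_mat <- with_seed(perm$seed, {
    vapply(seq_len(perm$n_perm),
           function(b) stat_for(sample(region_of)), numeric(nlevels(region_of)))
  })  # regions x n_perm
  cmp <- if (perm$side == "less") `<=` else `>=`
  p <- (1 + rowSums(cmp(null_mat, observed))) / (1 + perm$n_perm)
  data.frame(target_id = obs$target_id, score = observed,
             empirical_p = p, q_value = p.adjust(p, "BH"),
             null_mean = rowMeans(null_mat),
             null_sd = apply(null_mat, 1, stats::sd),
             n_perm = perm$n_perm, stringsAsFactors = FALSE)
}

tss_windows <- function(tss, window_bp) {
  # tss: data.frame(gene, chrom, tss [0-based position], optional strand)
  stopifnot(all(c("gene", "chrom", "tss") %in% names(tss)))
  GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(tss$tss - window_bp, 0) + 1L,
                     end = tss$tss + window_bp + 1L),
    gene = tss$gene)
}

#' Peak enrichment near the TSSs of a gene set
#'
#' Counts peaks intersecting the \eqn{\pm}\code{window_bp} window around the
#' TSS of at least one gene in \code{gene_set} (each peak counted once), then
#' builds a null by drawing equally sized gene sets uniformly without
#' replacement from all genes and recounting. One-sided (enrichment)
#' empirical p with add-one correction.
#'
#' @param peaks \code{GRanges} of peaks
#' @param tss data.frame with columns \code{gene}, \code{chrom}, \code{tss}
#'   (0-based TSS position)
#' @param gene_set character vector, subset of \code{tss$gene}
#' @param window_bp half-width of the TSS window (default 500 kb)
#' @param perm \code{PermConfig}; \code{side} is forced to \code{"greater"}
#' @return list: \code{observed_count}, \code{empirical_p}, \code{null_mean},
#'   \code{null_sd}, \code{window_bp}, \code{n_perm}
#' @export
tss_window_enrichment <- function(peaks, tss, gene_set, window_bp = 500000L,
                                  perm = perm_config(n_perm = 1000L)) {
  if (window_bp <= 0) rs_abort("window_bp must be > 0")
  missing_tss <- setdiff(gene_set, tss$gene)
  if (length(missing_tss))
    rs_abort("gene(s) in set without a TSS: ", paste(missing_tss, collapse = ", "))
  win <- tss_windows(tss, window_bp)
  hits <- GenomicRanges::findOverlaps(peaks, win)
  # per-gene list of peak indices within window
  peak_by_gene <- split(S4Vectors::queryHits(hits),
                        factor(tss$gene[S4Vectors::subjectHits(hits)], levels = tss$gene))
  count_for <- function(genes) {
    idx <- unlist(peak_by_gene[genes], use.names = FALSE)
    length(unique(idx))
  }
  observed <- count_for(gene_set)
  nulls <- with_seed(perm$seed, {
    vapply(seq_len(perm$n_perm),
           function(b) count_for(sample(tss$gene, length(unique(gene_set)))),
           numeric(1))
  })
  list(observed_count = observed,
       empirical_p = empirical_p(observed, nulls, side = "greater"),
       null_mean = mean(nulls), null_sd = stats::sd(nulls),
       window_bp = window_bp, n_perm = perm$n_perm)
}

#' Fisher's exact test for overlap of two interval sets within a universe
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over the universe
#' intervals, with membership either by interval identity
#' (\code{mode = "identity"}: an interval of the universe is "in A" when A
#' contains an identical interval) or by \eqn{\ge}1 bp intersection
#' (\code{mode = "overlap"}). Reports the sample odds ratio \eqn{ad/bc}, a
#' Woolf logit 95\% CI, and the one-sided (enrichment) Fisher exact p. Zero
#' cells get the Haldane-Anscombe 0.5 correction for the OR/CI only, flagged
#' in the output.
#'
#' @param setA,setB,universe \code{GRanges}
#' @param mode membership rule, see above
#' @return list: \code{odds_ratio}, \code{conf_int} (length 2),
#'   \code{p_value}, \code{table} (2x2), \code{haldane_corrected},
#'   \code{degenerate}
#' @export
interval_overlap_fisher <- function(setA, setB, universe,
                                    mode = c("identity", "overlap")) {
  mode <- match.arg(mode)
  member <- function(s) {
    if (mode == "identity") GenomicRanges::countOverlaps(universe, s, type = "equal") > 0
    else GenomicRanges::countOverlaps(universe, s) > 0
  }
  inA <- member(setA); inB <- member(setB)
  a <- sum(inA & inB); b <- sum(inA & !inB); c_ <- sum(!inA & inB); d <- sum(!inA & !inB)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  degenerate <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
  hal <- any(c(a, b, c_, d) == 0)
  or_cells <- c(a, b, c_, d) + if (hal) 0.5 else 0
  or <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])
  se <- sqrt(sum(1 / or_cells))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, conf_int = ci, p_value = p, table = tab,
       haldane_corrected = hal, degenerate = degenerate)
}

#' Overlap of two identifier sets after canonicalization
#'
#' Identifiers are canonicalized by trimming, collapsing internal whitespace
#' and upper-casing, then deduplicated.
#'
#' @param listA,listB character vectors
#' @return named integer vector \code{(n_a, n_b, n_shared)}
#' @export
set_overlap <- function(listA, listB) {
  canon <- function(x) unique(toupper(gsub("\\s+", " ", trimws(as.character(x)))))
  a <- canon(listA); b <- canon(listB)
  c(n_a = length(a), n_b = length(b), n_shared = length(intersect(a, b)))
}

#' Fraction of peaks in A intersecting at least one peak in B
#'
#' @param peaksA,peaksB \code{GRanges}
#' @param min_overlap minimum overlap in bp to count (default 1)
#' @return fraction in [0, 1]
#' @export
peak_cobinding_fraction <- function(peaksA, peaksB, min_overlap = 1L) {
  if (!length(peaksA)) rs_abort("peaksA is empty; co-binding fraction undefined")
  if (!length(peaksB)) return(0)
  mean(GenomicRanges::countOverlaps(peaksA, peaksB, minoverlap = min_overlap) > 0)
}
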