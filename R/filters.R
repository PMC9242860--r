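#' Time-course filter configuration
#'
#' @param lfc_max retained genes must have \code{log2fc < lfc_max} at every
#'   required timepoint (default 0: strictly downregulated)
#' @param padj_max adjusted-p ceiling at every required timepoint (default 0.05)
#' @param required_timepoints timepoints (hours) that must all pass
#'   (default c(32, 72): early and sustained)
#' @return object of class \code{FilterConfig}
#' @export
filter_config <- function(lfc_max = 0, padj_max = 0.05,
                          required_timepoints = c(32, 72)) {
  if (!length(required_timepoints)) rs_abort("required_timepoints must be non-empty")
  if (padj_max <= 0 || padj_max > 1) rs_abort("padj_max must be in (0, 1]")
  structure(list(lfc_max = lfc_max, padj_max = padj_max,
                 required_timepoints = as.numeric(required_timepoints)),
            class = "FilterConfig")
}

#' Genes with early and sustained downregulation
#'
#' A gene is retained iff at every required timepoint it is measured,
#' \code{log2fc < lfc_max} and \code{padj <= padj_max}. Genes missing a
#' required timepoint are excluded with a warning.
#'
#' @param points data.frame with columns \code{gene}, \code{timepoint_h},
#'   \code{log2fc}, \code{padj}
#' @param cfg \code{FilterConfig}
#' @return sorted character vector of retained genes
#' @export
sustained_downregulation_filter <- function(points, cfg = filter_config()) {
  stopifnot(inherits(cfg, "FilterConfig"))
  req <- c("gene", "timepoint_h", "log2fc", "padj")
  miss <- setdiff(req, names(points))
  if (length(miss)) rs_abort("time-course table missing column(s): ", paste(miss, collapse = ", "))
  if (any(points$padj < 0 | points$padj > 1, na.rm = TRUE))
    rs_abort("padj outside [0, 1]")
  pts <- points[points$timepoint_h %in% cfg$required_timepoints, , drop = FALSE]
  n_tp <- tapply(pts$timepoint_h, pts$gene,
                 function(t) length(unique(t)))
  incomplete <- names(n_tp)[n_tp < length(cfg$required_timepoints)]
  incomplete <- union(incomplete, setdiff(unique(points$gene), names(n_tp)))
  if (length(incomplete))
    warning(length(incomplete), " gene(s) missing a required timepoint, excluded: ",
            paste(head(incomplete, 5), collapse = ", "),
            if (length(incomplete) > 5) ", ...", call. = FALSE)
  pts <- pts[!pts$gene %in% incomplete, , drop = FALSE]
  pass <- !is.na(pts$log2fc) & !is.na(pts$padj) &
    pts$log2fc < cfg$lfc_max & pts$padj <= cfg$padj_max
  all_pass <- tapply(pass, pts$gene, all)
  sort(names(all_pass)[all_pass])
}

#' Link peaks to genes by TSS proximity
#'
#' Every (peak, gene in set) pair where the peak intersects the
#' \eqn{\pm}\code{window_bp} window around the gene's TSS (window inclusive
#' of the TSS base), with the signed distance from the TSS to the peak
#' midpoint (sign flipped for minus-strand genes when strand is provided).
#' The deduplicated peak count — the headline "peaks within the window of the
#' gene set" number — is attached as attribute \code{n_peaks_linked}.
#'
#' @inheritParams tss_window_enrichment
#' @return data.frame: \code{peak} (name or index), \code{gene},
#'   \code{distance}; attribute \code{n_peaks_linked}
#' @export
link_peaks_to_genes <- function(peaks, tss, gene_set, window_bp = 500000L) {
  if (window_bp < 0) rs_abort("window_bp must be >= 0")
  missing_tss <- setdiff(gene_set, tss$gene)
  if (length(missing_tss))
    rs_abort("gene(s) in set without a TSS: ", paste(missing_tss, collapse = ", "))
  sub <- tss[tss$gene %in% gene_set, , drop = FALSE]
  win <- tss_windows(sub, window_bp)
  hits <- GenomicRanges::findOverlaps(peaks, win)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  peak_label <- if (!is.null(names(peaks))) names(peaks) else as.character(seq_along(peaks))
  mid <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks) - 1) / 2  # 0-based midpoint
  dist <- mid[qi] - sub$tss[si]
  if (!is.null(sub$strand)) dist <- ifelse(sub$strand[si] == "-", -dist, dist)
  out <- data.frame(peak = peak_label[qi], gene = sub$gene[si], distance = dist,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_peaks_linked") <- length(unique(qi))
  out
}
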