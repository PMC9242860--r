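base_codes <- function(seq) {
  # A,C,G,T -> 1..4; anything else (N) -> NA
  match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
}

revcomp_pwm <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(p) <- DNA_BASES
  pwm(p, x$background[c("T", "G", "C", "A")], paste0(x$name, "_rc"), x$pseudoweight)
}

log_odds_matrix <- function(x) log2(sweep(x$probs, 2, x$background, "/"))

#' Maximum achievable log2-odds score of a PWM
#' @param x \code{PWM}
#' @return score in bits of the optimal word
#' @export
pwm_max_score <- function(x) sum(apply(log_odds_matrix(x), 1, max))

scan_strand <- function(lo, codes, L) {
  n <- length(codes) - L + 1L
  if (n < 1) return(list(start = integer(0), score = numeric(0)))
  # scores[i] = sum_j lo[j, codes[i + j - 1]]
  scores <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    contrib <- lo[j, ifelse(bad, 1L, cj)]
    scores <- scores + contrib
  }
  list(start = which(ok), score = scores[ok])
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window on both strands with the additive log2-odds score
#' \eqn{\sum_j \log_2(p_{j,base}/bg_{base})} (the minus strand scores the
#' reverse complement of the window). Windows containing N are skipped. Hits
#' at or above the threshold are returned sorted by (start, strand).
#'
#' @param x \code{PWM}
#' @param sequence DNA string (character or \code{DNAString}), alphabet
#'   A,C,G,T,N
#' @param threshold_bits absolute score threshold; if \code{NULL} (default)
#'   the threshold is \code{threshold_frac * pwm_max_score(x)}
#' @param threshold_frac fraction of the maximal achievable score (default 0.8)
#' @param sequence_id id recorded in the hit table
#' @return data.frame of hits: \code{sequence_id}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{strand}, \code{score}
#' @export
scan_pwm <- function(x, sequence, threshold_bits = NULL, threshold_frac = 0.8,
                     sequence_id = "seq") {
  stopifnot(inherits(x, "PWM"))
  if (is.null(threshold_bits)) threshold_bits <- threshold_frac * pwm_max_score(x)
  codes <- base_codes(sequence)
  L <- nrow(x$probs)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(codes) < L) return(empty)
  fwd <- scan_strand(log_odds_matrix(x), codes, L)
  rev_ <- scan_strand(log_odds_matrix(revcomp_pwm(x)), codes, L)
  hits <- rbind(
    data.frame(sequence_id = rep(sequence_id, length(fwd$start)),
               start = fwd$start - 1L, end = fwd$start - 1L + L,
               strand = rep("+", length(fwd$start)), score = fwd$score,
               stringsAsFactors = FALSE),
    data.frame(sequence_id = rep(sequence_id, length(rev_$start)),
               start = rev_$start - 1L, end = rev_$start - 1L + L,
               strand = rep("-", length(rev_$start)), score = rev_$score,
               stringsAsFactors = FALSE))
  hits <- hits[hits$score >= threshold_bits, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a whole set of sequences
#' @param x \code{PWM}
#' @param sequences named character vector or \code{DNAStringSet}
#' @inheritParams scan_pwm
#' @return row-bound hit table across sequences
#' @export
scan_pwm_set <- function(x, sequences, threshold_bits = NULL, threshold_frac = 0.8) {
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  do.call(rbind, lapply(seq_along(seqs), function(i)
    scan_pwm(x, seqs[[i]], threshold_bits, threshold_frac, ids[i])))
}

#' Allele-aware rescoring of a motif hit
#'
#' Replaces the base at one position of a hit and reports both scores and
#' their difference: \code{delta = score_ref - score_alt} in bits, positive
#' when the reference base is the better match to the motif. For minus-strand
#' hits the supplied (genomic, plus-strand) bases are complemented and the
#' motif column mirrored before lookup.
#'
#' @param x \code{PWM}
#' @param hit one row of a [scan_pwm()] hit table
#' @param offset_in_motif 0-based genomic offset of the variant from
#'   \code{hit$start}; must lie inside the motif
#' @param ref_base,alt_base plus-strand bases in \{A,C,G,T\}
#' @return list: \code{score_ref}, \code{score_alt}, \code{delta}
#' @export
allele_delta_score <- function(x, hit, offset_in_motif, ref_base, alt_base) {
  stopifnot(inherits(x, "PWM"))
  L <- nrow(x$probs)
  if (offset_in_motif < 0 || offset_in_motif >= L)
    rs_abort("offset_in_motif (", offset_in_motif, ") outside motif of length ", L)
  if (!all(c(ref_base, alt_base) %in% DNA_BASES))
    rs_abort("ref/alt bases must be in {A,C,G,T}")
  comp <- setNames(c("T", "G", "C", "A"), DNA_BASES)
  if (hit$strand == "-") {
    j <- L - offset_in_motif
    ref_base <- comp[[ref_base]]; alt_base <- comp[[alt_base]]
  } else {
    j <- offset_in_motif + 1L
  }
  lo <- log_odds_matrix(x)
  delta <- unname(lo[j, ref_base] - lo[j, alt_base])
  list(score_ref = hit$score, score_alt = hit$score - delta, delta = delta)
}

classify_orientation <- function(strand_up, strand_down, up_is_A) {
  if (strand_up == "+" && strand_down == "+") {
    if (up_is_A) "tandem_AB" else "tandem_BA"
  } else if (strand_up == "-" && strand_down == "-") {
    # reading along the minus strand runs right-to-left in genome coordinates
    if (up_is_A) "tandem_BA" else "tandem_AB"
  } else if (strand_up == "+") "convergent" else "divergent"
}

#' Geometry of motif-hit pairs
#'
#' Pairs every A hit with every B hit on the same sequence within
#' \code{max_span_bp} (edge-to-edge), classifies the relative orientation
#' motif-centrically — \code{tandem_AB} / \code{tandem_BA} (same strand, A
#' resp. B first in reading order), \code{convergent} (facing each other),
#' \code{divergent} (facing away) — and reports the edge-to-edge spacing
#' (negative = overlapping hits).
#'
#' @param hitsA,hitsB hit tables from [scan_pwm()]/[scan_pwm_set()]
#' @param max_span_bp maximum spacing retained
#' @return data.frame of pairs: sequence_id, coordinates and strands of both
#'   hits, \code{orientation}, \code{spacing_bp}, \code{overlapping}
#' @export
pair_geometry <- function(hitsA, hitsB, max_span_bp = 200L) {
  if (is.null(hitsA) || is.null(hitsB) || !nrow(hitsA) || !nrow(hitsB))
    return(data.frame(sequence_id = character(0), startA = integer(0),
                      endA = integer(0), strandA = character(0),
                      startB = integer(0), endB = integer(0),
                      strandB = character(0), orientation = character(0),
                      spacing_bp = integer(0), overlapping = logical(0),
                      stringsAsFactors = FALSE))
  ij <- merge(data.frame(ia = seq_len(nrow(hitsA)), sequence_id = hitsA$sequence_id,
                         stringsAsFactors = FALSE),
              data.frame(ib = seq_len(nrow(hitsB)), sequence_id = hitsB$sequence_id,
                         stringsAsFactors = FALSE))
  if (!nrow(ij)) return(pair_geometry(hitsA[0, ], hitsB[0, ]))
  a <- hitsA[as.integer(ij$ia), ]; b <- hitsB[as.integer(ij$ib), ]
  a_up <- a$start < b$start | (a$start == b$start & a$end <= b$end)
  spacing <- ifelse(a_up, b$start - a$end, a$start - b$end)
  keep <- spacing <= max_span_bp
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  a_up <- a_up[keep]; spacing <- spacing[keep]
  orientation <- vapply(seq_along(spacing), function(i) {
    if (a_up[i]) classify_orientation(a$strand[i], b$strand[i], TRUE)
    else classify_orientation(b$strand[i], a$strand[i], FALSE)
  }, character(1))
  data.frame(sequence_id = a$sequence_id, startA = a$start, endA = a$end,
             strandA = a$strand, startB = b$start, endB = b$end,
             strandB = b$strand, orientation = orientation,
             spacing_bp = as.integer(spacing), overlapping = spacing < 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize motif-pair geometries
#'
#' Tabulates (orientation, spacing) configurations, flags recurrent ones, and
#' counts pairs within a close-spacing band indicative of co-operative
#' binding-style geometry.
#'
#' @param pairs output of [pair_geometry()]
#' @param close_band_bp spacing (0..band) counted as "close" (default 10)
#' @param recurrent_min minimum count for a configuration to be called
#'   recurrent (default 5)
#' @return list: \code{by_orientation} (named counts), \code{config_counts}
#'   (data.frame orientation/spacing_bp/count), \code{recurrent} (subset with
#'   count >= recurrent_min), \code{mode} (single most frequent
#'   configuration), \code{n_close}
#' @export
pair_geometry_summary <- function(pairs, close_band_bp = 10L, recurrent_min = 5L) {
  orientations <- c("tandem_AB", "tandem_BA", "convergent", "divergent")
  by_or <- table(factor(pairs$orientation, levels = orientations))
  if (nrow(pairs)) {
    cfg <- stats::aggregate(count ~ orientation + spacing_bp,
                            data = cbind(pairs[c("orientation", "spacing_bp")], count = 1L),
                            FUN = sum)
    cfg <- cfg[order(-cfg$count, cfg$orientation, cfg$spacing_bp), ]
    rownames(cfg) <- NULL
  } else {
    cfg <- data.frame(orientation = character(0), spacing_bp = integer(0),
                      count = integer(0))
  }
  list(by_orientation = setNames(as.integer(by_or), orientations),
       config_counts = cfg,
       recurrent = cfg[cfg$count >= recurrent_min, , drop = FALSE],
       mode = if (nrow(cfg)) cfg[1, , drop = FALSE] else cfg,
       n_close = sum(pairs$spacing_bp >= 0 & pairs$spacing_bp <= close_band_bp))
}
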