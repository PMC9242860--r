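#' Allele-1 fraction of a paired allelic measurement
#'
#' @param allele1,allele2 nonnegative signals (counts, linearized qPCR
#'   signal); their sum must be positive
#' @return fraction allele1 / (allele1 + allele2); 0 or 1 indicates a
#'   monoallelic measurement (allowed, but uninformative as a normalizer)
#' @export
allele_fraction <- function(allele1, allele2) {
  if (any(allele1 < 0 | allele2 < 0)) rs_abort("allelic signals must be >= 0")
  tot <- allele1 + allele2
  if (any(tot == 0)) rs_abort("both allelic signals are zero")
  allele1 / tot
}

#' Normalize an allelic measurement to its reference
#'
#' The default odds form, \eqn{(f_s/(1-f_s)) / (f_r/(1-f_r))}, divides the
#' sample's allelic odds by the reference's (input chromatin for ChIP, gDNA
#' for expression): 1 means no allelic bias beyond the reference, and the
#' statistic inverts exactly (\eqn{r \to 1/r}) under allele relabelling.
#' \code{mode = "fraction"} divides the raw fractions instead, for
#' comparability with simpler pipelines.
#'
#' @param sample_a1,sample_a2 sample allele signals
#' @param ref_a1,ref_a2 reference allele signals; the reference fraction must
#'   be strictly inside (0, 1)
#' @param mode \code{"odds"} (default) or \code{"fraction"}
#' @return normalized allelic ratio (vectorized)
#' @export
normalize_to_reference <- function(sample_a1, sample_a2, ref_a1, ref_a2,
                                   mode = c("odds", "fraction")) {
  mode <- match.arg(mode)
  fs <- allele_fraction(sample_a1, sample_a2)
  fr <- allele_fraction(ref_a1, ref_a2)
  if (any(fr <= 0 | fr >= 1))
    rs_abort("reference allele fraction of 0 or 1 is uninformative")
  if (mode == "odds") (fs / (1 - fs)) / (fr / (1 - fr)) else fs / fr
}

#' Per-allele fold change after a knockdown
#'
#' For replicate measurements of a treated (e.g. factor-depleted) and a
#' control condition in the same assay context, computes per allele the mean
#' treated signal over the mean control signal, plus their ratio — the
#' allele-selectivity index (1 = the knockdown hits both alleles equally;
#' below 1 = allele 1 is preferentially lost).
#'
#' @param treated,control data.frames with numeric columns \code{allele1},
#'   \code{allele2} (one row per replicate), already normalized upstream
#'   (e.g. gDNA-normalized) if desired
#' @return list: \code{fold_allele1}, \code{fold_allele2}, \code{selectivity},
#'   \code{se_fold_allele1}, \code{se_fold_allele2}
#' @export
knockdown_allelic_shift <- function(treated, control) {
  for (d in list(treated, control))
    if (!all(c("allele1", "allele2") %in% names(d)) || !nrow(d))
      rs_abort("treated/control need >= 1 replicate with allele1, allele2 columns")
  m_t1 <- mean(treated$allele1); m_t2 <- mean(treated$allele2)
  m_c1 <- mean(control$allele1); m_c2 <- mean(control$allele2)
  if (m_c1 == 0 || m_c2 == 0) rs_abort("control mean of zero; fold change undefined")
  f1 <- m_t1 / m_c1; f2 <- m_t2 / m_c2
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(fold_allele1 = f1, fold_allele2 = f2, selectivity = f1 / f2,
       se_fold_allele1 = se(treated$allele1 / m_c1),
       se_fold_allele2 = se(treated$allele2 / m_c2))
}

#' Read an allelic measurement table
#'
#' TSV with columns \code{label}, \code{context} (ip/input/rna/gdna),
#' \code{condition}, \code{replicate}, \code{allele1}, \code{allele2}.
#'
#' @param path TSV path
#' @return validated data.frame
#' @export
read_allelic <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("label", "context", "condition", "replicate", "allele1", "allele2")
  miss <- setdiff(req, names(df))
  if (length(miss)) rs_abort("allelic table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$context), c("ip", "input", "rna", "gdna"))
  if (length(bad)) rs_abort("unknown allelic context: ", paste(bad, collapse = ", "))
  if (any(df$allele1 < 0 | df$allele2 < 0)) rs_abort("negative allelic signal")
  if (any(df$allele1 + df$allele2 <= 0)) rs_abort("measurement with zero total signal")
  df
}

#' Write an allelic measurement table (round-trips with [read_allelic])
#' @param df allelic data.frame
#' @param path TSV path
#' @export
write_allelic <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
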