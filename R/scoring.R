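#' Scoring configuration for dropout screens
#'
#' @param pseudocount added to every raw count before library-size
#'   normalization (keeps fold changes finite at zero counts)
#' @param k_gene number of most-depleted guides averaged per gene (default 3,
#'   the "top three depleted sgRNAs" statistic)
#' @param m_region number of most-depleted constructs averaged per region
#'   (default 2, the "two most depleted constructs per region" statistic)
#' @param control_center statistic of the non-targeting-control fold changes
#'   subtracted from every construct (\code{median}, robust default, or
#'   \code{mean})
#' @param fc_space \code{linear_then_log}: a target score is the log2 of the
#'   mean of the selected centred linear fold changes (the literal reading of
#'   "log2 of the mean of the top k depleted sgRNAs");
#'   \code{mean_of_logs}: the mean of their log2 fold changes.
#' @return object of class \code{ScoreConfig}
#' @export
score_config <- function(pseudocount = 0.5, k_gene = 3L, m_region = 2L,
                         control_center = c("median", "mean"),
                         fc_space = c("linear_then_log", "mean_of_logs")) {
  control_center <- match.arg(control_center)
  fc_space <- match.arg(fc_space)
  if (pseudocount < 0) rs_abort("pseudocount must be >= 0")
  if (k_gene < 1 || m_region < 1) rs_abort("k_gene and m_region must be >= 1")
  structure(list(pseudocount = pseudocount, k_gene = as.integer(k_gene),
                 m_region = as.integer(m_region), control_center = control_center,
                 fc_space = fc_space), class = "ScoreConfig")
}

#' Library-size normalize counts to counts-per-million
#'
#' Per sample, \eqn{a_i = 10^6 (c_i + pc) / \sum_j (c_j + pc)}; every column
#' sums to 1e6.
#'
#' @param cm \code{CountMatrix}
#' @param cfg \code{ScoreConfig} (supplies the pseudocount)
#' @return numeric matrix of abundances, same dimnames as the counts
#' @export
normalize_counts <- function(cm, cfg = score_config()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(cfg, "ScoreConfig"))
  x <- cm$counts + cfg$pseudocount
  tot <- colSums(x)
  if (any(tot == 0))
    rs_abort("sample(s) with all-zero counts and pseudocount 0: ",
             paste(colnames(cm$counts)[tot == 0], collapse = ", "))
  sweep(x, 2, tot, "/") * 1e6
}

#' Per-construct fold changes of endpoint vs reference abundance
#'
#' @param abundances matrix from [normalize_counts()]
#' @param samples the sample metadata (\code{cm$samples})
#' @return a \code{fc_table} data.frame with one row per (construct, endpoint
#'   sample): \code{construct_id}, \code{sample_id}, \code{reference_id},
#'   \code{unit_id}, \code{group_id}, \code{linear_fc}, \code{log2fc}.
#'   Attribute \code{centered} records whether [control_center()] has run.
#' @export
guide_log2fc <- function(abundances, samples) {
  ep <- samples[samples$role == "endpoint", , drop = FALSE]
  if (!nrow(ep)) rs_abort("no endpoint samples")
  if (!all(ep$sample_id %in% colnames(abundances)) ||
      !all(ep$reference_id %in% colnames(abundances)))
    rs_abort("endpoint or reference sample missing from abundance matrix")
  n <- nrow(abundances)
  out <- do.call(rbind, lapply(seq_len(nrow(ep)), function(i) {
    a_end <- abundances[, ep$sample_id[i]]
    a_ref <- abundances[, ep$reference_id[i]]
    if (any(a_ref <= 0)) rs_abort("internal error: nonpositive reference abundance")
    data.frame(construct_id = rownames(abundances),
               sample_id = ep$sample_id[i], reference_id = ep$reference_id[i],
               unit_id = ep$unit_id[i], group_id = ep$group_id[i],
               linear_fc = a_end / a_ref, log2fc = log2(a_end / a_ref),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(out, class = c("fc_table", "data.frame"), centered = FALSE)
}

#' Centre fold changes on the non-targeting controls
#'
#' Per endpoint sample, subtracts the centre (median by default) of the
#' non-targeting-control log2 fold changes from every construct, so the
#' controls define zero ("Control, average of non-targeting constructs").
#'
#' @param fc \code{fc_table} from [guide_log2fc()]
#' @param library \code{GuideLibrary} (identifies the controls)
#' @param cfg \code{ScoreConfig}
#' @return centred \code{fc_table}; attribute \code{centers} holds the
#'   per-sample control centres that were removed
#' @export
control_center <- function(fc, library, cfg = score_config()) {
  stopifnot(inherits(fc, "fc_table"), inherits(library, "GuideLibrary"))
  ctrl_ids <- library$constructs$construct_id[
    library$constructs$target_class == "nontargeting_control"]
  is_ctrl <- fc$construct_id %in% ctrl_ids
  if (!any(is_ctrl))
    rs_abort("no non-targeting controls with counts; pass uncentred fold changes ",
             "explicitly if centring is not wanted")
  fun <- if (cfg$control_center == "median") median else mean
  centers <- tapply(fc$log2fc[is_ctrl], fc$sample_id[is_ctrl], fun)
  missing_center <- setdiff(unique(fc$sample_id), names(centers))
  if (length(missing_center))
    rs_abort("endpoint sample(s) without control fold changes: ",
             paste(missing_center, collapse = ", "))
  fc$log2fc <- fc$log2fc - as.numeric(centers[fc$sample_id])
  fc$linear_fc <- 2^fc$log2fc
  attr(fc, "centered") <- TRUE
  attr(fc, "centers") <- centers
  fc
}

# Mean of the m lowest values of v within each level of factor f, ties broken
# by `tie` (construct id). Vectorised: one radix sort per call.
# Returns list(mean = per-level top-m mean, n_used = per-level min(m, size)).
top_m_mean_by <- function(v, f, m, tie = NULL) {
  f <- as.factor(f)
  o <- order(f, v, tie, method = "radix")
  fs <- as.integer(f)[o]
  sizes <- tabulate(fs, nbins = nlevels(f))
  take <- pmin(m, sizes)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  idx <- rep(starts[take > 0], take[take > 0]) + sequence(take[take > 0])
  grp <- rep(which(take > 0), take[take > 0])
  sums <- rep(NA_real_, nlevels(f))
  sums[take > 0] <- rowsum(v[o][idx], grp)[, 1]
  list(mean = sums / ifelse(take > 0, take, NA), n_used = take,
       levels = levels(f))
}

score_one_block <- function(linear_fc, log2fc, k, fc_space, tie) {
  # score for one target in one replicate: top-k depleted mean
  o <- order(log2fc, tie, method = "radix")
  sel <- o[seq_len(min(k, length(o)))]
  if (fc_space == "linear_then_log") log2(mean(linear_fc[sel])) else mean(log2fc[sel])
}

#' Gene-level sensitivity scores
#'
#' Per gene and replicate (endpoint sample), the \code{k_gene} most depleted
#' constructs are selected and averaged — under the default
#' \code{linear_then_log} space the replicate score is the log2 of the mean of
#' their centred linear fold changes — and replicate scores are averaged into
#' the gene's sensitivity score. Genes with fewer than \code{k_gene}
#' constructs use all of them (recorded in \code{n_constructs_used}).
#'
#' @param fc centred \code{fc_table}
#' @param library \code{GuideLibrary}
#' @param cfg \code{ScoreConfig}
#' @return data.frame: \code{target_id}, \code{score}, \code{n_constructs_used},
#'   then one \code{unit.<unit_id>} column per replicate
#' @export
gene_sensitivity_score <- function(fc, library, cfg = score_config()) {
  target_scores(fc, library, cfg, class = "gene", k = cfg$k_gene,
                by = "sample")
}

#' Region-level depletion scores
#'
#' Constructs' centred log2 fold changes are first averaged across each
#' group's units (tumours); per region and group the \code{m_region} lowest
#' construct averages are averaged into the group score ("normalized average
#' depletion for the two most depleted constructs per region"), and group
#' scores are averaged into the combined region score.
#'
#' @inheritParams gene_sensitivity_score
#' @return data.frame: \code{target_id}, \code{score}, \code{n_constructs_used},
#'   then one \code{group.<group_id>} column per group
#' @export
region_depletion_score <- function(fc, library, cfg = score_config()) {
  # the region statistic is defined directly in log2 space (a plain mean of
  # the m lowest construct averages); cfg$fc_space applies to gene scores only
  cfg$fc_space <- "mean_of_logs"
  target_scores(fc, library, cfg, class = "region", k = cfg$m_region,
                by = "group")
}

target_scores <- function(fc, library, cfg, class, k, by) {
  stopifnot(inherits(fc, "fc_table"))
  if (!isTRUE(attr(fc, "centered")))
    warning("scoring an uncentred fold-change table", call. = FALSE)
  cons <- library$constructs
  tgt_map <- setNames(cons$target_id, cons$construct_id)
  keep <- fc$construct_id %in% cons$construct_id[cons$target_class == class]
  if (!any(keep)) rs_abort("no constructs of class '", class, "' in the fold-change table")
  sub <- fc[keep, , drop = FALSE]
  sub$target_id <- as.character(tgt_map[sub$construct_id])
  unit_col <- if (by == "sample") sub$sample_id else sub$group_id
  if (by == "group" && any(!nzchar(unit_col)))
    rs_abort("endpoint sample(s) without a group_id; region scoring needs groups")

  sub <- data.frame(target_id = sub$target_id, construct_id = sub$construct_id,
                    unit = unit_col, log2fc = sub$log2fc, linear_fc = sub$linear_fc,
                    stringsAsFactors = FALSE)
  if (by == "group") {
    # average each construct's log2fc across the group's units first
    sub <- stats::aggregate(log2fc ~ target_id + construct_id + unit,
                            data = sub, FUN = mean)
    sub$linear_fc <- 2^sub$log2fc
  }

  targets <- sort(unique(sub$target_id))
  units <- sort(unique(sub$unit))
  mat <- matrix(NA_real_, length(targets), length(units),
                dimnames = list(targets, units))
  n_used <- setNames(integer(length(targets)), targets)
  for (tg in targets) {
    rows_t <- sub[sub$target_id == tg, , drop = FALSE]
    for (un in unique(rows_t$unit)) {
      r <- rows_t[rows_t$unit == un, , drop = FALSE]
      mat[tg, un] <- score_one_block(r$linear_fc, r$log2fc, k, cfg$fc_space,
                                     r$construct_id)
    }
    n_used[tg] <- min(k, length(unique(rows_t$construct_id)))
  }
  out <- data.frame(target_id = targets,
                    score = rowMeans(mat, na.rm = TRUE),
                    n_constructs_used = as.integer(n_used),
                    stringsAsFactors = FALSE, row.names = NULL)
  per_unit <- as.data.frame(mat)
  names(per_unit) <- paste0(if (by == "sample") "unit." else "group.", units)
  cbind(out, per_unit, row.names = NULL)
}
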