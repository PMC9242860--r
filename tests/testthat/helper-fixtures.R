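# Shared fixtures and independent oracles. Oracles deliberately use naive
# enumeration / quadratic algorithms, never the package's own code paths.

toy_library <- function() {
  guide_library(data.frame(
    construct_id = c("rA_c1", "rA_c2", "rB_c1", "g1_c1", "ntc_1", "ess_1"),
    protospacer_1 = strrep("ACGT", 5),
    protospacer_2 = c(strrep("GATC", 5), NA, NA, NA, NA, NA),
    target_id = c("regA", "regA", "regB", "gene1", "", "ESS1"),
    target_class = c("region", "region", "region", "gene",
                     "nontargeting_control", "essential_control"),
    stringsAsFactors = FALSE))
}

# hand-built fc_table, already "centred"
make_fc <- function(construct_id, sample_id, log2fc, unit_id = sample_id,
                    group_id = "g1", centered = TRUE) {
  df <- data.frame(construct_id = construct_id, sample_id = sample_id,
                   reference_id = "ref", unit_id = unit_id, group_id = group_id,
                   linear_fc = 2^log2fc, log2fc = log2fc,
                   stringsAsFactors = FALSE)
  structure(df, class = c("fc_table", "data.frame"), centered = centered)
}

bind_fc <- function(..., centered = TRUE) {
  structure(rbind(...), class = c("fc_table", "data.frame"), centered = centered)
}

simple_library <- function(targets, class = "region", n_ctrl = 2) {
  cons <- data.frame(construct_id = names(targets), target_id = unname(targets),
                     target_class = class, protospacer_1 = strrep("A", 20),
                     protospacer_2 = NA_character_, stringsAsFactors = FALSE)
  if (n_ctrl > 0)
    cons <- rbind(cons, data.frame(
      construct_id = sprintf("ntc_%d", seq_len(n_ctrl)), target_id = "",
      target_class = "nontargeting_control", protospacer_1 = strrep("A", 20),
      protospacer_2 = NA_character_, stringsAsFactors = FALSE))
  guide_library(cons)
}

# exhaustive top-k mean oracle: minimum over all k-subsets of the mean
oracle_top_k_mean <- function(values, k) {
  k <- min(k, length(values))
  min(apply(combn(length(values), k), 2, function(ix) mean(values[ix])))
}

# brute-force PWM scan: rescore every window on both strands by explicit loops
oracle_scan <- function(probs, background, sequence, threshold) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_word <- function(w) {
    b <- strsplit(w, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_along(b), function(j)
      log2(probs[j, b[j]] / background[b[j]]), numeric(1)))
  }
  L <- nrow(probs); n <- nchar(sequence)
  out <- NULL
  for (i in seq_len(n - L + 1)) {
    w <- substr(sequence, i, i + L - 1)
    for (st in c("+", "-")) {
      s <- score_word(if (st == "+") w else rc(w))
      if (!is.na(s) && s >= threshold)
        out <- rbind(out, data.frame(start = i - 1L, end = i - 1L + L,
                                     strand = st, score = s,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0), score = numeric(0)))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# one-sided (enrichment) Fisher p by explicit hypergeometric tail summation
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  sum(dhyper(xs[xs >= a], m, n, k))
}

toy_pwm_consensus <- function(word, p_major = 0.94) {
  bases <- strsplit(word, "")[[1]]
  probs <- matrix((1 - p_major) / 3, length(bases), 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- p_major
  pwm(probs, name = paste0("consensus_", word))
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

centered_fc_from_sim <- function(sim, cfg = score_config()) {
  ab <- normalize_counts(sim$counts, cfg)
  control_center(guide_log2fc(ab, sim$counts$samples), sim$library, cfg)
}
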