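#' Screen-simulation configuration
#'
#' The generative model mirrors an in vivo pooled dropout screen: a skewed
#' plasmid pool (log-normal abundance), per-construct efficacy, per-target
#' fitness effects acting over a number of population doublings, a
#' per-tumour engraftment bottleneck (multinomial founder draw), and
#' overdispersed (negative binomial) sequencing counts. Defaults emulate the
#' in vivo enhancer screen design: two groups (left/right flank) of tumours,
#' a shared plasmid reference, non-targeting and essential-gene controls.
#'
#' @param n_targets number of targets (regions or genes)
#' @param constructs_per_target constructs per target (default 4)
#' @param target_class \code{"region"} or \code{"gene"}
#' @param n_nontargeting,n_essential numbers of control constructs
#' @param n_depleting how many targets carry a true fitness effect
#' @param fitness_depleting fitness effect per doubling of true hits
#'   (default -0.3; a fully effective guide then drops
#'   \code{2^(n_doublings * fitness)}-fold)
#' @param fitness_essential fitness of essential-control constructs
#'   (default -0.5 per doubling, a strong dropout)
#' @param n_doublings population doublings between reference and endpoint
#' @param plasmid_log2_sd log2-scale s.d. of plasmid abundance skew (default 1)
#' @param efficacy_shape1,efficacy_shape2 Beta parameters of per-construct
#'   efficacy (default Beta(5, 1): most guides effective)
#' @param bottleneck_size founder cells per tumour (default 1e5)
#' @param n_groups,n_units_per_group screen layout (default 2 x 5)
#' @param depth sequencing depth per sample (default 1e6)
#' @param nb_size negative-binomial size (overdispersion; default 10)
#' @param seed integer seed; the whole simulation is a pure function of
#'   (config, seed)
#' @return object of class \code{SimConfig}
#' @export
sim_config <- function(n_targets = 100L, constructs_per_target = 4L,
                       target_class = c("region", "gene"),
                       n_nontargeting = 10L, n_essential = 10L,
                       n_depleting = 0L, fitness_depleting = -0.3,
                       fitness_essential = -0.5, n_doublings = 10L,
                       plasmid_log2_sd = 1, efficacy_shape1 = 5,
                       efficacy_shape2 = 1, bottleneck_size = 1e5,
                       n_groups = 2L, n_units_per_group = 5L,
                       depth = 1e6, nb_size = 10, seed = 1L) {
  target_class <- match.arg(target_class)
  if (depth <= 0) rs_abort("sequencing depth must be > 0")
  if (bottleneck_size < 1) rs_abort("bottleneck_size must be >= 1")
  if (n_depleting > n_targets) rs_abort("n_depleting exceeds n_targets")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a pooled dropout screen
#'
#' See [sim_config()] for the generative model. Reference counts are a
#' multinomial draw from the plasmid pool; each tumour/unit draws
#' \code{bottleneck_size} founders multinomially, each construct then grows
#' by \code{2^(n_doublings * efficacy * fitness)}, and endpoint counts are
#' negative binomial around the grown proportions times \code{depth}.
#'
#' @param cfg \code{SimConfig}
#' @return list: \code{library} (\code{GuideLibrary}), \code{counts}
#'   (\code{CountMatrix}), \code{truth} (list with per-target \code{fitness}
#'   and per-construct \code{efficacy})
#' @export
simulate_screen <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    tid <- sprintf("%s%03d", if (cfg$target_class == "region") "R" else "G",
                   seq_len(cfg$n_targets))
    fitness <- setNames(rep(0, cfg$n_targets), tid)
    if (cfg$n_depleting > 0)
      fitness[sample(tid, cfg$n_depleting)] <- cfg$fitness_depleting

    cons <- rbind(
      data.frame(construct_id = sprintf("%s_c%d", rep(tid, each = cfg$constructs_per_target),
                                        rep(seq_len(cfg$constructs_per_target), cfg$n_targets)),
                 target_id = rep(tid, each = cfg$constructs_per_target),
                 target_class = cfg$target_class, stringsAsFactors = FALSE),
      data.frame(construct_id = sprintf("NTC_c%02d", seq_len(cfg$n_nontargeting)),
                 target_id = "", target_class = "nontargeting_control",
                 stringsAsFactors = FALSE),
      data.frame(construct_id = sprintf("ESS_c%02d", seq_len(cfg$n_essential)),
                 target_id = sprintf("ESS%02d", seq_len(cfg$n_essential)),
                 target_class = "essential_control", stringsAsFactors = FALSE))
    n <- nrow(cons)
    cons$protospacer_1 <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, 20, replace = TRUE), collapse = ""), character(1))
    cons$protospacer_2 <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, 20, replace = TRUE), collapse = ""), character(1))

    regions <- NULL
    if (cfg$target_class == "region") {
      starts <- seq(10000L, by = 5000L, length.out = cfg$n_targets)
      regions <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts + 1L, end = starts + 400L))
      names(regions) <- tid
    }
    library <- guide_library(cons, regions)

    fitness_all <- c(fitness,
                     setNames(rep(cfg$fitness_essential, cfg$n_essential),
                              sprintf("ESS%02d", seq_len(cfg$n_essential))))
    fit_of_construct <- ifelse(cons$target_class == "nontargeting_control", 0,
                               fitness_all[cons$target_id])
    efficacy <- setNames(rbeta(n, cfg$efficacy_shape1, cfg$efficacy_shape2),
                         cons$construct_id)
    growth <- 2^(cfg$n_doublings * efficacy * fit_of_construct)

    plasmid_prop <- 2^rnorm(n, 0, cfg$plasmid_log2_sd)
    plasmid_prop <- plasmid_prop / sum(plasmid_prop)
    ref_counts <- as.vector(rmultinom(1, cfg$depth, plasmid_prop))

    samples <- data.frame(sample_id = "plasmid", role = "reference",
                          unit_id = "plasmid", group_id = "", reference_id = "",
                          stringsAsFactors = FALSE)
    cols <- list(plasmid = ref_counts)
    for (g in seq_len(cfg$n_groups)) for (u in seq_len(cfg$n_units_per_group)) {
      sid <- sprintf("g%d_t%02d", g, u)
      founders <- as.vector(rmultinom(1, cfg$bottleneck_size, plasmid_prop))
      grown <- founders * growth
      mu <- grown / sum(grown) * cfg$depth
      cols[[sid]] <- rnbinom(n, size = cfg$nb_size, mu = mu)
      samples <- rbind(samples, data.frame(
        sample_id = sid, role = "endpoint", unit_id = sprintf("t%02d", u),
        group_id = sprintf("group%d", g), reference_id = "plasmid",
        stringsAsFactors = FALSE))
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- cons$construct_id
    list(library = library, counts = count_matrix(counts, samples),
         truth = list(fitness = fitness_all, efficacy = efficacy))
  })
}

#' Simulate a genome annotation with optional planted TSS-proximal peaks
#'
#' TSSs are placed uniformly on the given chromosomes; a designated gene set
#' is drawn, and a fraction \code{enrichment} of peaks is planted uniformly
#' within \eqn{\pm}\code{window_bp} of random designated genes while the
#' rest fall uniformly on the genome.
#'
#' @param n_genes,n_peaks counts
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param gene_set_size size of the designated (e.g. downregulated) gene set
#' @param enrichment fraction of peaks planted near designated genes
#' @param window_bp planting window (default 500 kb)
#' @param peak_width width of simulated peaks (default 400 bp)
#' @param seed integer seed
#' @return list: \code{tss} (data.frame gene/chrom/tss), \code{peaks}
#'   (\code{GRanges} with \code{planted} flag), \code{gene_set}
#' @export
simulate_genome_annotation <- function(n_genes = 200L, n_peaks = 200L,
                                       chrom_lengths = c(chr1 = 50e6, chr2 = 50e6),
                                       gene_set_size = 20L, enrichment = 0,
                                       window_bp = 500000L, peak_width = 400L,
                                       seed = 1L) {
  if (any(chrom_lengths < 2 * window_bp + peak_width + 2))
    rs_abort("chromosome(s) too short for the requested window")
  if (gene_set_size > n_genes) rs_abort("gene_set_size exceeds n_genes")
  with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(runif(n_genes, window_bp, chrom_lengths[chrom] - window_bp))
    tss <- data.frame(gene = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = chrom, tss = pos, stringsAsFactors = FALSE)
    gene_set <- sort(sample(tss$gene, gene_set_size))
    n_planted <- round(enrichment * n_peaks)
    planted <- logical(0); pchrom <- character(0); pstart <- numeric(0)
    if (n_planted > 0) {
      host <- tss[match(sample(gene_set, n_planted, replace = TRUE), tss$gene), ]
      off <- floor(runif(n_planted, -window_bp, window_bp - peak_width))
      pchrom <- host$chrom; pstart <- host$tss + off; planted <- rep(TRUE, n_planted)
    }
    n_bg <- n_peaks - n_planted
    if (n_bg > 0) {
      bchrom <- sample(names(chrom_lengths), n_bg, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
      bstart <- floor(runif(n_bg, 0, chrom_lengths[bchrom] - peak_width))
      pchrom <- c(pchrom, bchrom); pstart <- c(pstart, bstart)
      planted <- c(planted, rep(FALSE, n_bg))
    }
    peaks <- if (n_peaks > 0) {
      gr <- intervals_bed0(pchrom, pstart, pstart + peak_width,
                           name = sprintf("peak%03d", seq_len(n_peaks)))
      gr$planted <- planted
      gr
    } else GenomicRanges::GRanges()
    list(tss = tss, peaks = peaks, gene_set = gene_set)
  })
}

sample_pwm_site <- function(x) {
  paste(apply(x$probs, 1, function(p) sample(DNA_BASES, 1, prob = p)), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate sequences with a planted motif pair
#'
#' Each sequence carries one site sampled from \code{pwmA} and one from
#' \code{pwmB} at the requested orientation and edge-to-edge spacing, at a
#' random offset; the rest is i.i.d. background. \code{orientation = "none"}
#' plants nothing (background-only sequences for false-positive calibration).
#'
#' @param pwmA,pwmB \code{PWM}s
#' @param orientation \code{"tandem_AB"}, \code{"tandem_BA"},
#'   \code{"convergent"}, \code{"divergent"} or \code{"none"}
#' @param spacing_bp edge-to-edge spacing of the planted pair (>= 0)
#' @param n_sequences,seq_length output dimensions
#' @param background base composition (A,C,G,T)
#' @param seed integer seed
#' @return list: \code{sequences} (named character vector), \code{truth}
#'   (data.frame of planted coordinates and strands, 0-based half-open)
#' @export
simulate_sequences_with_motifs <- function(pwmA, pwmB, orientation = "tandem_AB",
                                           spacing_bp = 7L, n_sequences = 100L,
                                           seq_length = 300L,
                                           background = rep(0.25, 4), seed = 1L) {
  orientation <- match.arg(orientation,
    c("tandem_AB", "tandem_BA", "convergent", "divergent", "none"))
  la <- nrow(pwmA$probs); lb <- nrow(pwmB$probs)
  span <- la + lb + spacing_bp
  if (orientation != "none" && (spacing_bp < 0 || span > seq_length))
    rs_abort("infeasible geometry: motifs + spacing exceed seq_length")
  with_seed(seed, {
    seqs <- character(n_sequences)
    truth <- NULL
    for (i in seq_len(n_sequences)) {
      s <- sample(DNA_BASES, seq_length, replace = TRUE, prob = background)
      if (orientation != "none") {
        site_a <- sample_pwm_site(pwmA); site_b <- sample_pwm_site(pwmB)
        # upstream/downstream words and strands per orientation class
        geom <- switch(orientation,
          tandem_AB = list(up = site_a, dn = site_b, su = "+", sd = "+", a_up = TRUE),
          tandem_BA = list(up = site_b, dn = site_a, su = "+", sd = "+", a_up = FALSE),
          convergent = list(up = site_a, dn = revcomp_chr(site_b), su = "+", sd = "-", a_up = TRUE),
          divergent = list(up = revcomp_chr(site_a), dn = site_b, su = "-", sd = "+", a_up = TRUE))
        lu <- nchar(geom$up); ld <- nchar(geom$dn)
        off <- sample.int(seq_length - span + 1L, 1) - 1L  # 0-based offset
        s[(off + 1):(off + lu)] <- strsplit(geom$up, "")[[1]]
        dstart <- off + lu + spacing_bp
        s[(dstart + 1):(dstart + ld)] <- strsplit(geom$dn, "")[[1]]
        a_start <- if (geom$a_up) off else dstart
        b_start <- if (geom$a_up) dstart else off
        truth <- rbind(truth, data.frame(
          sequence_id = sprintf("seq%04d", i),
          a_start = a_start, a_end = a_start + la,
          a_strand = if (geom$a_up) geom$su else geom$sd,
          b_start = b_start, b_end = b_start + lb,
          b_strand = if (geom$a_up) geom$sd else geom$su,
          orientation = orientation, spacing_bp = spacing_bp,
          stringsAsFactors = FALSE))
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- sprintf("seq%04d", seq_len(n_sequences))
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate allelic count tables with a programmed knockdown selectivity
#'
#' gDNA measurements are Binomial(depth, 0.5) per replicate; RNA
#' measurements are Binomial around the control fraction
#' \code{base_fraction} (control condition) or the fraction implied by
#' multiplying allele 1's signal by \code{true_selectivity} (treated
#' condition). Output matches the allelic module's input schema.
#'
#' @param true_selectivity programmed allele-selectivity index (fold change
#'   of allele 1 over fold change of allele 2 under the knockdown)
#' @param depth reads/molecules per measurement
#' @param n_replicates replicates per condition
#' @param base_fraction control-condition allele-1 fraction (default 0.5)
#' @param seed integer seed
#' @return data.frame in [read_allelic()] schema; conditions are
#'   \code{"control"} and \code{"treated"}
#' @export
simulate_allelic_counts <- function(true_selectivity = 1, depth = 1e4,
                                    n_replicates = 3L, base_fraction = 0.5,
                                    seed = 1L) {
  if (depth < 1) rs_abort("depth must be >= 1")
  f_treat <- base_fraction * true_selectivity /
    (base_fraction * true_selectivity + (1 - base_fraction))
  with_seed(seed, {
    rows <- list()
    for (cond in c("control", "treated")) {
      f_rna <- if (cond == "control") base_fraction else f_treat
      for (r in seq_len(n_replicates)) {
        g1 <- rbinom(1, depth, 0.5)
        rows[[length(rows) + 1]] <- data.frame(
          label = "locus", context = "gdna", condition = cond, replicate = r,
          allele1 = g1, allele2 = depth - g1, stringsAsFactors = FALSE)
        r1 <- rbinom(1, depth, f_rna)
        rows[[length(rows) + 1]] <- data.frame(
          label = "locus", context = "rna", condition = cond, replicate = r,
          allele1 = r1, allele2 = depth - r1, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
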