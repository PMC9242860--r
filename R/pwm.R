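DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs L x 4 numeric matrix of base probabilities, columns A,C,G,T;
#'   every row must sum to 1 (within 1e-9) with strictly positive entries.
#' @param background length-4 base composition of the null model (sums to 1)
#' @param name motif name
#' @param pseudoweight the pseudocount fraction used if built from counts
#'   (recorded for provenance; \code{NA} when \code{probs} were given directly)
#' @return object of class \code{PWM}
#' @export
pwm <- function(probs, background = rep(0.25, 4), name = "motif", pseudoweight = NA_real_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) rs_abort("PWM must have 4 columns (A,C,G,T)")
  colnames(probs) <- DNA_BASES
  if (any(probs <= 0)) rs_abort("PWM probabilities must be strictly positive (apply a pseudoweight)")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) rs_abort("PWM rows must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    rs_abort("background must be 4 positive probabilities summing to 1")
  names(background) <- DNA_BASES
  structure(list(probs = probs, background = background, name = name,
                 pseudoweight = pseudoweight), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$name, "- length", nrow(x$probs), "\n")
  cat("consensus:", paste(information_content(x)$consensus, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.PWM <- function(x) nrow(x$probs)

#' Build a PWM from a base-count matrix
#'
#' Per position with total count N, each cell receives a flat pseudocount of
#' \code{pseudoweight * N * 4 * background_b} (i.e. \code{pseudoweight * N}
#' per cell under the uniform background), so probabilities are
#' \code{(count + pseudo) / (N * (1 + 4 * pseudoweight))}.
#'
#' @param counts L x 4 nonnegative count matrix, columns A,C,G,T
#' @param pseudoweight fractional pseudocount per cell (default 0.01)
#' @param background,name as in [pwm()]
#' @return \code{PWM}
#' @export
pwm_from_counts <- function(counts, pseudoweight = 0.01,
                            background = rep(0.25, 4), name = "motif") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 || any(counts < 0)) rs_abort("counts must be L x 4, nonnegative")
  if (pseudoweight <= 0) rs_abort("pseudoweight must be > 0")
  n <- rowSums(counts)
  if (any(n == 0)) rs_abort("PWM position with zero total count")
  pseudo <- outer(n * 4 * pseudoweight, as.numeric(background))
  probs <- (counts + pseudo) / (n * (1 + 4 * pseudoweight))
  pwm(probs, background, name, pseudoweight)
}

#' Per-position information content of a PWM
#'
#' Kullback-Leibler information against the PWM's background,
#' \eqn{IC_j = \sum_b p_{jb} \log_2(p_{jb}/bg_b)} (bits), together with the
#' highest-probability base at each position.
#'
#' @param x \code{PWM}
#' @return data.frame with columns \code{position} (1-based), \code{ic_bits},
#'   \code{consensus}
#' @export
information_content <- function(x) {
  stopifnot(inherits(x, "PWM"))
  lo <- log2(sweep(x$probs, 2, x$background, "/"))
  data.frame(position = seq_len(nrow(x$probs)),
             ic_bits = rowSums(x$probs * lo),
             consensus = DNA_BASES[max.col(x$probs, ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Read PWMs from JASPAR raw-count or MEME minimal files
#'
#' JASPAR raw counts are converted to probabilities via [pwm_from_counts()]
#' with the given pseudoweight; MEME files already carry probabilities (a tiny
#' floor keeps zero cells positive). The background defaults to uniform unless
#' the MEME file specifies letter frequencies.
#'
#' @param path motif file
#' @param dialect \code{"jaspar"} or \code{"meme"}
#' @param pseudoweight pseudocount fraction for count-based matrices
#' @return list of \code{PWM}
#' @export
read_pwm <- function(path, dialect = c("jaspar", "meme"), pseudoweight = 0.01) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "jaspar") read_pwm_jaspar(lines, pseudoweight)
  else read_pwm_meme(lines)
}

read_pwm_jaspar <- function(lines, pseudoweight) {
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) rs_abort("no JASPAR records ('>' headers) found")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    name <- strsplit(trimws(hdr), "\\s+")[[1]]
    name <- if (length(name) > 1) name[2] else name[1]
    block <- lines[(starts[k] + 1L):ends[k]]
    if (length(block) != 4) rs_abort("JASPAR record '", name, "': expected 4 base rows")
    rows <- lapply(block, function(l) {
      base <- sub("^\\s*([ACGT]).*", "\\1", l)
      nums <- sub("^\\s*[ACGT]?\\s*\\[?", "", l)
      nums <- sub("\\]\\s*$", "", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) rs_abort("JASPAR record '", name, "': non-numeric counts")
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES)) bases <- DNA_BASES  # bare 4-line numeric form
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1)
      rs_abort("JASPAR record '", name, "': rows of unequal length")
    counts <- t(do.call(rbind, lapply(rows, `[[`, "vals")))
    colnames(counts) <- bases
    counts <- counts[, DNA_BASES, drop = FALSE]
    out[[k]] <- pwm_from_counts(counts, pseudoweight, name = name)
  }
  out
}

read_pwm_meme <- function(lines) {
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    if (anyNA(vals[DNA_BASES])) rs_abort("malformed MEME background line")
    background <- as.numeric(vals[DNA_BASES]) / sum(vals[DNA_BASES])
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) rs_abort("no MOTIF records found in MEME file")
  out <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[motif_at[k]])), "\\s+")[[1]][1]
    lpm <- grep("^letter-probability matrix", lines)
    lpm <- lpm[lpm > motif_at[k]][1]
    if (is.na(lpm)) rs_abort("MOTIF '", name, "' has no letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lpm])))
    if (is.na(w)) rs_abort("MOTIF '", name, "': cannot parse width (w=)")
    rows <- lines[(lpm + 1L):(lpm + w)]
    probs <- t(vapply(rows, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) rs_abort("MOTIF '", name, "': malformed probability row")
      v
    }, numeric(4), USE.NAMES = FALSE))
    probs[probs <= 0] <- 1e-9
    probs <- probs / rowSums(probs)
    out[[k]] <- pwm(probs, background, name)
  }
  out
}

#' Write PWMs in MEME minimal format (round-trips with [read_pwm()])
#' @param pwms a \code{PWM} or list of them
#' @param path output path
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(DNA_BASES, format(bg, digits = 17), collapse = " ")), con)
  for (p in pwms) {
    writeLines(c("", paste("MOTIF", p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d", nrow(p$probs))), con)
    writeLines(apply(p$probs, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  }
  invisible(path)
}
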