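#' Read genomic intervals from a BED file
#'
#' BED3+ (tab-separated, 0-based half-open) via \pkg{rtracklayer}; the file's
#' coordinates are preserved exactly on round-trip with [write_intervals].
#' Column 4 populates interval names when present; column 6 the strand.
#'
#' @param path BED file
#' @return \link[GenomicRanges]{GRanges} in file order
#' @export
read_intervals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GenomicRanges::GRanges())
  body <- !grepl("^(track|browser|#)", lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    line_no <- which(body)[i]
    if (length(f) < 3) rs_abort("BED line ", line_no, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) rs_abort("BED line ", line_no, ": non-numeric coordinates")
    if (e <= s) rs_abort("BED line ", line_no, ": end (", f[3],
                         ") must exceed start (", f[2], ")")
    if (s < 0) rs_abort("BED line ", line_no, ": negative start")
  }
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write intervals to BED (round-trips with [read_intervals])
#' @param gr \code{GRanges}; names (or a \code{name} column) become BED column 4
#' @param path output BED path
#' @export
write_intervals <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$name) && !is.null(names(gr))) gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Build intervals from raw BED-convention coordinates
#'
#' Convenience constructor taking 0-based half-open coordinates (the BED
#' convention used by all of this package's text formats) and returning the
#' 1-based closed \code{GRanges} used internally.
#'
#' @param chrom,start,end vectors of chromosome, 0-based start, exclusive end
#' @param name optional interval names
#' @param strand optional strand ("+", "-", "*")
#' @return \code{GRanges}
#' @export
intervals_bed0 <- function(chrom, start, end, name = NULL, strand = NULL) {
  if (any(end <= start)) rs_abort("end must exceed start")
  if (any(start < 0)) rs_abort("negative start")
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end)),
    strand = if (is.null(strand)) "*" else strand)
  if (!is.null(name)) { names(gr) <- name; gr$name <- name }
  gr
}
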