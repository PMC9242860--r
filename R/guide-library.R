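TARGET_CLASSES <- c("gene", "region", "nontargeting_control", "essential_control")

#' Construct a guide library
#'
#' A guide library maps constructs (single or tandem protospacer pairs, as
#' used for CRISPRi enhancer silencing) to their targets. Targets belong to
#' one of four classes: \code{gene}, \code{region}, \code{nontargeting_control}
#' (no genomic target; used for centring fold changes) and
#' \code{essential_control} (positive-control dropouts).
#'
#' @param constructs data.frame with columns \code{construct_id},
#'   \code{protospacer_1}, optionally \code{protospacer_2} (NA or "" for
#'   single-guide constructs), \code{target_id} (empty/NA only for
#'   non-targeting controls) and \code{target_class}.
#' @param region_coords optional \link[GenomicRanges]{GRanges} of region-target
#'   coordinates, with names (or a \code{name} column) equal to region
#'   \code{target_id}s.
#' @return object of class \code{GuideLibrary}: a list with elements
#'   \code{constructs} (validated data.frame) and \code{regions}.
#' @export
guide_library <- function(constructs, region_coords = NULL) {
  stopifnot(is.data.frame(constructs))
  req <- c("construct_id", "protospacer_1", "target_id", "target_class")
  missing_cols <- setdiff(req, names(constructs))
  if (length(missing_cols))
    rs_abort("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  constructs <- as.data.frame(constructs, stringsAsFactors = FALSE)
  if (!"protospacer_2" %in% names(constructs)) constructs$protospacer_2 <- NA_character_
  constructs$construct_id <- as.character(constructs$construct_id)
  constructs$target_id <- ifelse(is.na(constructs$target_id), "", as.character(constructs$target_id))
  constructs$target_class <- as.character(constructs$target_class)

  dup <- constructs$construct_id[duplicated(constructs$construct_id)]
  if (length(dup))
    rs_abort("duplicate construct_id: ", paste(unique(dup), collapse = ", "))
  bad_class <- setdiff(unique(constructs$target_class), TARGET_CLASSES)
  if (length(bad_class))
    rs_abort("unknown target_class token(s): ", paste(bad_class, collapse = ", "))
  ntc <- constructs$target_class == "nontargeting_control"
  if (any(ntc & nzchar(constructs$target_id)))
    rs_abort("nontargeting_control constructs must have an empty target_id: ",
             paste(constructs$construct_id[ntc & nzchar(constructs$target_id)], collapse = ", "))
  if (any(!ntc & !nzchar(constructs$target_id)))
    rs_abort("targeting constructs must have a non-empty target_id: ",
             paste(constructs$construct_id[!ntc & !nzchar(constructs$target_id)], collapse = ", "))
  for (col in c("protospacer_1", "protospacer_2")) {
    sp <- constructs[[col]]
    sp <- sp[!is.na(sp) & nzchar(sp)]
    if (length(sp) && any(grepl("[^ACGT]", sp)))
      rs_abort(col, " contains characters outside {A,C,G,T}")
  }

  if (!is.null(region_coords)) {
    stopifnot(methods::is(region_coords, "GRanges"))
    rn <- names(region_coords)
    if (is.null(rn) && !is.null(region_coords$name)) rn <- region_coords$name
    if (is.null(rn)) rs_abort("region_coords must be named by region target_id")
    names(region_coords) <- rn
    region_targets <- unique(constructs$target_id[constructs$target_class == "region"])
    orphan <- setdiff(rn, region_targets)
    if (length(orphan))
      rs_abort("region_coords for targets with no construct: ", paste(orphan, collapse = ", "))
  }

  structure(list(constructs = constructs, regions = region_coords),
            class = "GuideLibrary")
}

#' @export
print.GuideLibrary <- function(x, ...) {
  tally <- table(factor(x$constructs$target_class, levels = TARGET_CLASSES))
  cat("GuideLibrary:", nrow(x$constructs), "constructs\n")
  for (cl in TARGET_CLASSES) cat(sprintf("  %-22s %d\n", cl, tally[[cl]]))
  if (!is.null(x$regions)) cat("  region coordinates for", length(x$regions), "targets\n")
  invisible(x)
}

#' Per-class construct tally of a guide library
#' @param library a \code{GuideLibrary}
#' @return named integer vector over the four target classes
#' @export
library_class_tally <- function(library) {
  stopifnot(inherits(library, "GuideLibrary"))
  tab <- table(factor(library$constructs$target_class, levels = TARGET_CLASSES))
  setNames(as.integer(tab), TARGET_CLASSES)
}

#' Read a guide library from TSV
#'
#' Expected columns: \code{construct_id}, \code{protospacer_1}, optional
#' \code{protospacer_2}, \code{target_id}, \code{target_class}, and optional
#' \code{chrom}/\code{start}/\code{end} (BED convention: 0-based half-open)
#' giving the coordinates of region targets.
#'
#' @param path TSV file path
#' @param quiet suppress the per-class tally message
#' @return \code{GuideLibrary}
#' @export
read_library <- function(path, quiet = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  regions <- NULL
  if (all(c("chrom", "start", "end") %in% names(df))) {
    has <- nzchar(df$chrom) & !is.na(df$chrom)
    if (any(has)) {
      coord <- unique(df[has, c("target_id", "chrom", "start", "end")])
      if (anyDuplicated(coord$target_id))
        rs_abort("conflicting region coordinates for target(s): ",
                 paste(coord$target_id[duplicated(coord$target_id)], collapse = ", "))
      regions <- GenomicRanges::GRanges(
        coord$chrom,
        IRanges::IRanges(start = as.integer(coord$start) + 1L,
                         end = as.integer(coord$end)))
      names(regions) <- coord$target_id
    }
  }
  lib <- guide_library(df[setdiff(names(df), c("chrom", "start", "end"))], regions)
  if (!quiet) {
    tally <- library_class_tally(lib)
    message("read_library: ", nrow(lib$constructs), " constructs (",
            paste(sprintf("%s=%d", names(tally), tally), collapse = ", "), ")")
  }
  lib
}

#' Write a guide library to TSV (round-trips with [read_library])
#' @param library a \code{GuideLibrary}
#' @param path output TSV path
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "GuideLibrary"))
  df <- library$constructs
  if (!is.null(library$regions)) {
    r <- library$regions
    idx <- match(df$target_id, names(r))
    df$chrom <- ifelse(is.na(idx), "", as.character(GenomicRanges::seqnames(r))[idx])
    df$start <- ifelse(is.na(idx), "", GenomicRanges::start(r)[idx] - 1L)
    df$end <- ifelse(is.na(idx), "", GenomicRanges::end(r)[idx])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
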