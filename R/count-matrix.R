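#' Construct a screen count matrix
#'
#' Couples a nonnegative integer construct-by-sample count matrix with
#' per-sample metadata describing the screen design: each sample is either a
#' \code{reference} (plasmid pool / assay start) or an \code{endpoint}
#' (assay end / tumour), carries a replicate or tumour \code{unit_id}, an
#' optional \code{group_id} (e.g. left vs right mouse flank), and endpoint
#' samples name their reference via \code{reference_id}.
#'
#' @param counts integer matrix, rownames = construct ids, colnames = sample ids
#' @param samples data.frame with columns \code{sample_id}, \code{role}
#'   (\code{reference}/\code{endpoint}), \code{unit_id}, \code{group_id},
#'   \code{reference_id}
#' @return object of class \code{CountMatrix}
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    rs_abort("counts must be nonnegative integers")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max at high depth
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "role", "unit_id", "group_id", "reference_id")
  miss <- setdiff(req, names(samples))
  if (length(miss)) rs_abort("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id))
    rs_abort("sample metadata ids must match count matrix columns exactly")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad_role <- setdiff(unique(samples$role), c("reference", "endpoint"))
  if (length(bad_role)) rs_abort("unknown sample role: ", paste(bad_role, collapse = ", "))
  ep <- samples$role == "endpoint"
  refs <- samples$sample_id[samples$role == "reference"]
  unresolved <- ep & !(samples$reference_id %in% refs)
  if (any(unresolved))
    rs_abort("endpoint sample(s) with unresolvable reference: ",
             paste(samples$sample_id[unresolved], collapse = ", "))
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "constructs x", ncol(x$counts), "samples (",
      sum(x$samples$role == "reference"), "reference,",
      sum(x$samples$role == "endpoint"), "endpoint )\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a screen count table plus its sample-metadata sidecar
#'
#' The count TSV has a header row of sample ids and construct ids in the first
#' column. The sidecar TSV has columns \code{sample_id}, \code{role},
#' \code{unit_id}, \code{group_id}, \code{reference_id}. Constructs present in
#' \code{library} but absent from the file are zero-filled with a warning
#' (plasmid-library dropouts are expected in real screens); constructs in the
#' file but not in the library are an error.
#'
#' @param path count TSV
#' @param library \code{GuideLibrary} the counts must conform to
#' @param meta_path sample-metadata TSV sidecar
#' @return \code{CountMatrix} with one row per library construct, in library order
#' @export
read_count_table <- function(path, library, meta_path) {
  stopifnot(inherits(library, "GuideLibrary"))
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) rs_abort("count table needs a construct column plus >=1 sample")
  ids <- raw[[1]]
  unknown <- setdiff(ids, library$constructs$construct_id)
  if (length(unknown))
    rs_abort("count table contains construct(s) not in the library: ",
             paste(unknown, collapse = ", "))
  if (anyDuplicated(ids))
    rs_abort("duplicated construct rows in count table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- matrix(0, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(ids, names(raw)[-1]))
  for (j in seq_len(ncol(mat))) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) | num < 0 | num != round(num)
    if (any(bad)) {
      i <- which(bad)[1]
      rs_abort("non-integer or negative count at ", ids[i], ",", colnames(mat)[j],
               " (value '", col[i], "')", class = "regscreen_format_error")
    }
    mat[, j] <- num
  }
  absent <- setdiff(library$constructs$construct_id, ids)
  if (length(absent)) {
    warning(length(absent), " library construct(s) absent from count file, zero-filled: ",
            paste(head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ...", call. = FALSE)
    mat <- rbind(mat, matrix(0, nrow = length(absent), ncol = ncol(mat),
                             dimnames = list(absent, colnames(mat))))
  }
  mat <- mat[library$constructs$construct_id, , drop = FALSE]
  samples <- read.delim(meta_path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  samples$group_id[is.na(samples$group_id)] <- ""
  samples$reference_id[is.na(samples$reference_id)] <- ""
  count_matrix(mat, samples)
}

#' Write a count matrix and its sample-metadata sidecar (round-trips with
#' [read_count_table])
#' @param cm \code{CountMatrix}
#' @param path count TSV path
#' @param meta_path sample-metadata TSV path
#' @export
write_count_table <- function(cm, path, meta_path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(construct_id = rownames(cm$counts),
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
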