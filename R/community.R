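#' Construct a sample-by-OTU community matrix
#'
#' A community matrix holds non-negative abundances (sequence read counts,
#' stem counts, subplot frequencies ...) for each sample (row) and OTU or
#' species (column), together with the sampling hierarchy mapping each sample
#' to a plot and, optionally, a subplot code. All downstream diversity and
#' comparison functions consume this class.
#'
#' @param counts numeric matrix, samples in rows and OTUs in columns, with
#'   unique rownames (sample ids) and colnames (OTU ids). All values must be
#'   finite and non-negative, and every row must have a positive total:
#'   empty samples are rejected rather than silently dropped so the number of
#'   samples entering any analysis is always intentional.
#' @param marker method label for the matrix, e.g. `"16S"`, `"COI-spun"`,
#'   `"seedlings"`.
#' @param plots named character vector mapping every sample id to a plot id.
#'   Defaults to each sample being its own plot (a plot-level matrix).
#' @param subplots optional named character vector of subplot codes
#'   (conventionally letters A-P) for subplot-level matrices.
#'
#' @return An object of class `community_matrix`: a list with elements
#'   `counts`, `marker`, `plots`, `subplots`.
#' @seealso [read_community_matrix()], [pool_to_plots()],
#'   [partition_diversity()]
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
#'             dimnames = list(c("P1-A", "P1-B"), c("otu1", "otu2")))
#' community_matrix(m, marker = "16S",
#'                  plots = c("P1-A" = "P1", "P1-B" = "P1"),
#'                  subplots = c("P1-A" = "A", "P1-B" = "B"))
community_matrix <- function(counts, marker = "unknown", plots = NULL,
                             subplots = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample ids as rownames and OTU ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU ids", call. = FALSE)
  }
  if (ncol(counts) == 0L) {
    stop("community matrix has no OTUs", call. = FALSE)
  }
  if (any(!is.finite(counts))) {
    stop("non-finite abundance values", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    stop(sprintf("empty sample(s): %s",
                 paste(rownames(counts)[empty], collapse = ", ")),
         call. = FALSE)
  }
  ids <- rownames(counts)
  if (is.null(plots)) {
    plots <- stats::setNames(ids, ids)
  }
  if (!all(ids %in% names(plots))) {
    stop(sprintf("sample(s) without a plot assignment: %s",
                 paste(setdiff(ids, names(plots)), collapse = ", ")),
         call. = FALSE)
  }
  plots <- plots[ids]
  if (!is.null(subplots)) {
    if (!all(ids %in% names(subplots))) {
      stop("`subplots`, when given, must cover every sample id",
           call. = FALSE)
    }
    subplots <- subplots[ids]
  }
  structure(
    list(counts = counts, marker = as.character(marker), plots = plots,
         subplots = subplots),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix [%s]: %d samples x %d OTUs, total count %s\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat(sprintf("Plots: %d (%s)\n", length(unique(x$plots)),
              if (is.null(x$subplots)) "plot-level" else "subplot-level"))
  invisible(x)
}

#' @export
summary.community_matrix <- function(object, ...) {
  cat(sprintf("Community matrix [%s]\n", object$marker))
  cat(sprintf("  samples: %d in %d plots\n", nrow(object$counts),
              length(unique(object$plots))))
  cat(sprintf("  OTUs: %d (singletons: %d)\n", ncol(object$counts),
              sum(colSums(object$counts) == 1)))
  cat(sprintf("  per-sample totals: %s\n",
              paste(range(rowSums(object$counts)), collapse = " - ")))
  invisible(object)
}

# Parse sample labels into plot/subplot under a label pattern. "auto" parses
# ids of the form <plot>-<subplot> where possible and treats anything else as
# a plot-level id; an explicit regex (with exactly two capture groups) is
# strict, and a non-matching id is an error.
parse_sample_labels <- function(ids, label_pattern = "auto") {
  default_pat <- "^(.+)-([A-Za-z0-9]+)$"
  strict <- !identical(label_pattern, "auto")
  pat <- if (strict) label_pattern else default_pat
  m <- regmatches(ids, regexec(pat, ids))
  ok <- lengths(m) == 3L
  if (strict && !all(ok)) {
    stop(sprintf("sample id(s) not matching label pattern '%s': %s", pat,
                 paste(ids[!ok], collapse = ", ")),
         call. = FALSE)
  }
  plots <- ifelse(ok, vapply(m, function(g) if (length(g) == 3L) g[2L] else "",
                             character(1)), ids)
  subplots <- ifelse(ok, vapply(m, function(g) if (length(g) == 3L) g[3L] else "",
                                character(1)), NA_character_)
  list(plots = stats::setNames(plots, ids),
       subplots = if (all(is.na(subplots))) NULL else
         stats::setNames(subplots, ids))
}

#' Read a community matrix from CSV
#'
#' The expected dialect is UTF-8, comma-separated, a header row whose first
#' field is `sample_id` followed by OTU ids, one row per sample, numeric
#' cells, no quoting. This is the dialect written by
#' [write_community_matrix()], so write/read round-trips are cell-exact.
#'
#' @param path path to a CSV file.
#' @param marker method label; defaults to the file name without extension.
#' @param label_pattern `"auto"` (default) parses sample ids of the form
#'   `<plot>-<subplot>` (e.g. `"Plot4-K"`) and treats other ids as plot-level;
#'   alternatively a regular expression with exactly two capture groups
#'   (plot, subplot), in which case every sample id must match.
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path, marker = NULL,
                                  label_pattern = "auto") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("community matrix CSV needs a sample_id column plus >=1 OTU column",
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  cells <- df[, -1L, drop = FALSE]
  for (k in seq_along(cells)) {
    col <- cells[[k]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1L]
      stop(sprintf("non-numeric cell at sample '%s', OTU column '%s'",
                   ids[bad], names(cells)[k]),
           call. = FALSE)
    }
    if (any(col < 0, na.rm = TRUE)) {
      bad <- which(col < 0)[1L]
      stop(sprintf("negative cell at sample '%s', OTU column '%s'",
                   ids[bad], names(cells)[k]),
           call. = FALSE)
    }
  }
  counts <- as.matrix(cells)
  rownames(counts) <- ids
  lab <- parse_sample_labels(ids, label_pattern)
  community_matrix(counts,
                   marker = marker %||%
                     sub("\\.[^.]*$", "", basename(path)),
                   plots = lab$plots, subplots = lab$subplots)
}

#' Write a community matrix to CSV
#'
#' Writes the dialect documented in [read_community_matrix()]: header row
#' `sample_id,<otu ids...>`, one row per sample, integers without a decimal
#' point and non-integers at full double precision, so re-reading the file
#' reproduces the matrix bit-exactly.
#'
#' @param cm a [community_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "community_matrix"))
  ids <- c("sample_id", colnames(cm$counts), rownames(cm$counts))
  if (any(grepl("[,\"\n]", ids))) {
    stop("sample/OTU ids must not contain commas, quotes or newlines",
         call. = FALSE)
  }
  fmt <- function(x) {
    ifelse(x == round(x) & abs(x) < 2^53,
           sprintf("%.0f", x),
           vapply(x, function(v) formatC(v, digits = 17, format = "g"),
                  character(1)))
  }
  lines <- c(
    paste(c("sample_id", colnames(cm$counts)), collapse = ","),
    vapply(seq_len(nrow(cm$counts)), function(r) {
      paste(c(rownames(cm$counts)[r], fmt(cm$counts[r, ])), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a community matrix from an OTU-to-read mapping
#'
#' OTU clustering pipelines emit a mapping file associating each sequence
#' read with the OTU it was assigned to; the sample of origin (plot and
#' subplot) is embedded in the read label during deconvolution. This function
#' tallies the mapping into a community matrix: `counts[s, o]` is the number
#' of reads with label resolving to sample `s` assigned to OTU `o`.
#'
#' @param map data frame (or 2-column matrix) with columns `read_label` and
#'   `otu_id`, one row per read. A 2-column TSV of this shape can be read
#'   with `read.delim`.
#' @param read_pattern regular expression with one capture group extracting
#'   the sample id from a read label; the default strips a trailing
#'   `_<read-number>` suffix. Read labels that do not match are an error
#'   (listed in the message).
#' @param label_pattern passed to [parse_sample_labels] semantics as in
#'   [read_community_matrix()] to build the plot/subplot hierarchy.
#' @param marker method label.
#' @return a [community_matrix()] whose grand total equals `nrow(map)`.
#' @export
build_matrix_from_otu_map <- function(map, read_pattern = "^(.+)_[^_]+$",
                                      label_pattern = "auto",
                                      marker = "unknown") {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (ncol(map) < 2L || nrow(map) == 0L) {
    stop("`map` must be a non-empty table of (read_label, otu_id)",
         call. = FALSE)
  }
  reads <- as.character(map[[1L]])
  otus <- as.character(map[[2L]])
  m <- regmatches(reads, regexec(read_pattern, reads))
  ok <- lengths(m) == 2L
  if (!all(ok)) {
    stop(sprintf("read label(s) mapping to no sample: %s",
                 paste(unique(reads[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  samples <- vapply(m, `[`, character(1), 2L)
  counts <- table(factor(samples, levels = unique(samples)),
                  factor(otus, levels = unique(otus)))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  lab <- parse_sample_labels(rownames(counts), label_pattern)
  community_matrix(counts, marker = marker, plots = lab$plots,
                   subplots = lab$subplots)
}

#' Remove single-read OTUs
#'
#' Drops every OTU whose grand-total count is exactly 1. Single-read OTUs
#' are commonly treated as likely sequencing artifacts, and analyses are
#' often run in parallel with and without them. The operation is idempotent.
#'
#' @param cm a [community_matrix()] of read counts.
#' @return a [community_matrix()] without singleton OTUs. If removal would
#'   empty a sample this is an error (empty samples are never silently
#'   dropped).
#' @export
remove_singleton_otus <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  keep <- colSums(cm$counts) != 1
  if (all(keep)) {
    return(cm)
  }
  counts <- cm$counts[, keep, drop = FALSE]
  if (ncol(counts) == 0L) {
    stop("removing singleton OTUs left no OTUs", call. = FALSE)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    stop(sprintf("removing singleton OTUs emptied sample(s): %s",
                 paste(rownames(counts)[empty], collapse = ", ")),
         call. = FALSE)
  }
  community_matrix(counts, marker = cm$marker, plots = cm$plots,
                   subplots = cm$subplots)
}

#' Pool a subplot-level matrix to plot level
#'
#' Sums counts over the subplots of each plot, producing one row per plot.
#' Grand totals and per-OTU totals are conserved. Already plot-level
#' matrices are returned unchanged (up to the hierarchy becoming the
#' identity map).
#'
#' @param cm a [community_matrix()].
#' @return a plot-level [community_matrix()] with rows in order of first
#'   appearance of each plot.
#' @export
pool_to_plots <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  plot_levels <- unique(unname(cm$plots))
  counts <- rowsum(cm$counts, group = factor(cm$plots, levels = plot_levels),
                   reorder = FALSE)
  counts <- as.matrix(counts)
  rownames(counts) <- plot_levels
  community_matrix(counts, marker = cm$marker,
                   plots = stats::setNames(plot_levels, plot_levels))
}

#' Convert abundances to presence-absence
#'
#' `mode = "binary"` maps every positive count to 1 in place. `mode =
#' "subplot-frequency"` mirrors understorey-style vegetation scoring: the
#' result is a plot-level matrix whose cell is the number of subplots
#' (0-24) of that plot in which the species occurs; it requires a
#' subplot-level matrix with at most 24 subplots per plot.
#'
#' @param cm a [community_matrix()].
#' @param mode `"binary"` or `"subplot-frequency"`.
#' @return a [community_matrix()].
#' @export
to_presence_absence <- function(cm, mode = c("binary", "subplot-frequency")) {
  stopifnot(inherits(cm, "community_matrix"))
  mode <- match.arg(mode)
  if (mode == "binary") {
    counts <- (cm$counts > 0) * 1
    dimnames(counts) <- dimnames(cm$counts)
    return(community_matrix(counts, marker = cm$marker, plots = cm$plots,
                            subplots = cm$subplots))
  }
  if (is.null(cm$subplots)) {
    stop("subplot-frequency mode needs a subplot-level matrix", call. = FALSE)
  }
  per_plot <- table(cm$plots)
  if (any(per_plot > 24)) {
    stop(sprintf("plot(s) with more than 24 subplots: %s",
                 paste(names(per_plot)[per_plot > 24], collapse = ", ")),
         call. = FALSE)
  }
  binary <- (cm$counts > 0) * 1
  plot_levels <- unique(unname(cm$plots))
  counts <- rowsum(binary, group = factor(cm$plots, levels = plot_levels),
                   reorder = FALSE)
  counts <- as.matrix(counts)
  rownames(counts) <- plot_levels
  community_matrix(counts, marker = cm$marker,
                   plots = stats::setNames(plot_levels, plot_levels))
}
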