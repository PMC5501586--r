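# All internal coordinates are 0-based half-open; conversions to the disk
# dialects (SEG 1-based inclusive, BED-like 0-based half-open) happen only
# here.

#' Read / write bin-count tables
#'
#' Tab-delimited with header: `chrom`, `start`, `end`, `gc`, then one count
#' column per sample. The in-memory `mask` column is not serialised; freshly
#' read tables start fully usable.
#'
#' @param table Bin-count tibble.
#' @param path File path.
#' @return `read_bincounts()` returns a bin-count tibble (with `mask`
#'   initialised to `TRUE`); `write_bincounts()` returns `path` invisibly.
#' @export
write_bincounts <- function(table, path) {
  cols <- c("chrom", "start", "end", "gc", bin_samples(table))
  readr::write_tsv(table[cols], path)
  invisible(path)
}

#' @rdname write_bincounts
#' @export
read_bincounts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(tbl)))
  tbl$mask <- TRUE
  dplyr::relocate(tbl, "mask", .after = "gc")
}

#' Read a SEG segmentation file
#'
#' Tab-delimited with header (`Sample`, `Chromosome`, `Start`, `End`,
#' `Num_Probes`, `Segment_Mean`), 1-based inclusive coordinates on disk.
#' Values are converted to absolute copy numbers: for the conventional
#' log2-ratio dialect, `copies = 2 * 2^segment_mean`; `value_kind =
#' "copies"` takes the column at face value.
#'
#' @param path File path.
#' @param value_kind `"log2"` (default, TCGA-style segment means) or
#'   `"copies"`.
#' @param chr_prefix `"keep"` (default), `"strip"` or `"add"` — chromosome
#'   name normalisation on read.
#' @return Tibble `sample_id`, `chrom`, `start`, `end`, `num_probes`,
#'   `copies` (0-based half-open).
#' @export
read_seg <- function(path, value_kind = c("log2", "copies"),
                     chr_prefix = c("keep", "strip", "add")) {
  value_kind <- match.arg(value_kind)
  chr_prefix <- match.arg(chr_prefix)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 5) stop("SEG file needs at least 5 columns", call. = FALSE)
  names(raw)[1:5] <- c("sample_id", "chrom", "start", "end", "num_probes")
  val_col <- if (ncol(raw) >= 6) 6L else 5L
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  value <- suppressWarnings(as.numeric(raw[[val_col]]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    stop(sprintf("unparseable SEG rows at line(s): %s",
                 paste(bad + 1, collapse = ", ")), call. = FALSE)
  }
  if (any(end < start)) {
    stop(sprintf("SEG end < start at line(s): %s",
                 paste(which(end < start) + 1, collapse = ", ")), call. = FALSE)
  }
  chrom <- raw$chrom
  if (chr_prefix == "strip") chrom <- sub("^chr", "", chrom)
  if (chr_prefix == "add") chrom <- ifelse(grepl("^chr", chrom), chrom,
                                           paste0("chr", chrom))
  copies <- if (value_kind == "log2") 2 * 2^value else value
  if (any(copies < 0)) stop("negative copy number after conversion", call. = FALSE)
  tibble::tibble(
    sample_id = raw$sample_id, chrom = chrom,
    start = start - 1, end = end,
    num_probes = suppressWarnings(as.integer(raw$num_probes)),
    copies = copies
  )
}

#' Write segmentation records as SEG
#'
#' @param records Tibble `sample_id`, `chrom`, `start`, `end`, `copies`
#'   (0-based half-open); an optional `num_probes` column is carried
#'   through.
#' @param path File path.
#' @param value_kind `"log2"` writes `log2(copies / 2)` segment means (zero
#'   copies floored to -10); `"copies"` writes copies directly.
#' @return `path`, invisibly.
#' @export
write_seg <- function(records, path, value_kind = c("log2", "copies")) {
  value_kind <- match.arg(value_kind)
  value <- if (value_kind == "log2") {
    pmax(log2(pmax(records$copies, 1e-3) / 2), -10)
  } else {
    records$copies
  }
  out <- tibble::tibble(
    Sample = records$sample_id,
    Chromosome = records$chrom,
    Start = records$start + 1,
    End = records$end,
    Num_Probes = if ("num_probes" %in% names(records)) records$num_probes
                 else pmax(1L, as.integer(round((records$end - records$start) / 1e4))),
    Segment_Mean = value
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write a germline allele-frequency resource
#'
#' BED-like, tab-delimited, no header: `chrom`, `start`, `end`, `af`
#' (0-based half-open on disk, as in BED).
#'
#' @param resource Tibble `chrom`, `start`, `end`, `af`.
#' @param path File path.
#' @return `read_germline()` returns the resource tibble;
#'   `write_germline()` returns `path` invisibly.
#' @export
write_germline <- function(resource, path) {
  readr::write_tsv(resource[c("chrom", "start", "end", "af")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_germline
#' @export
read_germline <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "af"),
                  show_col_types = FALSE)
}

#' Serialise / restore a fitted count model as JSON
#'
#' @param model An `nb_fit` object.
#' @param path File path.
#' @return `read_model_json()` returns an `nb_fit`; `write_model_json()`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nb_fit"))
  jsonlite::write_json(
    list(m = model$m, r = model$r, bin_size = model$bin_size,
         read_length = model$read_length, depth = model$depth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nb_model(m = x$m, r = x$r, bin_size = x$bin_size, read_length = x$read_length)
}

#' Write copy profiles as plot-ready matrices
#'
#' Two TSV matrices (samples x segments): five-level categories and average
#' copy deviations.
#'
#' @param profiles A `copy_profiles` tibble.
#' @param path_category,path_avgdev Output paths.
#' @return Invisibly, the two paths.
#' @export
write_profiles <- function(profiles, path_category, path_avgdev) {
  cat_wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "sample_id", "segment_id", "category"),
    names_from = "segment_id", values_from = "category")
  dev_wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "sample_id", "segment_id", "avg_dev"),
    names_from = "segment_id", values_from = "avg_dev")
  readr::write_tsv(cat_wide, path_category)
  readr::write_tsv(dev_wide, path_avgdev)
  invisible(c(path_category, path_avgdev))
}
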