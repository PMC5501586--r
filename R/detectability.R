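# The five-level copy-state alphabet, in increasing copy order.
CATEGORY_LEVELS <- c("DEL2", "DEL1", "NEUTRAL", "AMP1", "AMP2PLUS")
CATEGORY_CODES <- setNames(-2:2, CATEGORY_LEVELS)

#' Category alphabet for discretised copy profiles
#'
#' @return Character vector `DEL2 < DEL1 < NEUTRAL < AMP1 < AMP2PLUS`.
#' @export
category_levels <- function() CATEGORY_LEVELS

#' Remove common germline CNVs from segmentation records
#'
#' Records that reciprocally overlap (by at least `reciprocal_overlap` of
#' both intervals) a population-resource interval with allele frequency
#' above `af_threshold` are treated as germline polymorphisms and removed,
#' so only somatic (tumor-derived) events feed the detectability profiles.
#'
#' @param records Segmentation tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `copies`; 0-based half-open).
#' @param af_resource Tibble `chrom`, `start`, `end`, `af` (see
#'   [sim_germline_af()] / [read_germline()]).
#' @param af_threshold Allele frequency above which a resource interval
#'   flags germline events (default 0.01, i.e. >1%).
#' @param reciprocal_overlap Minimum reciprocal overlap fraction (default
#'   0.5).
#' @return The records tibble with germline-matching rows removed.
#' @export
filter_germline <- function(records, af_resource, af_threshold = 0.01,
                            reciprocal_overlap = 0.5) {
  if (nrow(records) == 0 || nrow(af_resource) == 0) return(records)
  if (any(records$end <= records$start) ||
      any(af_resource$end <= af_resource$start)) {
    stop("malformed intervals: end must exceed start", call. = FALSE)
  }
  res <- af_resource[af_resource$af > af_threshold, , drop = FALSE]
  if (nrow(res) == 0) return(records)
  hits <- GenomicRanges::findOverlaps(as_granges0(records), as_granges0(res))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(records$end[qi], res$end[si]) - pmax(records$start[qi], res$start[si])
  wq <- records$end[qi] - records$start[qi]
  ws <- res$end[si] - res$start[si]
  germ <- unique(qi[ov >= reciprocal_overlap * wq & ov >= reciprocal_overlap * ws])
  if (length(germ)) records[-germ, , drop = FALSE] else records
}

# Resolve overlapping records within one sample: later records take
# precedence (earlier ones are trimmed against them), with a warning.
resolve_record_overlaps <- function(records) {
  if (nrow(records) <= 1) return(records)
  out <- vector("list", 0)
  warned <- FALSE
  for (ch in unique(records$chrom)) {
    rc <- records[records$chrom == ch, , drop = FALSE]
    kept <- IRanges::IRanges()
    pieces <- vector("list", nrow(rc))
    for (i in rev(seq_len(nrow(rc)))) {
      ir <- IRanges::IRanges(rc$start[i] + 1, rc$end[i])
      free <- IRanges::setdiff(ir, kept)
      if (sum(IRanges::width(free)) < IRanges::width(ir)) warned <- TRUE
      if (length(free)) {
        pieces[[i]] <- tibble::tibble(
          sample_id = rc$sample_id[i], chrom = ch,
          start = IRanges::start(free) - 1, end = IRanges::end(free),
          copies = rc$copies[i])
      }
      kept <- IRanges::union(kept, ir)
    }
    out <- c(out, pieces)
  }
  if (warned) warning("overlapping records within a sample; later records take precedence")
  dplyr::bind_rows(out)
}

#' Average copy deviation of one sample over a genome grid
#'
#' For each grid segment, the length-weighted average deviation from the
#' diploid state: `sum over record-segment intersections of
#' (copies - 2) * overlap / segment_length`; uncovered basepairs contribute
#' zero deviation. Overlapping records are resolved with later-record
#' precedence (warning).
#'
#' @param records Segmentation records of a single sample.
#' @param grid Genome grid from [genome_grid()].
#' @return Numeric vector of average copy deviations, one per grid segment
#'   (in `grid` order).
#' @examples
#' g <- genome_grid(c(chrA = 5e6), 5e6)
#' r <- tibble::tibble(sample_id = "s", chrom = "chrA",
#'                     start = 0, end = 1e6, copies = 7)
#' segment_average_copy(r, g)  # 1 Mb at +5 in a 5 Mb segment -> +1
#' @export
segment_average_copy <- function(records, grid) {
  dev <- numeric(nrow(grid))
  if (nrow(records) == 0) return(dev)
  if (length(unique(records$sample_id)) > 1) {
    stop("segment_average_copy expects records of a single sample", call. = FALSE)
  }
  chrom_ends <- tapply(grid$end, grid$chrom, max)
  bad <- !(records$chrom %in% names(chrom_ends)) |
    records$end > chrom_ends[records$chrom] | records$start < 0
  if (any(bad)) stop("record beyond chromosome end (or unknown chromosome)", call. = FALSE)
  records <- resolve_record_overlaps(records)
  hits <- GenomicRanges::findOverlaps(as_granges0(records), as_granges0(grid))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(records$end[qi], grid$end[si]) - pmax(records$start[qi], grid$start[si])
  contrib <- (records$copies[qi] - 2) * ov / (grid$end[si] - grid$start[si])
  add <- tapply(contrib, si, sum)
  dev[as.integer(names(add))] <- as.numeric(add)
  dev
}

#' Flag ctDNA-detectable grid segments
#'
#' A segment is considered detectable when its average copy deviation
#' reaches at least one full copy (`|avg_dev| >= threshold`); e.g. a 5 Mb
#' segment with a 1 Mb, +5-copy subsection (average +1) or fully spanned by
#' a single-copy gain. The rule is applied symmetrically to losses.
#'
#' @param avg_dev Numeric vector of average copy deviations.
#' @param threshold Detectability threshold in average copies (default 1).
#' @return Logical vector.
#' @export
flag_detectable <- function(avg_dev, threshold = 1.0) {
  abs(avg_dev) >= threshold
}

#' Discretise average copy deviations to the five-level alphabet
#'
#' Symbolic-aggregate-approximation-style reduction to cardinality 5 with
#' copy-count-semantic breakpoints (nearest integer copy state):
#' `(-Inf,-1.5] -> DEL2`, `(-1.5,-0.5] -> DEL1`, `(-0.5,0.5) -> NEUTRAL`,
#' `[0.5,1.5) -> AMP1`, `[1.5,Inf) -> AMP2PLUS`.
#'
#' @param avg_dev Numeric vector.
#' @return Ordered factor with levels [category_levels()].
#' @export
sax_discretize <- function(avg_dev) {
  out <- rep("NEUTRAL", length(avg_dev))
  out[avg_dev <= -0.5] <- "DEL1"
  out[avg_dev <= -1.5] <- "DEL2"
  out[avg_dev >= 0.5] <- "AMP1"
  out[avg_dev >= 1.5] <- "AMP2PLUS"
  factor(out, levels = CATEGORY_LEVELS, ordered = TRUE)
}

#' Build ctDNA-detectable copy profiles for a cohort
#'
#' Runs the full conversion for every sample: optional germline filtering,
#' grid averaging, detectability flagging and five-level discretisation.
#'
#' @param records Segmentation tibble covering all samples.
#' @param grid Genome grid from [genome_grid()].
#' @param af_resource Optional germline AF resource for [filter_germline()].
#' @param detect_threshold Passed to [flag_detectable()].
#' @param af_threshold,reciprocal_overlap Passed to [filter_germline()].
#' @param sample_ids Optional character vector forcing the sample universe
#'   (samples without records get flat profiles).
#' @return Tibble of class `copy_profiles`: `sample_id`, `segment_id`,
#'   `avg_dev`, `category`, `detectable`; the grid is attached as attribute
#'   `"grid"`.
#' @export
build_copy_profiles <- function(records, grid, af_resource = NULL,
                                detect_threshold = 1.0, af_threshold = 0.01,
                                reciprocal_overlap = 0.5, sample_ids = NULL) {
  if (!is.null(af_resource)) {
    records <- filter_germline(records, af_resource,
                               af_threshold = af_threshold,
                               reciprocal_overlap = reciprocal_overlap)
  }
  ids <- sample_ids %||% unique(records$sample_id)
  out <- purrr::map(ids, function(sid) {
    dev <- segment_average_copy(records[records$sample_id == sid, , drop = FALSE],
                                grid)
    tibble::tibble(
      sample_id = sid, segment_id = grid$segment_id, avg_dev = dev,
      category = sax_discretize(dev),
      detectable = flag_detectable(dev, detect_threshold)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "grid") <- grid
  class(out) <- c("copy_profiles", class(out))
  out
}

#' Wide matrix view of copy profiles
#'
#' @param profiles A `copy_profiles` tibble.
#' @param what `"code"` (integer copy-state codes -2..2), `"avg_dev"`, or
#'   `"detectable"`.
#' @return Matrix samples x segments (rownames sample ids, colnames segment
#'   ids).
#' @export
profile_matrix <- function(profiles, what = c("code", "avg_dev", "detectable")) {
  what <- match.arg(what)
  val <- switch(what,
    code = CATEGORY_CODES[as.character(profiles$category)],
    avg_dev = profiles$avg_dev,
    detectable = profiles$detectable)
  ids <- unique(profiles$sample_id)
  segs <- sort(unique(profiles$segment_id))
  m <- matrix(val[order(match(profiles$sample_id, ids),
                        match(profiles$segment_id, segs))],
              nrow = length(ids), ncol = length(segs), byrow = TRUE,
              dimnames = list(ids, segs))
  m
}

#' Fraction of samples per cancer type with detectable CNV events
#'
#' @param profiles A `copy_profiles` tibble.
#' @param labels Tibble `sample_id`, `type` covering all profiled samples.
#' @param min_events Minimum number of detectable segments a sample must
#'   show (1 or 2 in the screening scenarios).
#' @param segments Optional segment-id subset to restrict the count to
#'   (e.g. random-forest-important segments); `NULL` means all segments; an
#'   empty vector yields all-zero fractions.
#' @return Tibble `type`, `n`, `n_detected`, `fraction`.
#' @export
cohort_detectable_fraction <- function(profiles, labels, min_events = 1,
                                       segments = NULL) {
  if (!all(unique(profiles$sample_id) %in% labels$sample_id)) {
    stop("labels must cover every profiled sample", call. = FALSE)
  }
  x <- profiles
  if (!is.null(segments)) x <- x[x$segment_id %in% segments, , drop = FALSE]
  per_sample <- dplyr::summarise(
    dplyr::group_by(x, .data$sample_id),
    n_detectable = sum(.data$detectable), .groups = "drop")
  per_sample <- dplyr::left_join(
    tibble::tibble(sample_id = unique(profiles$sample_id)),
    per_sample, by = "sample_id")
  per_sample$n_detectable[is.na(per_sample$n_detectable)] <- 0L
  per_sample <- dplyr::left_join(per_sample, labels, by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(per_sample, .data$type),
    n = dplyr::n(),
    n_detected = sum(.data$n_detectable >= min_events),
    fraction = .data$n_detected / .data$n,
    .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
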