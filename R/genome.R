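#' Synthetic genome used by the simulators
#'
#' The package works on an abstract linear genome: a set of named
#' pseudo-chromosomes with stated lengths. No real reference genome is
#' required; every coordinate in the package is 0-based half-open.
#' The default genome has eight pseudo-chromosomes totalling 1.7 Gb, each a
#' multiple of the 10 kb bin size, so 5 Mb grids tile exactly while 100 Mb
#' grids exercise trailing partial segments.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @examples
#' default_chrom_sizes()
#' @export
default_chrom_sizes <- function() {
  c(
    pc1 = 300e6, pc2 = 280e6, pc3 = 250e6, pc4 = 220e6,
    pc5 = 200e6, pc6 = 180e6, pc7 = 150e6, pc8 = 120e6
  )
}

#' Tile a genome into fixed-width segments
#'
#' Builds the coarse genome grid (nominally 5 Mb or 100 Mb) on which
#' ctDNA-detectable copy profiles are computed. Segments tile each chromosome
#' without gaps or overlaps; the trailing segment of a chromosome may be
#' shorter than `segment_size` and is averaged over its true length
#' downstream.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param segment_size Segment width in bp (e.g. `5e6` or `100e6`).
#' @return A tibble with columns `segment_id` (integer, genomic order),
#'   `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' genome_grid(c(chrA = 12e6), 5e6)
#' @export
genome_grid <- function(chrom_sizes = default_chrom_sizes(), segment_size = 5e6) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
            all(chrom_sizes > 0), segment_size > 0)
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector", call. = FALSE)
  }
  pieces <- purrr::map2(names(chrom_sizes), unname(chrom_sizes), function(ch, len) {
    starts <- seq(0, len - 1, by = segment_size)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + segment_size, len))
  })
  out <- dplyr::bind_rows(pieces)
  out$segment_id <- seq_len(nrow(out))
  dplyr::select(out, "segment_id", "chrom", "start", "end")
}

# GRanges view of interval tibbles (internal; converts half-open to 1-based).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}
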