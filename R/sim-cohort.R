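#' Define a cancer type's recurrent CNV signature
#'
#' A signature lists recurrent copy-number events on a genome grid: each
#' event hits one grid segment with some probability and, when it occurs,
#' draws a signed copy change from a small distribution over
#' `{-2, -1, +1, +2, +3, ...}`. A `passenger_rate` adds Poisson-many random
#' extra events per sample, and `flatness` scales all event probabilities so
#' CNV-poor types (flat profiles, hard to detect) can be emulated.
#'
#' @param type_name Unique label for the cancer type.
#' @param events Tibble/data frame with columns `segment` (grid segment id),
#'   `prob` (event probability in \[0, 1\]) and `delta` (either a single
#'   signed copy change per row or a list-column of candidate changes,
#'   sampled uniformly). `NULL` means no recurrent events (e.g. "normal").
#' @param passenger_rate Expected number of random passenger events per
#'   sample (>= 0); passengers pick a uniform random segment and a copy
#'   change from `{-2, -1, +1, +2}`.
#' @param flatness Multiplier applied to all event probabilities (>= 0).
#' @return A list of class `cancer_signature`.
#' @examples
#' cancer_signature("typeA", data.frame(segment = c(3, 9), prob = 1, delta = 2))
#' @export
cancer_signature <- function(type_name, events = NULL, passenger_rate = 0,
                             flatness = 1) {
  stopifnot(is.character(type_name), length(type_name) == 1, nzchar(type_name))
  if (passenger_rate < 0) stop("passenger_rate must be >= 0", call. = FALSE)
  if (flatness < 0) stop("flatness must be >= 0", call. = FALSE)
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("segment", "prob", "delta") %in% names(events)))
    if (any(events$prob < 0 | events$prob > 1)) {
      stop("event probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (!is.list(events$delta)) events$delta <- as.list(events$delta)
    if (any(vapply(events$delta, function(d) any(2 + d < 0), logical(1)))) {
      stop("copy deltas must keep total copies >= 0", call. = FALSE)
    }
  }
  structure(list(type_name = type_name, events = events,
                 passenger_rate = passenger_rate, flatness = flatness),
            class = "cancer_signature")
}

#' Disjoint probability-1 signatures for a separable test cohort
#'
#' Convenience constructor for parameter-recovery experiments: each type gets
#' `events_per_type` dedicated grid segments (disjoint across types, spread
#' evenly along the genome) that are always altered by `delta` copies, so
#' types are perfectly separable by their copy profiles.
#'
#' @param type_names Character vector of type labels.
#' @param grid Genome grid from [genome_grid()].
#' @param events_per_type Signature segments per type.
#' @param delta Copy change applied at each signature segment.
#' @param passenger_rate Passed to [cancer_signature()].
#' @return Named list of `cancer_signature` objects.
#' @export
separable_signatures <- function(type_names, grid, events_per_type = 2,
                                 delta = 2, passenger_rate = 0) {
  need <- length(type_names) * events_per_type
  if (need > nrow(grid)) stop("grid too small for the requested signatures", call. = FALSE)
  segs <- round(seq(1, nrow(grid), length.out = need))
  segs <- unique(segs)
  if (length(segs) < need) segs <- seq_len(need)  # dense small grids
  sig <- purrr::imap(setNames(type_names, type_names), function(nm, i) {
    k <- match(nm, type_names)
    mine <- segs[seq((k - 1) * events_per_type + 1, k * events_per_type)]
    cancer_signature(nm, tibble::tibble(segment = mine, prob = 1, delta = delta),
                     passenger_rate = passenger_rate)
  })
  sig
}

#' Simulate a tumor segmentation cohort with type-specific CNV signatures
#'
#' Emulates per-type tumor copy-number segmentation data: for each sample of
#' a type, every recurrent event in the type's signature occurs independently
#' (Bernoulli at its probability times `flatness`) and emits one segmentation
#' record spanning the whole grid segment at `2 + delta` copies; Poisson-many
#' passenger events add records at random segments. A signature with no
#' events yields a flat (record-free) profile — use it as the "normal" class.
#'
#' @param signatures List of [cancer_signature()] objects.
#' @param n_per_type Named integer vector of samples per type; names must
#'   match the signatures' `type_name`s.
#' @param grid Genome grid from [genome_grid()].
#' @param seed Optional integer seed.
#' @return List with `records` (tibble `sample_id`, `chrom`, `start`, `end`,
#'   `copies`) and `labels` (tibble `sample_id`, `type`).
#' @examples
#' g <- genome_grid(c(chrA = 50e6), 5e6)
#' sig <- list(cancer_signature("A", data.frame(segment = 7, prob = 1, delta = 2)),
#'             cancer_signature("normal"))
#' coh <- sim_tumor_cohort(sig, c(A = 3, normal = 2), g, seed = 1)
#' @export
sim_tumor_cohort <- function(signatures, n_per_type, grid, seed = NULL) {
  sig_names <- vapply(signatures, function(s) s$type_name, character(1))
  if (anyDuplicated(sig_names)) stop("type_name must be unique", call. = FALSE)
  if (is.null(names(n_per_type)) || !all(names(n_per_type) %in% sig_names)) {
    stop("n_per_type must be named with known type_names", call. = FALSE)
  }
  for (s in signatures) {
    if (!is.null(s$events) && any(!(s$events$segment %in% grid$segment_id))) {
      stop("signature refers to a segment absent from the grid", call. = FALSE)
    }
  }
  names(signatures) <- sig_names
  run <- function() {
    recs <- list()
    labs <- list()
    for (ty in names(n_per_type)) {
      s <- signatures[[ty]]
      for (i in seq_len(n_per_type[[ty]])) {
        sid <- sprintf("%s_%03d", ty, i)
        labs[[sid]] <- tibble::tibble(sample_id = sid, type = ty)
        ev <- tibble::tibble(segment = integer(), delta = numeric())
        if (!is.null(s$events) && nrow(s$events) > 0) {
          p <- pmin(1, s$events$prob * s$flatness)
          hit <- runif(nrow(s$events)) < p
          if (any(hit)) {
            delta <- vapply(s$events$delta[hit], function(d) {
              if (length(d) == 1) d else sample(d, 1)
            }, numeric(1))
            ev <- dplyr::bind_rows(ev, tibble::tibble(
              segment = s$events$segment[hit], delta = delta))
          }
        }
        n_pass <- if (s$passenger_rate > 0) rpois(1, s$passenger_rate) else 0L
        if (n_pass > 0) {
          ev <- dplyr::bind_rows(ev, tibble::tibble(
            segment = sample(grid$segment_id, n_pass, replace = TRUE),
            delta = sample(c(-2, -1, 1, 2), n_pass, replace = TRUE)))
        }
        if (nrow(ev) > 0) {
          gseg <- grid[match(ev$segment, grid$segment_id), ]
          recs[[sid]] <- tibble::tibble(
            sample_id = sid, chrom = gseg$chrom, start = gseg$start,
            end = gseg$end, copies = 2 + ev$delta)
        }
      }
    }
    list(records = dplyr::bind_rows(recs), labels = dplyr::bind_rows(labs))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a germline CNV population-frequency resource
#'
#' Emits random intervals with population allele frequencies, standing in
#' for a germline CNV frequency catalogue (1000 Genomes-style). Records with
#' AF above the screening threshold (conventionally 1%) are the ones the
#' germline filter should remove.
#'
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param n_events Number of intervals to generate.
#' @param af_range Length-2 allele-frequency range within \[0, 1\].
#' @param width_range Length-2 interval width range in bp.
#' @param seed Optional integer seed.
#' @return Tibble `chrom`, `start`, `end`, `af` (0-based half-open), sorted
#'   by position.
#' @export
sim_germline_af <- function(chrom_sizes = default_chrom_sizes(), n_events = 100,
                            af_range = c(0, 0.2), width_range = c(1e4, 1e6),
                            seed = NULL) {
  stopifnot(length(af_range) == 2, all(af_range >= 0), all(af_range <= 1),
            length(chrom_sizes) >= 1)
  if (n_events == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), af = numeric()))
  }
  run <- function() {
    ch <- sample(names(chrom_sizes), n_events, replace = TRUE,
                 prob = chrom_sizes / sum(chrom_sizes))
    w <- runif(n_events, width_range[1], width_range[2])
    start <- floor(runif(n_events, 0, pmax(1, chrom_sizes[ch] - w)))
    out <- tibble::tibble(
      chrom = ch, start = start, end = floor(start + w),
      af = runif(n_events, af_range[1], af_range[2]))
    dplyr::arrange(out, .data$chrom, .data$start)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
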