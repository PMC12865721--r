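# Windowed depth computation, depth normalisation, and SDR calling from the
# female/male depth ratio.

#' Depth track constructor
#'
#' A tiling of one or more chromosomes with the mean per-base depth of one
#' pool per window (0-based half-open windows, sorted, non-overlapping).
#'
#' @param chrom,start,end,depth Parallel vectors.
#' @param sample_label Pool identifier.
#' @return A `depth_track` data.frame.
#' @export
depth_track <- function(chrom, start, end, depth, sample_label = "pool") {
  chrom <- rep_len(chrom, length(start))
  stopifnot(length(start) == length(end), length(end) == length(depth))
  if (any(depth < 0)) stop("depth must be >= 0")
  if (any(end <= start)) stop("windows must have end > start")
  df <- data.frame(chrom = chrom, start = as.numeric(start),
                   end = as.numeric(end), depth = as.numeric(depth),
                   sample = sample_label, stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, ]
    if (is.unsorted(w$start, strictly = TRUE) ||
        any(w$start[-1] < w$end[-nrow(w)]))
      stop("windows on ", ch, " must be sorted and non-overlapping")
  }
  class(df) <- c("depth_track", "data.frame")
  df
}

#' Windowed mean depth from a per-base depth source
#'
#' Accepts an in-memory per-base table (`chrom`, `pos` 1-based, `depth`), a
#' TSV path with those three columns, or a BAM path (depth is extracted per
#' position via pileup with a mapping-quality filter). Bases absent from the
#' source count as depth 0.
#'
#' @param depth_source Data frame, TSV path, or BAM path.
#' @param window Window size in bp (>= 100).
#' @param chrom_lengths Named vector; windows tile each chromosome. When
#'   `NULL`, lengths default to the largest observed position.
#' @param sample_label Pool identifier for the track.
#' @param min_mapq Mapping-quality cutoff used for BAM input (default 20).
#' @return A [depth_track()].
#' @export
compute_windowed_depth <- function(depth_source, window = 10000,
                                   chrom_lengths = NULL,
                                   sample_label = "pool", min_mapq = 20) {
  if (window < 100) stop("window must be >= 100 bp")
  if (is.character(depth_source) && length(depth_source) == 1L) {
    if (grepl("\\.bam$", depth_source, ignore.case = TRUE)) {
      p <- Rsamtools::pileup(
        depth_source,
        pileupParam = Rsamtools::PileupParam(
          min_mapq = min_mapq, min_base_quality = 0L,
          max_depth = 100000L, distinguish_strands = FALSE,
          distinguish_nucleotides = FALSE))
      depth_source <- data.frame(chrom = as.character(p$seqnames),
                                 pos = p$pos, depth = p$count,
                                 stringsAsFactors = FALSE)
    } else {
      depth_source <- data.table::fread(depth_source)  # header auto-detected
      if (ncol(depth_source) != 3L)
        stop("per-base depth TSV must have columns: chrom, pos, depth")
      data.table::setnames(depth_source, c("chrom", "pos", "depth"))
    }
  }
  df <- as.data.frame(depth_source)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(df)))
  if (!nrow(df)) stop("depth source is empty")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(df$pos, df$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  } else {
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown))
      stop("unknown chromosome(s) in depth source: ",
           paste(unknown, collapse = ", "))
  }
  grid <- window_grid(chrom_lengths, window)
  akey <- paste(df$chrom, (df$pos - 1) %/% window)
  agg <- rowsum(df$depth, akey)
  key <- paste(grid$chrom, grid$start %/% window)
  tot <- stats::setNames(rep(0, nrow(grid)), key)
  hit <- rownames(agg) %in% key
  tot[rownames(agg)[hit]] <- agg[hit, 1]
  depth_track(grid$chrom, grid$start, grid$end,
              unname(tot) / (grid$end - grid$start), sample_label)
}

#' Normalize a depth track by its autosomal median
#'
#' Divides every window depth by the median depth over autosomal windows, so
#' pools of unequal sequencing effort become comparable (normalized
#' autosomal median = 1).
#'
#' @param track A [depth_track()].
#' @param autosome_names Chromosome names treated as autosomes.
#' @return The normalized [depth_track()].
#' @export
normalize_track <- function(track, autosome_names) {
  stopifnot(inherits(track, "depth_track"))
  if (!length(autosome_names)) stop("autosome_names must be non-empty")
  auto <- track$depth[track$chrom %in% autosome_names]
  if (!length(auto)) stop("no windows on the given autosomes")
  med <- stats::median(auto)
  if (med == 0) stop("autosomal median depth is zero; cannot normalize")
  track$depth <- track$depth / med
  track
}

# maximal runs of candidate windows allowing interior gaps <= max_gap
candidate_runs <- function(cand, max_gap) {
  idx <- which(cand)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  brk <- which(diff(idx) > max_gap + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  cbind(starts, ends)
}

#' Call the sex-determining region from paired normalized depth tracks
#'
#' Per window, the ratio `r = female / max(male, floor)` is computed; windows
#' with `r < ratio_threshold` are SDR candidates. Maximal candidate runs
#' tolerating up to `max_gap_windows` interior non-candidate windows are
#' merged, and runs spanning fewer than `min_windows` windows are discarded.
#'
#' @param female,male Normalized [depth_track()]s on the same window grid.
#' @param ratio_threshold Candidate cutoff on the female/male ratio.
#' @param min_windows Minimum windows spanned by a reported call.
#' @param max_gap_windows Interior non-candidate windows tolerated per run.
#' @param male_floor Denominator floor (normalized units) preventing division
#'   by zero.
#' @return Data frame of calls: `chrom`, `start`, `end` (0-based half-open),
#'   `n_windows`, `mean_ratio`, `male_relative_depth`.
#' @export
call_sdr <- function(female, male, ratio_threshold = 0.3, min_windows = 5,
                     max_gap_windows = 2, male_floor = 0.05) {
  stopifnot(inherits(female, "depth_track"), inherits(male, "depth_track"))
  if (nrow(female) != nrow(male) ||
      any(female$chrom != male$chrom) || any(female$start != male$start) ||
      any(female$end != male$end))
    stop("female and male tracks are on different window grids")
  calls <- list()
  for (ch in unique(female$chrom)) {
    f <- female[female$chrom == ch, ]
    m <- male[male$chrom == ch, ]
    r <- f$depth / pmax(m$depth, male_floor)
    runs <- candidate_runs(r < ratio_threshold, max_gap_windows)
    for (k in seq_len(nrow(runs))) {
      i <- runs[k, 1]:runs[k, 2]
      if (length(i) < min_windows) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, start = f$start[runs[k, 1]], end = f$end[runs[k, 2]],
        n_windows = length(i), mean_ratio = mean(r[i]),
        male_relative_depth = mean(m$depth[i]), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_ratio = numeric(0),
                      male_relative_depth = numeric(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
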