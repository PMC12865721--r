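# Repeat-density summarisation over a window grid from a classified repeat
# annotation (BED intervals with class labels).

REPEAT_CLASSES <- c("LTR/Gypsy", "LTR/Copia", "LINE", "DNA", "other")

# bucket free-text repeat labels into the reported classes
repeat_class_bucket <- function(labels) {
  out <- rep("other", length(labels))
  out[grepl("^LTR/Gypsy", labels, ignore.case = TRUE)] <- "LTR/Gypsy"
  out[grepl("^LTR/Copia", labels, ignore.case = TRUE)] <- "LTR/Copia"
  out[grepl("^LINE", labels, ignore.case = TRUE)] <- "LINE"
  out[grepl("^DNA", labels, ignore.case = TRUE)] <- "DNA"
  out
}

# BED6 (or BED4) reader with per-line validation
read_repeat_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 4L)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": bad coordinates")
  data.frame(chrom = chrom, start = start, end = end,
             class = vapply(fields, `[[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Per-window repeat coverage fractions by repeat class
#'
#' For every window and repeat class, reports the fraction of the window
#' covered by the union of that class's intervals (overlaps within a class
#' never count twice); `total` is the union across all classes.
#'
#' @param repeats BED path or data.frame (`chrom`, `start`, `end` 0-based
#'   half-open, `class`). Labels are bucketed into LTR/Gypsy, LTR/Copia,
#'   LINE, DNA and other.
#' @param windows A [depth_track()] or any data.frame with `chrom`, `start`,
#'   `end` defining the window grid.
#' @return Data frame with one row per window and one fraction column per
#'   class plus `total`.
#' @export
summarize_repeat_density <- function(repeats, windows) {
  if (is.character(repeats)) repeats <- read_repeat_bed(repeats)
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(repeats)))
  repeats$bucket <- repeat_class_bucket(repeats$class)
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$end))
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, stringsAsFactors = FALSE)
  covered_frac <- function(sub) {
    if (!nrow(sub)) return(rep(0, length(win_gr)))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1, sub$end)))
    hits <- GenomicRanges::findOverlaps(win_gr, gr)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(win_gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gr)[S4Vectors::subjectHits(hits)]))
    frac <- rep(0, length(win_gr))
    add <- tapply(ov, S4Vectors::queryHits(hits), sum)
    frac[as.integer(names(add))] <- as.numeric(add)
    frac / (windows$end - windows$start)
  }
  for (cls in setdiff(REPEAT_CLASSES, "other"))
    out[[cls]] <- covered_frac(repeats[repeats$bucket == cls, , drop = FALSE])
  out[["other"]] <- covered_frac(repeats[repeats$bucket == "other", , drop = FALSE])
  out[["total"]] <- covered_frac(repeats)
  out
}
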