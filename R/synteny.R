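# Anchor ranking along X and Y, inverted-block detection, breakpoints and
# displaced-pair counting.

#' Rank gametolog anchors along X and Y
#'
#' Sorts pairs by X midpoint to assign `x_rank` and by Y midpoint for
#' `y_rank`; ties break by gene id.
#'
#' @param pairs Data frame with `x_mid`, `y_mid` and optionally `anchor_id`
#'   (or `x_id`).
#' @return Anchor data.frame in X order with `anchor_id`, `x_rank`,
#'   `y_rank`, `x_mid`, `y_mid`.
#' @export
rank_anchors <- function(pairs) {
  stopifnot(all(c("x_mid", "y_mid") %in% names(pairs)))
  id <- pairs$anchor_id %||% pairs$x_id %||%
    sprintf("anchor%03d", seq_len(nrow(pairs)))
  if (any(duplicated(paste(pairs$x_mid, id))))
    stop("duplicate coordinates with duplicate ids")
  ox <- order(pairs$x_mid, id)
  out <- data.frame(anchor_id = id[ox], x_mid = pairs$x_mid[ox],
                    y_mid = pairs$y_mid[ox], stringsAsFactors = FALSE)
  out$x_rank <- seq_len(nrow(out))
  out$y_rank <- rank(out$y_mid, ties.method = "first")
  out[, c("anchor_id", "x_rank", "y_rank", "x_mid", "y_mid")]
}

# strict/tolerant segmentation into maximal constant-direction runs
segment_runs <- function(y, tolerant = FALSE) {
  n <- length(y)
  if (n == 1L) return(data.frame(start = 1L, end = 1L, orientation = "forward"))
  d <- diff(y)
  step_ok <- if (tolerant) d != 0 else abs(d) == 1
  blocks <- list()
  s <- 1L
  dir <- 0L
  for (i in seq_len(n - 1L)) {
    di <- if (step_ok[i]) sign(d[i]) else 0L
    if (dir == 0L && di != 0L) { dir <- di; next }
    if (di == dir && di != 0L) next
    blocks[[length(blocks) + 1L]] <- c(s, i, dir)
    s <- i + 1L
    dir <- 0L
  }
  blocks[[length(blocks) + 1L]] <- c(s, n, dir)
  out <- do.call(rbind, blocks)
  data.frame(start = out[, 1], end = out[, 2],
             orientation = ifelse(out[, 3] < 0, "inverted", "forward"),
             stringsAsFactors = FALSE)
}

#' Detect inverted anchor blocks
#'
#' Walks anchors in X order and segments them into maximal runs where
#' consecutive `y_rank` differences keep a constant sign (strict mode
#' requires exact unit steps; tolerant mode any monotone run). Blocks
#' spanning fewer than `min_block` anchors are merged into the larger
#' neighbouring block (majority orientation). Breakpoints are the boundaries
#' between consecutive blocks.
#'
#' @param anchors Anchor data.frame from [rank_anchors()] or
#'   [make_anchor_permutation()].
#' @param min_block Minimum anchors per reported block.
#' @param tolerant Accept monotone non-unit steps.
#' @return Data frame of blocks in X order: `anchor_start`, `anchor_end`
#'   (1-based inclusive indices), `n_anchors`, `orientation`, `x_span`,
#'   `y_span` (bp, from midpoints). Breakpoint indices are attached as
#'   attribute `breakpoints` (boundary after each non-final block).
#' @export
detect_inversions <- function(anchors, min_block = 3, tolerant = FALSE) {
  stopifnot(nrow(anchors) >= 2, all(c("x_rank", "y_rank") %in% names(anchors)))
  a <- anchors[order(anchors$x_rank), ]
  y <- a$y_rank
  blocks <- segment_runs(y, tolerant)
  # merge short blocks into the larger neighbour until all pass min_block
  while (nrow(blocks) > 1L) {
    n_anch <- blocks$end - blocks$start + 1L
    small <- which(n_anch < min_block)
    if (!length(small)) break
    i <- small[1]
    nb <- if (i == 1L) 2L
      else if (i == nrow(blocks)) i - 1L
      else if (n_anch[i - 1L] >= n_anch[i + 1L]) i - 1L else i + 1L
    lo <- min(i, nb); hi <- max(i, nb)
    ori <- if (n_anch[lo] >= n_anch[hi]) blocks$orientation[lo] else
      blocks$orientation[hi]
    blocks$end[lo] <- blocks$end[hi]
    blocks$orientation[lo] <- ori
    blocks <- blocks[-hi, , drop = FALSE]
    rownames(blocks) <- NULL
  }
  blocks$n_anchors <- blocks$end - blocks$start + 1L
  span <- function(v, s, e) max(v[s:e]) - min(v[s:e])
  blocks$x_span <- mapply(span, list(a$x_mid), blocks$start, blocks$end)
  blocks$y_span <- mapply(span, list(a$y_mid), blocks$start, blocks$end)
  out <- data.frame(anchor_start = blocks$start, anchor_end = blocks$end,
                    n_anchors = blocks$n_anchors,
                    orientation = blocks$orientation,
                    x_span = blocks$x_span, y_span = blocks$y_span,
                    stringsAsFactors = FALSE)
  attr(out, "breakpoints") <- if (nrow(out) > 1)
    data.frame(after_anchor = out$anchor_end[-nrow(out)],
               before_anchor = out$anchor_start[-1]) else
    data.frame(after_anchor = integer(0), before_anchor = integer(0))
  out
}

#' Count anchors displaced between X and Y
#'
#' An anchor is displaced when its Y rank differs from its X rank. Reports
#' the overall tally and, when blocks are supplied, the per-block tallies.
#'
#' @param anchors Anchor data.frame.
#' @param blocks Optional block table from [detect_inversions()].
#' @return List with `total`, `ids` (displaced anchor ids in X order), and
#'   `per_block` (integer vector parallel to `blocks`, or `NULL`).
#' @export
displaced_pairs <- function(anchors, blocks = NULL) {
  a <- anchors[order(anchors$x_rank), ]
  disp <- a$y_rank != a$x_rank
  per_block <- NULL
  if (!is.null(blocks))
    per_block <- vapply(seq_len(nrow(blocks)), function(i)
      sum(disp[blocks$anchor_start[i]:blocks$anchor_end[i]]), integer(1))
  list(total = sum(disp),
       ids = if (!is.null(a$anchor_id)) a$anchor_id[disp] else which(disp),
       per_block = per_block)
}
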