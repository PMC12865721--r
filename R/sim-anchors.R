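# Anchor-permutation construction: gametolog anchors numbered 1..n along the
# X; the Y order is the X order with specified runs reversed.

#' Construct an anchor table with known inverted runs
#'
#' Anchors are numbered `1..n_anchors` in X order; the Y order equals the X
#' order with each run in `inversion_spec` reversed. Midpoints are laid out
#' on a regular grid of `spacing` bp.
#'
#' @param n_anchors Number of anchors.
#' @param inversion_spec List of `c(start, end)` 1-based inclusive runs to
#'   reverse; runs must be within range and non-overlapping.
#' @param spacing Distance between consecutive anchor midpoints (bp).
#' @param out_tsv Optional path for a TSV with header
#'   `anchor_id x_rank y_rank x_mid y_mid`.
#' @return Data frame of anchors in X order with `x_rank`, `y_rank`,
#'   `x_mid`, `y_mid`; the truth (reversed runs) is attached as attribute
#'   `inversion_truth`.
#' @export
make_anchor_permutation <- function(n_anchors, inversion_spec = list(),
                                    spacing = 10000, out_tsv = NULL) {
  stopifnot(n_anchors >= 1)
  y_order <- apply_inversion_runs(n_anchors, inversion_spec)
  y_rank <- match(seq_len(n_anchors), y_order)
  anchors <- data.frame(
    anchor_id = sprintf("pair%03d", seq_len(n_anchors)),
    x_rank = seq_len(n_anchors),
    y_rank = y_rank,
    x_mid = (seq_len(n_anchors) - 0.5) * spacing,
    y_mid = (y_rank - 0.5) * spacing,
    stringsAsFactors = FALSE)
  attr(anchors, "inversion_truth") <- inversion_spec
  if (!is.null(out_tsv))
    utils::write.table(anchors, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  anchors
}
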