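# X/Y homology catalogue by reciprocal best hit over translated-protein
# alignment, per-region partition, and Y gene-loss quantification.

#' Protein-level similarity score for two coding sequences
#'
#' Translates both CDS and scores a global protein alignment (BLOSUM62,
#' affine gaps). Symmetric in its arguments.
#'
#' @param cds_a,cds_b Coding sequences (character), length a multiple of 3,
#'   no internal stop codon.
#' @return Alignment score (numeric).
#' @export
score_pair <- function(cds_a, cds_b) {
  pa <- as.character(Biostrings::translate(Biostrings::DNAString(
    check_cds(as.character(cds_a), "cds_a"))))
  pb <- as.character(Biostrings::translate(Biostrings::DNAString(
    check_cds(as.character(cds_b), "cds_b"))))
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
}

translate_set <- function(cds) {
  stopifnot(is.character(cds), !is.null(names(cds)))
  for (id in names(cds)) check_cds(cds[[id]], id)
  aa <- Biostrings::translate(Biostrings::DNAStringSet(cds))
  names(aa) <- names(cds)
  aa
}

#' Build the X/Y homology catalogue by reciprocal best hit
#'
#' Scores every X-vs-Y protein pair; gene x is paired with gene y iff each is
#' the other's highest-scoring partner and the pair's score reaches
#' `min_score_fraction` of the self-alignment score of the shorter gene.
#' Unpaired genes become X-specific or Y-specific. Independent of input
#' order; best-hit ties break deterministically by score then gene id.
#'
#' @param x_genes,y_genes Named character vectors of CDS (names are gene
#'   ids), or `DNAStringSet`s.
#' @param min_score_fraction Minimum score as a fraction of the shorter
#'   gene's self-score.
#' @return A `homology_catalog` list: `pairs` (data.frame x_id, y_id,
#'   score), `x_specific`, `y_specific`.
#' @export
find_rbh_pairs <- function(x_genes, y_genes, min_score_fraction = 0.3) {
  if (methods::is(x_genes, "XStringSet")) x_genes <- as.character(x_genes)
  if (methods::is(y_genes, "XStringSet")) y_genes <- as.character(y_genes)
  if (!length(x_genes) || !length(y_genes)) {
    return(structure(list(
      pairs = data.frame(x_id = character(0), y_id = character(0),
                         score = numeric(0), stringsAsFactors = FALSE),
      x_specific = sort(names(x_genes)), y_specific = sort(names(y_genes))),
      class = "homology_catalog"))
  }
  x_genes <- x_genes[order(names(x_genes))]
  y_genes <- y_genes[order(names(y_genes))]
  aax <- translate_set(x_genes)
  aay <- translate_set(y_genes)
  scores <- matrix(NA_real_, length(x_genes), length(y_genes),
                   dimnames = list(names(x_genes), names(y_genes)))
  for (j in seq_along(aay))
    scores[, j] <- Biostrings::pairwiseAlignment(
      aax, aay[[j]], substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global", scoreOnly = TRUE)
  self_x <- vapply(seq_along(aax), function(i) Biostrings::pairwiseAlignment(
    aax[[i]], aax[[i]], substitutionMatrix = "BLOSUM62", gapOpening = 10,
    gapExtension = 0.5, type = "global", scoreOnly = TRUE), numeric(1))
  self_y <- vapply(seq_along(aay), function(i) Biostrings::pairwiseAlignment(
    aay[[i]], aay[[i]], substitutionMatrix = "BLOSUM62", gapOpening = 10,
    gapExtension = 0.5, type = "global", scoreOnly = TRUE), numeric(1))
  # deterministic argmax: first index at the maximum (ids are sorted)
  best_y_for_x <- apply(scores, 1, which.max)
  best_x_for_y <- apply(scores, 2, which.max)
  pairs <- list()
  for (i in seq_along(x_genes)) {
    j <- best_y_for_x[i]
    if (best_x_for_y[j] != i) next
    shorter_self <- if (nchar(x_genes[i]) <= nchar(y_genes[j]))
      self_x[i] else self_y[j]
    if (scores[i, j] < min_score_fraction * shorter_self) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      x_id = names(x_genes)[i], y_id = names(y_genes)[j],
      score = scores[i, j], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(x_id = character(0), y_id = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 x_specific = setdiff(names(x_genes), pairs$x_id),
                 y_specific = setdiff(names(y_genes), pairs$y_id)),
            class = "homology_catalog")
}

#' @export
print.homology_catalog <- function(x, ...) {
  cat(sprintf("homology catalog: %d gametolog pairs, %d X-specific, %d Y-specific\n",
              nrow(x$pairs), length(x$x_specific), length(x$y_specific)))
  invisible(x)
}

#' Partition a homology catalogue by genomic region
#'
#' Assigns each gene to SDR, PAR or neither by midpoint containment
#' (half-open intervals); pairs are assigned by their Y member. Genes outside
#' both regions are tallied as `unassigned` with a warning.
#'
#' @param catalog A `homology_catalog` from [find_rbh_pairs()].
#' @param genes Data frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open) for every catalogued gene.
#' @param sdr,par [region()]s (or data.frames of intervals); must be
#'   disjoint.
#' @return Data frame of counts with rows SDR, PAR, unassigned and columns
#'   `pairs`, `x_specific`, `y_specific`.
#' @export
partition_by_region <- function(catalog, genes, sdr, par) {
  sdr_df <- as_region_df(sdr); par_df <- as_region_df(par)
  for (i in seq_len(nrow(sdr_df))) for (j in seq_len(nrow(par_df)))
    if (regions_overlap(as.list(sdr_df[i, ]), as.list(par_df[j, ])))
      stop("SDR and PAR regions overlap")
  mid <- floor((genes$start + genes$end) / 2)
  reg <- ifelse(point_in_regions(genes$chrom, mid, sdr_df), "SDR",
                ifelse(point_in_regions(genes$chrom, mid, par_df), "PAR",
                       "unassigned"))
  names(reg) <- genes$id
  missing <- setdiff(c(catalog$pairs$x_id, catalog$pairs$y_id,
                       catalog$x_specific, catalog$y_specific), genes$id)
  if (length(missing))
    stop("no coordinates for: ", paste(utils::head(missing, 5), collapse = ", "))
  if (any(reg == "unassigned"))
    warning(sum(reg == "unassigned"), " gene(s) outside SDR and PAR")
  tally <- function(ids) table(factor(reg[ids],
                                      levels = c("SDR", "PAR", "unassigned")))
  out <- data.frame(
    pairs = as.integer(tally(catalog$pairs$y_id)),
    x_specific = as.integer(tally(catalog$x_specific)),
    y_specific = as.integer(tally(catalog$y_specific)))
  rownames(out) <- c("SDR", "PAR", "unassigned")
  out
}

#' Y gene-loss percentage
#'
#' `100 * (n_x - n_y) / n_x`: the share of X genes with no surviving Y copy.
#'
#' @param n_y,n_x Gene counts on the Y-SDR and its X counterpart.
#' @return List with `percent` (full precision) and `rounded` (nearest
#'   integer).
#' @export
gene_loss_fraction <- function(n_y, n_x) {
  if (n_x <= 0) stop("n_x must be positive")
  p <- 100 * (n_x - n_y) / n_x
  list(percent = p, rounded = as.integer(round(p)))
}
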