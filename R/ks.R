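# Codon-aware alignment and Nei-Gojobori Ks/Ka estimation with
# Jukes-Cantor correction.

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Translates both CDS, aligns the proteins globally with affine gap
#' penalties (BLOSUM62), and back-threads the nucleotides through the protein
#' alignment so that every gap is a whole codon.
#'
#' @param cds_x,cds_y Coding sequences (character or `DNAString`), length a
#'   multiple of 3, no internal stop codon.
#' @param pair_id Identifier carried through to downstream tables.
#' @return A `codon_alignment` list with `aligned_x` / `aligned_y` (codon
#'   vectors, gaps as `"---"`) and `n_codons_aligned`, the number of gapless
#'   unambiguous codon columns.
#' @export
align_codons <- function(cds_x, cds_y, pair_id = "pair") {
  cds_x <- check_cds(as.character(cds_x), "cds_x")
  cds_y <- check_cds(as.character(cds_y), "cds_y")
  px <- as.character(Biostrings::translate(Biostrings::DNAString(cds_x)))
  py <- as.character(Biostrings::translate(Biostrings::DNAString(cds_y)))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(px), Biostrings::AAString(py),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ax <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ay <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cod_x <- split_codons(cds_x)
  cod_y <- split_codons(cds_y)
  ix <- iy <- 0L
  out_x <- out_y <- character(length(ax))
  for (k in seq_along(ax)) {
    if (ax[k] == "-") out_x[k] <- "---" else { ix <- ix + 1L; out_x[k] <- cod_x[ix] }
    if (ay[k] == "-") out_y[k] <- "---" else { iy <- iy + 1L; out_y[k] <- cod_y[iy] }
  }
  gapless <- out_x != "---" & out_y != "---" &
    !grepl("[^ACGT]", out_x) & !grepl("[^ACGT]", out_y)
  if (!any(gapless)) stop("zero aligned codon columns for ", pair_id)
  structure(list(pair_id = pair_id, aligned_x = out_x, aligned_y = out_y,
                 n_codons_aligned = sum(gapless)),
            class = "codon_alignment")
}

#' Nei-Gojobori site and difference counts for a codon alignment
#'
#' Site totals S and N are the mean of the two sequences' per-codon sums over
#' gapless columns; differences are pathway-averaged per differing codon pair.
#'
#' @param alignment A `codon_alignment`.
#' @return List with `S`, `N`, `Sd`, `Nd` and `n_codons_aligned`.
#' @export
ng_counts <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  keep <- alignment$aligned_x != "---" & alignment$aligned_y != "---" &
    !grepl("[^ACGT]", alignment$aligned_x) &
    !grepl("[^ACGT]", alignment$aligned_y)
  x <- alignment$aligned_x[keep]
  y <- alignment$aligned_y[keep]
  lk <- ng_lookup()
  S <- (sum(lk$s[x]) + sum(lk$s[y])) / 2
  N <- 3 * length(x) - S
  idx <- cbind(match(x, rownames(lk$sd)), match(y, colnames(lk$sd)))
  Sd <- sum(lk$sd[idx])
  Nd <- sum(lk$nd[idx])
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons_aligned = length(x))
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; `NA` at or beyond saturation
#' (`p >= 3/4`).
#'
#' @param p Observed proportion(s) of differing sites.
#' @return Corrected distance(s); `NA_real_` where saturated.
#' @export
jc_correct <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE))
  d <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  # 4/3*p can round to exactly 1 -> -0.75*log(0) = Inf; treat as saturated
  d[!is.finite(d)] <- NA_real_
  d
}

#' Estimate Ks and Ka for one gametolog pair
#'
#' @inheritParams align_codons
#' @return One-row data.frame (`ks_estimate`) with site counts, difference
#'   counts, proportions, Jukes-Cantor-corrected `Ks`/`Ka` and a `saturated`
#'   flag (`TRUE` when `(4/3) * pS >= 1` and `Ks` is undefined).
#' @export
estimate_ks <- function(cds_x, cds_y, pair_id = "pair") {
  aln <- align_codons(cds_x, cds_y, pair_id)
  cnt <- ng_counts(aln)
  pS <- if (cnt$S > 0) cnt$Sd / cnt$S else 0
  pN <- if (cnt$N > 0) cnt$Nd / cnt$N else 0
  data.frame(pair_id = pair_id,
             n_codons_aligned = cnt$n_codons_aligned,
             S = cnt$S, N = cnt$N, Sd = cnt$Sd, Nd = cnt$Nd,
             pS = pS, pN = pN,
             Ks = jc_correct(pS), Ka = jc_correct(pN),
             saturated = (4 / 3) * pS >= 1,
             stringsAsFactors = FALSE)
}

#' Ks table over a set of gametolog pairs
#'
#' @param cds A named character vector (or `DNAStringSet`) of coding
#'   sequences whose names follow the `<pair>__X` / `<pair>__Y` convention,
#'   or a list with elements `x` and `y` of equal-length named vectors.
#' @return Data frame of per-pair Ks estimates (see [estimate_ks()]).
#' @export
ks_table <- function(cds) {
  if (methods::is(cds, "XStringSet")) cds <- as.character(cds)
  if (is.list(cds) && !is.null(cds$x) && !is.null(cds$y)) {
    stopifnot(length(cds$x) == length(cds$y))
    pairs <- data.frame(id = names(cds$x) %||% paste0("pair", seq_along(cds$x)),
                        x = unname(cds$x), y = unname(cds$y),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(is.character(cds), !is.null(names(cds)))
    ids <- sub("__[XY]$", "", names(cds))
    xs <- cds[endsWith(names(cds), "__X")]
    ys <- cds[endsWith(names(cds), "__Y")]
    common <- intersect(sub("__X$", "", names(xs)), sub("__Y$", "", names(ys)))
    if (!length(common)) stop("no <pair>__X / <pair>__Y id pairs found")
    pairs <- data.frame(id = common,
                        x = unname(xs[paste0(common, "__X")]),
                        y = unname(ys[paste0(common, "__Y")]),
                        stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    estimate_ks(pairs$x[i], pairs$y[i], pairs$id[i])))
}
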