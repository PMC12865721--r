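# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG state is untouched.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# deterministic sub-stream seed, kept well below 2^31
sub_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + offset * 7919
  as.integer(s %% 2147483629 + 1)
}

#' Genomic interval in 0-based half-open coordinates
#'
#' Lightweight region descriptor used for SDR / PAR spans.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span, `end > start`.
#' @return A `region` list with elements `chrom`, `start`, `end`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(end > start) || start < 0)
    stop("invalid region [", start, ", ", end, ") on ", chrom)
  structure(list(chrom = chrom, start = start, end = end), class = "region")
}

as_region_df <- function(x) {
  if (inherits(x, "region"))
    return(data.frame(chrom = x$chrom, start = x$start, end = x$end,
                      stringsAsFactors = FALSE))
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    return(x[, c("chrom", "start", "end")])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "region")))
    return(do.call(rbind, lapply(x, as_region_df)))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as region(s)")
}

regions_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# midpoint containment against a region data.frame; half-open convention
point_in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos >= regions$start[i] & pos < regions$end[i])
  }
  hit
}
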