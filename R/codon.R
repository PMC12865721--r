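# Nei-Gojobori (1986) codon machinery: fractional synonymous/nonsynonymous
# site counts per codon and difference counts per codon pair, averaging over
# minimal mutational pathways. Lookup tables are built once per session.

.ng <- new.env(parent = emptyenv())

NG_BASES <- c("A", "C", "G", "T")
NG_STOPS <- c("TAA", "TAG", "TGA")

ng_all_codons <- function() {
  g <- expand.grid(b3 = NG_BASES, b2 = NG_BASES, b1 = NG_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

ng_aa <- function(codons) {
  if (is.null(.ng$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ng$aa <- gc[ng_all_codons()]
    names(.ng$aa) <- ng_all_codons()
  }
  unname(.ng$aa[codons])
}

ng_is_stop <- function(codon) codon %in% NG_STOPS

# the 9 single-base neighbours of a codon
ng_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(NG_BASES, ch[p])) {
      v <- ch; v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position the synonymous fraction is the number of the three
#' possible single-base changes that preserve the amino acid, divided by the
#' number that do not create a stop codon (mutations to stops are excluded
#' from the denominator). Site counts always sum to 3.
#'
#' @param codon A single codon string of A/C/G/T, not a stop codon.
#' @return Named numeric vector `c(s = , n = )`.
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 unambiguous bases, got '", codon, "'")
  if (ng_is_stop(codon)) stop("stop codon '", codon, "' has no site counts")
  tab <- ng_sites_table()
  c(s = tab[[codon]], n = 3 - tab[[codon]])
}

ng_sites_table <- function() {
  if (!is.null(.ng$sites)) return(.ng$sites)
  codons <- setdiff(ng_all_codons(), NG_STOPS)
  s <- vapply(codons, function(cd) {
    aa0 <- ng_aa(cd)
    ch <- strsplit(cd, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      muts <- vapply(setdiff(NG_BASES, ch[p]), function(b) {
        v <- ch; v[p] <- b; paste(v, collapse = "")
      }, character(1))
      ok <- muts[!ng_is_stop(muts)]
      if (length(ok))
        tot <- tot + sum(ng_aa(ok) == aa0) / length(ok)
    }
    tot
  }, numeric(1))
  .ng$sites <- as.list(s)
  .ng$sites
}

ng_perms <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

#' Pathway-averaged difference counts for one codon pair
#'
#' Enumerates every minimal mutational pathway between two codons, classifies
#' each step as synonymous or nonsynonymous by amino-acid identity, and
#' averages the two tallies over pathways. Pathways passing through a stop
#' codon are excluded unless every pathway does.
#'
#' @param codon_a,codon_b Codon strings (A/C/G/T, non-stop).
#' @return Named numeric vector `c(sd = , nd = )`, summing to the number of
#'   differing positions.
#' @export
ng_pair_diffs <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd))
      stop("codon must be 3 unambiguous bases, got '", cd, "'")
    if (ng_is_stop(cd)) stop("stop codon '", cd, "' not allowed")
  }
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  paths <- lapply(ng_perms(length(pos)), function(ord) {
    cur <- a
    sd <- 0; nd <- 0; via_stop <- FALSE
    for (p in pos[ord]) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (ng_is_stop(c2) && c2 != codon_b) via_stop <- TRUE
      if (ng_aa(c1) == ng_aa(c2)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, via_stop = via_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd")))
}

# 64x64 lookup matrices (NA rows/cols for stops) for vectorised counting
ng_lookup <- function() {
  if (!is.null(.ng$lookup)) return(.ng$lookup)
  codons <- ng_all_codons()
  ok <- setdiff(codons, NG_STOPS)
  sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  sites <- ng_sites_table()
  for (x in ok) {
    for (y in ok) {
      if (x == y) { sd[x, y] <- 0; nd[x, y] <- 0; next }
      d <- ng_pair_diffs(x, y)
      sd[x, y] <- d[["sd"]]; nd[x, y] <- d[["nd"]]
    }
  }
  s <- setNames(rep(NA_real_, 64), codons)
  s[ok] <- unlist(sites[ok])
  .ng$lookup <- list(sd = sd, nd = nd, s = s)
  .ng$lookup
}

# synonymous / nonsynonymous single-base neighbours excluding stops,
# cached per codon; used by the sequence-evolution simulator
ng_syn_neighbours <- function(codon, synonymous = TRUE) {
  key <- if (synonymous) "syn" else "nonsyn"
  if (is.null(.ng[[key]])) {
    codons <- setdiff(ng_all_codons(), NG_STOPS)
    .ng[[key]] <- lapply(setNames(codons, codons), function(cd) {
      nb <- ng_neighbours(cd)
      nb <- nb[!ng_is_stop(nb)]
      same <- ng_aa(nb) == ng_aa(cd)
      if (synonymous) nb[same] else nb[!same]
    })
  }
  .ng[[key]][[codon]]
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

check_cds <- function(cds, id = "CDS") {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop(id, " contains non-ACGT characters")
  cod <- split_codons(cds)
  if (length(cod) < 10L)
    stop(id, " shorter than 10 codons")
  if (any(ng_is_stop(cod[-length(cod)])))
    stop(id, " contains an internal stop codon")
  if (ng_is_stop(cod[length(cod)]))
    stop(id, " ends in a stop codon; supply coding sequence only")
  cds
}
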