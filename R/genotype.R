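# Lightweight genotype representation: a named list, locus -> character
# vector of one or two allele names (homozygotes may be given once and
# are normalized to a duplicated pair).

CLASS_I_LOCI <- c("A", "B", "C")

#' Locus of an allele name
#'
#' @param allele WHO-style allele name(s), e.g. \code{"B*07:02"}.
#' @return the locus prefix before \code{"*"} (the whole name if no
#'   \code{"*"} is present, as for serologic tokens like \code{"B7"}).
#' @export
locusOf <- function(allele) {
  sub("\\*.*$", "", allele)
}

#' Construct a genotype
#'
#' @param ... one character vector of allele names per locus, named by
#'   locus (e.g. \code{A = c("A*01:01", "A*02:01")}). Length-1 entries
#'   are treated as homozygous and duplicated.
#' @return a named list of length-2 character vectors, class
#'   \code{"Genotype"}.
#' @export
genotype <- function(...) {
  g <- list(...)
  if (length(g) == 1L && is.list(g[[1]]) && is.null(names(g)[1]))
    g <- g[[1]]
  if (is.null(names(g)) || any(names(g) == ""))
    stop("genotype entries must be named by locus")
  g <- lapply(g, function(al) {
    al <- as.character(al)
    if (!length(al) %in% c(1L, 2L))
      stop("each locus needs one or two alleles")
    if (length(al) == 1L) al <- rep(al, 2L)
    al
  })
  structure(g, class = "Genotype")
}

#' @export
print.Genotype <- function(x, ...) {
  cat("Genotype:\n")
  for (L in names(x))
    cat(sprintf("  %-6s %s\n", L, paste(unique(x[[L]]), collapse = " / ")))
  invisible(x)
}

# all Class I alleles of a genotype (up to six names, duplicates kept)
classIAlleles <- function(g) {
  unlist(g[intersect(names(g), CLASS_I_LOCI)], use.names = FALSE)
}

# presenter (Class II) loci present in a genotype
presenterLoci <- function(g) {
  setdiff(names(g), CLASS_I_LOCI)
}
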