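#' Per-locus allele frequency spectra of one population sample
#'
#' Counts alleles over the non-missing gene copies of a sample and normalizes
#' to relative frequencies. For diploid data the gene-copy count is twice the
#' number of non-missing individuals at the locus.
#'
#' @param table a [GenotypeTable-class].
#' @param sample a sample label.
#' @return A named list, one entry per locus: `list(freq = <named numeric,
#'   allele -> relative frequency>, n = <gene copies>)`, or `NULL` for a locus
#'   with no non-missing call (flagged absent rather than a division by zero).
#' @examples
#' ann <- data.frame(label = "s", deme = "crossriver", time_bp = 0)
#' gt <- GenotypeTable(matrix(c(12L, 12L), 2), matrix(c(14L, 12L), 2),
#'                     loci = "L1", ids = c("i1", "i2"), pop = c("s", "s"),
#'                     annotation = ann)
#' alleleFrequencies(gt, "s")$L1  # 12 -> 0.75, 14 -> 0.25, n = 4
#' @export
alleleFrequencies <- function(table, sample) {
  stopifnot(is(table, "GenotypeTable"))
  if (!sample %in% table@annotation$label)
    stop("unknown sample label: ", sample)
  keep <- table@pop == sample
  out <- vector("list", length(table@loci))
  names(out) <- table@loci
  for (j in seq_along(table@loci)) {
    copies <- c(table@a1[keep, j], table@a2[keep, j])
    copies <- copies[!is.na(copies)]
    if (!length(copies)) next  # absent entry
    tab <- table(copies)
    out[[j]] <- list(freq = setNames(as.numeric(tab) / length(copies),
                                     names(tab)),
                     n = length(copies))
  }
  out
}

#' Allele counts per locus of one sample
#'
#' Convenience wrapper over [alleleFrequencies()] returning integer counts
#' (used by the allelic-richness rarefaction).
#'
#' @inheritParams alleleFrequencies
#' @return Named list per locus of named integer count vectors (`NULL` when
#'   the locus has no data).
#' @export
alleleCounts <- function(table, sample) {
  afs <- alleleFrequencies(table, sample)
  lapply(afs, function(a) {
    if (is.null(a)) return(NULL)
    setNames(as.integer(round(a$freq * a$n)), names(a$freq))
  })
}

#' Reduce a diploid table to one haplotype per individual
#'
#' For every individual and locus exactly one of the two alleles is retained,
#' chosen uniformly at random. Missing genotypes stay missing. Sampling one
#' gene copy per individual halves the number of alleles drawn from the same
#' deme, which avoids the spurious bottleneck signal that over-sampling a
#' structured deme produces in coalescent inference (the scattering-phase
#' artifact).
#'
#' @param table a [GenotypeTable-class].
#' @param seed optional integer seed; for a fixed seed the result is
#'   deterministic.
#' @return An integer matrix (individuals x loci) of retained repeat counts,
#'   with the `pop` attribute carrying the per-individual sample label and
#'   `annotation` the annotation data.frame.
#' @export
oneHaplotypePerIndividual <- function(table, seed = NULL) {
  stopifnot(is(table, "GenotypeTable"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreRNG(old), add = TRUE)
    set.seed(seed)
  }
  pickFirst <- matrix(runif(length(table@a1)) < 0.5, nrow(table@a1))
  hap <- ifelse(pickFirst, table@a1, table@a2)
  dimnames(hap) <- list(table@ids, table@loci)
  storage.mode(hap) <- "integer"
  attr(hap, "pop") <- table@pop
  attr(hap, "annotation") <- table@annotation
  hap
}

restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Convert repeat counts to fragment lengths
#'
#' Repeat counts are the unit of every analysis in this package; this helper
#' converts to fragment length in base pairs only when a user explicitly asks
#' for it (it is never applied implicitly).
#'
#' @param repeats integer repeat counts.
#' @param motifLength repeat-motif length in bp.
#' @param offset flanking length in bp added to every allele.
#' @return Numeric fragment lengths `offset + motifLength * repeats`.
#' @export
repeatsToFragmentLength <- function(repeats, motifLength, offset = 0) {
  offset + motifLength * repeats
}
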