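#' Read a Genepop file with a sampling-time annotation sidecar
#'
#' Parses a standard Genepop file (title line, locus names either one per line
#' or comma-separated on a single line, `POP` blocks with comma-separated
#' individual identifiers) into a [GenotypeTable-class]. Both the 2-digit and
#' the 3-digit allele-code dialects are accepted (detected from the genotype
#' field width); the all-zero code (`0000` / `000000`) is parsed as missing.
#' Allele codes are interpreted directly as repeat counts.
#'
#' Genepop has no sampling-time field, so a plain-text sidecar supplies one
#' annotation line per `POP` block, in file order: `label deme time_bp`
#' (whitespace-separated; `#` starts a comment). `deme` must be `crossriver`
#' or `western`; `time_bp` is in generations before present.
#'
#' @param path path to the Genepop file.
#' @param annotation either the path to the sidecar file or an annotation
#'   data.frame with columns `label`, `deme`, `time_bp`, one row per POP
#'   block in order.
#' @return A [GenotypeTable-class].
#' @seealso [writeGenepop()], [readSampleAnnotation()]
#' @export
readGenepop <- function(path, annotation) {
  if (is.character(annotation)) annotation <- readSampleAnnotation(annotation)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2) stop("not a Genepop file: fewer than two lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]

  # locus names: everything between the title and the first POP line
  if (is.na(first_pop)) {
    loci_lines <- lines[-1]
    loci_lines <- loci_lines[nzchar(trimws(loci_lines))]
    first_pop <- length(lines) + 1L
  } else {
    loci_lines <- lines[seq(2, first_pop - 1)]
  }
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found")

  pop_starts <- which(is_pop)
  n_pop <- length(pop_starts)
  if (n_pop != nrow(annotation))
    stop(sprintf("annotation config lists %d samples but file has %d POP blocks",
                 nrow(annotation), n_pop))

  ids <- character(); pop <- character()
  a1 <- NULL; a2 <- NULL
  rows1 <- list(); rows2 <- list()
  for (b in seq_len(n_pop)) {
    from <- pop_starts[b] + 1L
    to <- if (b < n_pop) pop_starts[b + 1] - 1L else length(lines)
    if (to < from) next
    for (ln in from:to) {
      line <- lines[ln]
      if (!nzchar(trimws(line))) next
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2)
        stop(sprintf("line %d: expected 'id , genotypes'", ln))
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
      genos <- genos[nzchar(genos)]
      if (length(genos) != length(loci))
        stop(sprintf("line %d: %d genotype fields for %d loci", ln,
                     length(genos), length(loci)))
      w <- unique(nchar(genos))
      if (length(w) != 1 || !w %in% c(4L, 6L))
        stop(sprintf("line %d: genotype fields must be uniformly 4 or 6 digits", ln))
      half <- w / 2
      x1 <- as.integer(substr(genos, 1, half))
      x2 <- as.integer(substr(genos, half + 1, w))
      if (anyNA(x1) || anyNA(x2))
        stop(sprintf("line %d: non-numeric allele code", ln))
      # the all-zero code means missing; a half-zero code is malformed
      if (any(xor(x1 == 0, x2 == 0)))
        stop(sprintf("line %d: half-missing genotype (one allele coded 0)", ln))
      x1[x1 == 0] <- NA_integer_; x2[x2 == 0] <- NA_integer_
      ids <- c(ids, id); pop <- c(pop, annotation$label[b])
      rows1[[length(rows1) + 1L]] <- x1
      rows2[[length(rows2) + 1L]] <- x2
    }
  }
  if (length(rows1)) {
    a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  } else {
    a1 <- matrix(NA_integer_, 0, length(loci))
    a2 <- matrix(NA_integer_, 0, length(loci))
  }
  GenotypeTable(a1, a2, loci = loci, ids = ids, pop = pop,
                annotation = annotation)
}

#' Write a GenotypeTable as Genepop (3-digit dialect) plus sidecar
#'
#' Emits the 3-digit allele-code dialect with missing genotypes as `000000`,
#' one `POP` block per sample label in annotation order. Output is bit-stable
#' for identical inputs.
#'
#' @param table a [GenotypeTable-class].
#' @param path output path for the Genepop file.
#' @param annotationPath optional path for the annotation sidecar; omit to
#'   skip writing it.
#' @param title title line (first line of the file).
#' @return Invisibly, `path`.
#' @export
writeGenepop <- function(table, path, annotationPath = NULL,
                         title = "driftABC genotypes") {
  stopifnot(is(table, "GenotypeTable"))
  mx <- suppressWarnings(max(table@a2, na.rm = TRUE))
  if (is.finite(mx) && mx > 999)
    stop("allele repeat count ", mx, " exceeds the 3-digit Genepop code")
  enc <- function(x) ifelse(is.na(x), "000", formatC(x, width = 3, flag = "0"))
  out <- c(title, table@loci)
  for (lab in table@annotation$label) {
    out <- c(out, "POP")
    idx <- which(table@pop == lab)
    for (i in idx) {
      g <- paste0(enc(table@a1[i, ]), enc(table@a2[i, ]))
      out <- c(out, paste0(table@ids[i], " , ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  if (!is.null(annotationPath)) writeSampleAnnotation(table@annotation, annotationPath)
  invisible(path)
}

#' Read / write the sampling-time annotation sidecar
#'
#' One line per POP block, in file order: `label deme time_bp`,
#' whitespace-separated; blank lines and `#` comments ignored.
#'
#' @param path path to the sidecar file.
#' @return `readSampleAnnotation`: a data.frame with columns `label`, `deme`,
#'   `time_bp`.
#' @export
readSampleAnnotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation config: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("annotation line ", bad[1], " does not have 3 fields (label deme time_bp)")
  data.frame(label = vapply(parts, `[`, "", 1),
             deme = vapply(parts, `[`, "", 2),
             time_bp = as.integer(vapply(parts, `[`, "", 3)))
}

#' @rdname readSampleAnnotation
#' @param annotation annotation data.frame to write.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  writeLines(sprintf("%s %s %d", annotation$label, annotation$deme,
                     as.integer(annotation$time_bp)), path)
  invisible(path)
}
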