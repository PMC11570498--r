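#' @importFrom Biostrings readBStringSet writeXStringSet AAStringSet
#'   pairwiseAlignment alignedPattern alignedSubject
#' @importFrom utils data write.table
NULL

.AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
.AA_WITH_X <- c(.AA_ALPHABET, "X")

#' Read a proteome from FASTA
#'
#' Reads amino-acid FASTA, sanitizes the sequences and returns an
#' [Biostrings::AAStringSet] whose names are the header identifiers (first
#' whitespace-delimited token) and whose `mcols()$description` carries the
#' remainder of each header.  Sanitization uppercases, strips trailing stop
#' codons (`*`) and, in non-strict mode, replaces letters outside the 20
#' canonical amino acids (for example U, O, B, Z, J) by `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @param strict if `TRUE`, letters outside the canonical alphabet raise an
#'   error instead of being replaced by `X`.
#' @return An `AAStringSet` with unique names and sanitized sequences.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKV", ">p2", "GG"), fa)
#' readProteome(fa)
#' @export
readProteome <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("header(s) with no sequence: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- gsub(paste0("[", paste(.AA_WITH_X, collapse = ""), "]"), "", seqs)
  if (any(nzchar(bad))) {
    letters_found <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    if (strict) {
      stop("illegal letter(s) in strict mode: ",
           paste(letters_found, collapse = ", "))
    }
    warning("replaced non-canonical letter(s) by X: ",
            paste(letters_found, collapse = ", "))
    for (ch in letters_found)
      seqs <- gsub(ch, "X", seqs, fixed = TRUE)
  }
  out <- AAStringSet(seqs)
  names(out) <- ids
  mcols(out)$description <- desc
  out
}

#' Write a proteome to FASTA
#'
#' Writes an `AAStringSet` as multi-line FASTA with 60-character wrapping.
#' Descriptions stored in `mcols()$description` are appended to the headers.
#'
#' @param proteome an [Biostrings::AAStringSet].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeProteome <- function(proteome, path) {
  x <- proteome
  d <- mcols(x)$description
  if (!is.null(d) && any(nzchar(d)))
    names(x) <- ifelse(nzchar(d), paste(names(x), d), names(x))
  writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Write a results table deterministically
#'
#' Writes a data frame as TSV or JSON with a stable column order and numeric
#' formatting (6 significant digits), so identical input always produces
#' byte-identical output.
#'
#' @param rows a `data.frame` or `DataFrame`; all rows share one field set.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @examples
#' writeTable(data.frame(id = "p1", score = pi), tempfile(), format = "tsv")
#' @export
writeTable <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) {
    v <- df[[j]]
    df[[j]] <- ifelse(is.na(v), NA_character_, sprintf("%.6g", v))
  }
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", eol = "\n", fileEncoding = "")
  } else {
    json <- jsonlite::toJSON(df, dataframe = "rows", na = "null",
                             auto_unbox = FALSE, pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  }
  invisible(path)
}

# -- pairwise alignment -------------------------------------------------------

.substitution_matrix <- function(name) {
  ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
          "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% ok) stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal global pairwise alignment
#'
#' Needleman--Wunsch global alignment with affine gap penalties, computed
#' with [Biostrings::pairwiseAlignment].  A gap of length L costs
#' `gapOpen + L * gapExtend`.  Used for pairwise linker comparisons (for
#' example CsLinker against EPYC1); multiple alignment is out of scope.
#'
#' @param a,b amino-acid sequences (character or `AAString`), nonempty.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return A list of class `"linkerAlignment"` with elements `gappedA`,
#'   `gappedB` (equal-length gapped strings, gap symbol `-`) and `score`.
#' @examples
#' aln <- globalAlign("MKVEEK", "MKVDEK")
#' percentIdentity(aln)
#' @export
globalAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 10, gapExtend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  m <- .substitution_matrix(matrix)
  pa <- pairwiseAlignment(a, b,
    substitutionMatrix = m, gapOpening = gapOpen, gapExtension = gapExtend,
    type = "global"
  )
  out <- list(
    gappedA = as.character(alignedPattern(pa)),
    gappedB = as.character(alignedSubject(pa)),
    score = as.numeric(Biostrings::score(pa))
  )
  stopifnot(nchar(out$gappedA) == nchar(out$gappedB))
  class(out) <- "linkerAlignment"
  out
}

#' @export
print.linkerAlignment <- function(x, ...) {
  cat("Global alignment, score", x$score, "\n")
  cat(" ", x$gappedA, "\n ", x$gappedB, "\n")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identical columns as a percentage of the chosen denominator, reported to
#' one decimal place.  By default the denominator is the number of alignment
#' columns (including internal gaps) after trimming terminal gap-only
#' overhangs; alternatives use the shorter or longer ungapped sequence
#' length.
#'
#' @param aln result of [globalAlign()], or a sequence (in which case `b`
#'   must be supplied and the pair is aligned first).
#' @param b optional second sequence.
#' @param denominator `"columns"`, `"shorter"` or `"longer"`.
#' @param ... further arguments passed to [globalAlign()] when aligning.
#' @return Percent identity in \[0, 100\], rounded to one decimal.
#' @export
percentIdentity <- function(aln, b = NULL,
                            denominator = c("columns", "shorter", "longer"),
                            ...) {
  denominator <- match.arg(denominator)
  if (!inherits(aln, "linkerAlignment")) {
    if (is.null(b)) stop("supply an alignment or two sequences")
    aln <- globalAlign(aln, b, ...)
  }
  ca <- strsplit(aln$gappedA, "")[[1]]
  cb <- strsplit(aln$gappedB, "")[[1]]
  n <- length(ca)
  if (n == 0L) stop("zero-length alignment")
  # trim terminal overhangs: leading/trailing columns where either row is gap
  gap <- ca == "-" | cb == "-"
  first <- match(FALSE, gap)
  if (is.na(first)) stop("alignment is all gaps")
  last <- n + 1L - match(FALSE, rev(gap))
  keep <- first:last
  ident <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
  den <- switch(denominator,
    columns = length(keep),
    shorter = min(sum(ca != "-"), sum(cb != "-")),
    longer  = max(sum(ca != "-"), sum(cb != "-"))
  )
  round(100 * ident / den, 1)
}
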