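#' Construct an isoform sequence record
#'
#' An `isoform_sequence` is one protein sequence with a short isoform label,
#' the row unit of a family analysis. Residues are upper-case one-letter
#' amino-acid codes; `X` marks an unknown residue and is tolerated by the
#' aligner (it scores 0 against everything) but rejected by hydropathy
#' scoring.
#'
#' @param id Short isoform label, e.g. `"CA2"`.
#' @param residues Character scalar of one-letter residue codes.
#' @return An object of class `isoform_sequence` with fields `id` and
#'   `residues`.
#' @examples
#' isoform_sequence("CA2", "HHWGYGKHNGPEHW")
#' @export
isoform_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("sequence '", id, "': residues must be non-empty")
  bad <- setdiff(strsplit(residues, "")[[1]], AA_CODES)
  if (length(bad) > 0)
    stop("sequence '", id, "': illegal residue character(s): ",
         paste(sQuote(unique(bad)), collapse = ", "))
  structure(list(id = id, residues = residues), class = "isoform_sequence")
}

#' @export
print.isoform_sequence <- function(x, ...) {
  cat(sprintf("<isoform_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read a protein family from a FASTA file
#'
#' Accepts multi-record FASTA with wrapped or unwrapped sequence lines.
#' Residues are upper-cased and whitespace-stripped; record order is
#' preserved. Duplicate identifiers and illegal residue characters are
#' rejected with the offending token named.
#'
#' @param path Path to a FASTA file.
#' @return A list of [isoform_sequence()] records.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not FASTA: first non-blank line is not a '>' header")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record(s) with no sequence lines in ", path)
  mapply(isoform_sequence, ids, unname(seqs),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write a protein family to a FASTA file
#'
#' @param family List of [isoform_sequence()] records.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(family, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in family) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, nchar(s$residues), by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1L, nchar(s$residues))), con)
  }
  invisible(path)
}
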