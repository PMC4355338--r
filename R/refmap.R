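#' Map family positions onto a reference numbering
#'
#' Every alignment column that is non-gap in the reference row is
#' numbered consecutively by the reference's ungapped index (1-based),
#' giving the family-wide reference frame (e.g. "CA II numbering").
#' Member residues in those columns map to the corresponding reference
#' position; member insertions relative to the reference map to no
#' position and are dropped; member deletions leave the position absent
#' (`-`) for that member.
#'
#' @param msa An `msa` from [progressive_msa()].
#' @param reference_label Label of the reference row.
#' @return An object of class `reference_map`: fields `reference`,
#'   `labels` (all members, reference included), `positions` (1..L),
#'   `ref_residues`, and `residues` (L x members character matrix,
#'   absent residues as `-`), plus `member_index` (L x members integer
#'   matrix giving each member's own ungapped residue index at each
#'   reference position, `NA` where absent).
#' @export
build_reference_map <- function(msa, reference_label) {
  if (!reference_label %in% msa$labels)
    stop("reference label '", reference_label, "' not found in alignment")
  cols <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
  ref <- cols[[reference_label]]
  keep <- which(ref != "-")
  L <- length(keep)
  labels <- msa$labels
  residues <- matrix("-", L, length(labels), dimnames = list(NULL, labels))
  member_index <- matrix(NA_integer_, L, length(labels),
                         dimnames = list(NULL, labels))
  for (lab in labels) {
    ch <- cols[[lab]]
    ungapped <- cumsum(ch != "-")
    residues[, lab] <- ch[keep]
    member_index[, lab] <- ifelse(ch[keep] == "-", NA_integer_, ungapped[keep])
  }
  structure(list(reference = reference_label, labels = labels,
                 positions = seq_len(L), ref_residues = ref[keep],
                 residues = residues, member_index = member_index),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("<reference_map> reference %s, %d positions, %d members\n",
              x$reference, length(x$positions), length(x$labels)))
  invisible(x)
}

#' Map a member's own residue numbering to reference positions
#'
#' @param map A `reference_map`.
#' @param label Member label.
#' @return Named integer vector: names are the member's own (ungapped,
#'   1-based) residue indices, values the reference positions they
#'   occupy.
#' @export
member_position_map <- function(map, label) {
  if (!label %in% map$labels) stop("label '", label, "' not in map")
  idx <- map$member_index[, label]
  ok <- !is.na(idx)
  setNames(map$positions[ok], idx[ok])
}

residue_table_new <- function(positions, ref_residues, isoforms, residues) {
  positions <- as.integer(positions)
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(residues == "" | nchar(residues) != 1L))
    stop("residue cells must be single characters")
  bad <- setdiff(unique(as.vector(residues)), c(AA_CODES, "-"))
  if (length(bad) > 0)
    stop("illegal residue character(s): ", paste(sQuote(bad), collapse = ", "))
  dimnames(residues) <- list(paste0(ref_residues, positions), isoforms)
  structure(list(positions = positions, ref_residues = ref_residues,
                 isoforms = isoforms, residues = residues),
            class = "residue_table")
}

#' Extract an isoform-by-position residue table
#'
#' Pulls the residues at selected reference positions for every family
#' member out of a [build_reference_map()] result — the operation that
#' produces an active-site residue table from an alignment. Row labels
#' combine the reference residue and position (e.g. `"N67"`).
#'
#' @param map A `reference_map`.
#' @param positions Integer vector of reference positions (ascending).
#' @return An object of class `residue_table`: fields `positions`,
#'   `ref_residues`, `isoforms`, and `residues` (positions x isoforms
#'   character matrix, absent residues as `-`).
#' @export
extract_residue_table <- function(map, positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0)
    return(residue_table_new(integer(0), character(0), map$labels,
                             matrix(character(0), 0, length(map$labels))))
  out <- setdiff(positions, map$positions)
  if (length(out) > 0)
    stop("position(s) outside reference range 1..",
         max(map$positions), ": ", paste(out, collapse = ", "))
  idx <- match(positions, map$positions)
  residue_table_new(positions, map$ref_residues[idx], map$labels,
                    map$residues[idx, , drop = FALSE])
}

#' @export
print.residue_table <- function(x, ...) {
  cat(sprintf("<residue_table> %d positions x %d isoforms\n",
              length(x$positions), length(x$isoforms)))
  print(x$residues, quote = FALSE)
  invisible(x)
}

#' Read / write a residue table as TSV
#'
#' The format is a header row of isoform labels preceded by a `residue`
#' column of reference position labels (reference residue + position,
#' e.g. `Y7`), one row per position. Round-tripping is lossless. Ragged
#' rows, duplicate or non-increasing positions, and malformed labels
#' are rejected.
#'
#' @param path File path.
#' @param table A `residue_table`.
#' @return `read_residue_table` returns a `residue_table`;
#'   `write_residue_table` returns `path` invisibly.
#' @examples
#' t4 <- read_residue_table(system.file("extdata", "table4_cleft.tsv",
#'                                      package = "isopocket"))
#' t4$residues["I91", "IX"]
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  lines <- lines[vapply(lines, length, 0L) > 0]
  widths <- vapply(lines, length, 0L)
  if (length(unique(widths)) != 1)
    stop("ragged residue-table TSV: rows have ", paste(unique(widths),
         collapse = "/"), " fields")
  isoforms <- lines[[1]][-1]
  rows <- lines[-1]
  labels <- vapply(rows, `[`, "", 1L)
  if (!all(grepl("^[A-Z][0-9]+$", labels)))
    stop("malformed position label(s): ",
         paste(labels[!grepl("^[A-Z][0-9]+$", labels)], collapse = ", "))
  positions <- as.integer(sub("^[A-Z]", "", labels))
  if (anyDuplicated(positions))
    stop("duplicate position(s): ",
         paste(positions[duplicated(positions)], collapse = ", "))
  residues <- matrix(as.character(unlist(lapply(rows, `[`, -1))),
                     nrow = length(rows), ncol = length(isoforms),
                     byrow = TRUE)
  residue_table_new(positions, substr(labels, 1, 1), isoforms, residues)
}

#' @rdname read_residue_table
#' @export
write_residue_table <- function(table, path) {
  df <- data.frame(residue = rownames(table$residues), table$residues,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled residue-table fixtures
#'
#' Returns the path of a residue table shipped with the package:
#' `"active_site"` — the 17-position active-site table of the 12
#' catalytically active human carbonic anhydrases (CA II numbering,
#' CA II stored as an explicit column); `"cleft"` — the 9-position
#' hydrophobic-cleft table of 11 isoforms used for hydrophobicity
#' totals; `"cleft_printed_totals"` — the totals printed alongside the
#' cleft table, used to flag computed-vs-printed disagreements;
#' `"identity"` — the published identity / conserved-count matrix of
#' the 12 isoforms.
#'
#' @param name One of `"active_site"`, `"cleft"`,
#'   `"cleft_printed_totals"`, `"identity"`.
#' @return File path inside the installed package.
#' @export
isopocket_fixture <- function(name = c("active_site", "cleft",
                                       "cleft_printed_totals", "identity")) {
  name <- match.arg(name)
  fn <- switch(name,
               active_site = "table3_active_site.tsv",
               cleft = "table4_cleft.tsv",
               cleft_printed_totals = "table4_printed_totals.tsv",
               identity = "table2_identity.tsv")
  path <- system.file("extdata", fn, package = "isopocket")
  if (!nzchar(path)) stop("fixture not found: ", fn)
  path
}
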