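#' Alignment parameters
#'
#' Scoring parameters for global pairwise and progressive alignment:
#' a substitution matrix name and affine gap penalties. A gap run of
#' length k costs `gap_open + k * gap_extend`. Defaults follow common
#' protein-alignment practice (BLOSUM62, open 10, extend 0.5).
#'
#' The substitution matrix is taken from the named score set shipped
#' with Biostrings; its `X` row and column are set to 0 so unknown
#' residues are alignment-neutral.
#'
#' @param matrix Substitution matrix name (any matrix data set exported
#'   by Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative gap extension penalty; must not exceed
#'   `gap_open`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(matrix), length(matrix) == 1L)
  stopifnot(is.numeric(gap_open), gap_open >= 0,
            is.numeric(gap_extend), gap_extend >= 0)
  if (gap_extend > gap_open)
    stop("gap_extend (", gap_extend, ") must not exceed gap_open (", gap_open, ")")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

# substitution matrix over AA_CODES, X row/column zeroed
submatrix <- function(params) {
  env <- new.env()
  data(list = params$matrix, package = "Biostrings", envir = env)
  m <- get(params$matrix, envir = env)
  missing <- setdiff(AA_CODES, rownames(m))
  if (length(missing) > 0)
    stop("substitution matrix ", params$matrix, " lacks residue(s): ",
         paste(missing, collapse = ", "))
  m <- m[AA_CODES, AA_CODES]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  m
}

encode_residues <- function(residues) {
  match(strsplit(residues, "")[[1]], AA_CODES)
}

apply_moves <- function(a_chars, b_chars, moves) {
  n <- length(moves)
  outa <- character(n); outb <- character(n)
  i <- 0L; j <- 0L
  for (k in seq_len(n)) {
    if (moves[k] == 1L) {
      i <- i + 1L; j <- j + 1L
      outa[k] <- a_chars[i]; outb[k] <- b_chars[j]
    } else if (moves[k] == 2L) {
      i <- i + 1L
      outa[k] <- a_chars[i]; outb[k] <- "-"
    } else {
      j <- j + 1L
      outa[k] <- "-"; outb[k] <- b_chars[j]
    }
  }
  list(a = paste(outa, collapse = ""), b = paste(outb, collapse = ""))
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment of two isoform sequences under
#' affine gap scoring (Gotoh's algorithm). Ties in the traceback are
#' broken deterministically, preferring diagonal over up over left.
#'
#' @param a,b [isoform_sequence()] records (or plain character scalars,
#'   which are converted with ids `"a"`/`"b"`).
#' @param params [alignment_params()].
#' @return An object of class `pairwise_alignment` with fields
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   and the input `ids`.
#' @examples
#' aln <- global_align(isoform_sequence("s1", "HEAGAWGHEE"),
#'                     isoform_sequence("s2", "PAWHEAE"))
#' percent_identity(aln)
#' @export
global_align <- function(a, b, params = alignment_params()) {
  if (is.character(a)) a <- isoform_sequence("a", a)
  if (is.character(b)) b <- isoform_sequence("b", b)
  sm <- submatrix(params)
  res <- .nw_align_cpp(encode_residues(a$residues), encode_residues(b$residues),
                       sm, params$gap_open, params$gap_extend)
  al <- apply_moves(strsplit(a$residues, "")[[1]],
                    strsplit(b$residues, "")[[1]], res$moves)
  structure(list(aligned_a = al$a, aligned_b = al$b, score = res$score,
                 ids = c(a$id, b$id)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s / %s  score %.1f  identity %.1f%%\n",
              x$ids[1], x$ids[2], x$score, percent_identity(x)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

aln_columns <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  list(a = a, b = b)
}

#' Percent identity of a pairwise alignment
#'
#' 100 times the fraction of identical columns among columns where both
#' sequences are non-gap (the co-aligned columns). Unknown residues
#' (`X`) are never counted as identical. Reported to one decimal.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percent identity in `[0, 100]`, rounded to one decimal.
#' @export
percent_identity <- function(aln) {
  cols <- aln_columns(aln)
  both <- cols$a != "-" & cols$b != "-"
  if (!any(both))
    stop("percent identity undefined: no co-aligned (both non-gap) columns")
  ident <- both & cols$a == cols$b & cols$a != "X"
  round(100 * sum(ident) / sum(both), 1)
}

#' Count conserved residues in a pairwise alignment
#'
#' The number of alignment columns carrying the identical residue in
#' both sequences (`X` never counts).
#'
#' @param aln A `pairwise_alignment`.
#' @return Non-negative integer count.
#' @export
conserved_count <- function(aln) {
  cols <- aln_columns(aln)
  sum(cols$a != "-" & cols$a == cols$b & cols$a != "X")
}

#' Pairwise identity and conserved-count matrices for a family
#'
#' Aligns every pair of family members globally and records the percent
#' identity and the conserved-residue count. Both matrices are symmetric;
#' the identity diagonal is exactly 100 and the conserved-count diagonal
#' is the sequence length.
#'
#' @param family List of [isoform_sequence()] records (at least two).
#' @param params [alignment_params()].
#' @return An object of class `identity_matrix` with fields `labels`,
#'   `identity` (numeric matrix, percent), `conserved` (integer matrix).
#' @seealso [write_identity_matrix()], [identity_to_distance()]
#' @export
identity_matrix <- function(family, params = alignment_params()) {
  if (length(family) < 2) stop("need at least two sequences")
  labels <- vapply(family, `[[`, "", "id")
  if (anyDuplicated(labels))
    stop("duplicate isoform labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(family)
  ident <- matrix(100, n, n, dimnames = list(labels, labels))
  cons <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(cons) <- vapply(family, function(s) nchar(s$residues), 0L)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      aln <- tryCatch(global_align(family[[i]], family[[j]], params),
                      error = function(e)
                        stop("alignment failed for pair ", labels[i], " / ",
                             labels[j], ": ", conditionMessage(e)))
      ident[i, j] <- ident[j, i] <- percent_identity(aln)
      cons[i, j] <- cons[j, i] <- conserved_count(aln)
    }
  }
  structure(list(labels = labels, identity = ident, conserved = cons),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d isoforms\n", length(x$labels)))
  m <- x$identity
  m[upper.tri(m)] <- x$conserved[upper.tri(m)]
  diag(m) <- NA
  print(m)
  invisible(x)
}

#' Write / read an identity matrix as TSV
#'
#' The file layout mirrors the classic family-comparison table: first
#' row and first column hold the isoform labels, the lower triangle
#' holds percent identities, the upper triangle holds conserved-residue
#' counts, and the diagonal is printed as `-`. On reading, diagonal
#' identities are restored to 100 and diagonal conserved counts (the
#' sequence lengths, which the layout does not store) are set to `NA`.
#'
#' @param m An `identity_matrix`.
#' @param path File path.
#' @return `write_identity_matrix` returns `path` invisibly;
#'   `read_identity_matrix` returns an `identity_matrix`.
#' @export
write_identity_matrix <- function(m, path) {
  out <- matrix("-", length(m$labels), length(m$labels))
  out[lower.tri(out)] <- sprintf("%.1f", m$identity[lower.tri(m$identity)])
  out[upper.tri(out)] <- as.character(m$conserved[upper.tri(m$conserved)])
  df <- data.frame(isoform = m$labels, out, check.names = FALSE)
  colnames(df) <- c("isoform", m$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_identity_matrix
#' @export
read_identity_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  labels <- df[[1]]
  if (!identical(colnames(df)[-1], labels))
    stop("identity matrix TSV: row and column labels disagree")
  raw <- as.matrix(df[, -1, drop = FALSE])
  n <- length(labels)
  ident <- matrix(100, n, n, dimnames = list(labels, labels))
  cons <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  ident[lower.tri(ident)] <- as.numeric(raw[lower.tri(raw)])
  ident[upper.tri(ident)] <- t(ident)[upper.tri(ident)]
  cons[upper.tri(cons)] <- as.integer(raw[upper.tri(raw)])
  cons[lower.tri(cons)] <- t(cons)[lower.tri(cons)]
  structure(list(labels = labels, identity = ident, conserved = cons),
            class = "identity_matrix")
}

# profile as integer matrix rows = sequences, 0 = gap
msa_to_codes <- function(rows) {
  t(vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    ifelse(ch == "-", 0L, match(ch, AA_CODES))
  }, integer(nchar(rows[[1]]))))
}

insert_gaps <- function(rows, moves, consume) {
  # consume: which move codes advance this profile (1 plus 2 or 3)
  vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    out <- character(length(moves))
    i <- 0L
    for (k in seq_along(moves)) {
      if (moves[k] %in% consume) { i <- i + 1L; out[k] <- ch[i] }
      else out[k] <- "-"
    }
    paste(out, collapse = "")
  }, "")
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by UPGMA on the pairwise identity-distance matrix
#' (distance = 100 - percent identity), then merges profiles pairwise in
#' guide-tree order with affine-gap profile-profile alignment. Gaps once
#' introduced are never removed ("once a gap, always a gap"), so
#' de-gapping any output row reproduces the corresponding input exactly.
#'
#' @param family List of [isoform_sequence()] records (at least two).
#' @param params [alignment_params()].
#' @return An object of class `msa`: fields `labels` and `rows` (named
#'   character vector of equal-length gapped strings, input order).
#' @seealso [build_reference_map()], [write_msa()]
#' @export
progressive_msa <- function(family, params = alignment_params()) {
  if (length(family) < 2) stop("need at least two sequences")
  labels <- vapply(family, `[[`, "", "id")
  if (length(family) == 2) {
    aln <- global_align(family[[1]], family[[2]], params)
    rows <- setNames(c(aln$aligned_a, aln$aligned_b), labels)
    return(structure(list(labels = labels, rows = rows), class = "msa"))
  }
  im <- identity_matrix(family, params)
  d <- identity_to_distance(im)
  merges <- upgma_merges(d$matrix, d$labels)
  sm <- submatrix(params)
  # profiles keyed by sorted member-label string
  profiles <- setNames(
    lapply(seq_along(family), function(i)
      setNames(family[[i]]$residues, labels[i])),
    labels)
  key <- function(members) paste(sort(members), collapse = "\r")
  for (i in seq_along(family)) names(profiles)[i] <- key(labels[i])
  for (m in merges) {
    A <- profiles[[key(m$left)]]
    B <- profiles[[key(m$right)]]
    res <- .profile_align_cpp(msa_to_codes(A), msa_to_codes(B), sm,
                              params$gap_open, params$gap_extend)
    merged <- c(setNames(insert_gaps(A, res$moves, c(1L, 2L)), names(A)),
                setNames(insert_gaps(B, res$moves, c(1L, 3L)), names(B)))
    profiles[[key(c(m$left, m$right))]] <- merged
  }
  rows <- profiles[[key(labels)]][labels]
  structure(list(labels = labels, rows = rows), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences, %d columns\n",
              length(x$rows), nchar(x$rows[[1]])))
  w <- max(nchar(x$labels))
  for (i in seq_along(x$rows))
    cat(sprintf(" %-*s %s\n", w, x$labels[i],
                if (nchar(x$rows[i]) > 70)
                  paste0(substr(x$rows[i], 1, 67), "...") else x$rows[i]))
  invisible(x)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  fam <- mapply(function(id, row)
    structure(list(id = id, residues = row), class = "isoform_sequence"),
    msa$labels, msa$rows, SIMPLIFY = FALSE)
  # bypass residue validation: rows legitimately contain '-'
  con <- file(path, "w")
  on.exit(close(con))
  for (s in fam) {
    writeLines(paste0(">", s$id), con)
    writeLines(s$residues, con)
  }
  invisible(path)
}
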