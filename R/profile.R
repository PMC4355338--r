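#' Hydropathy scales
#'
#' A hydropathy scale maps each of the 20 standard residues to a signed
#' hydrophobicity value. [kd_scale()] returns the Kyte-Doolittle scale
#' (range -4.5 for Arg to +4.5 for Ile); [read_hydropathy_scale()] loads
#' an alternative scale from a two-column TSV (residue, value) so other
#' scales can be swapped in. The scale must cover all 20 residues.
#'
#' @param path Path to a TSV with columns `residue` and `value`.
#' @return Named numeric vector of length 20 (class `hydropathy_scale`).
#' @examples
#' kd_scale()[["W"]]
#' @export
kd_scale <- function() {
  hydropathy_scale(c(
    I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5))
}

#' @rdname kd_scale
#' @export
read_hydropathy_scale <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric"))
  hydropathy_scale(setNames(df[[2]], df[[1]]))
}

hydropathy_scale <- function(values) {
  std <- setdiff(AA_CODES, "X")
  missing <- setdiff(std, names(values))
  if (length(missing) > 0)
    stop("hydropathy scale incomplete; missing: ",
         paste(missing, collapse = ", "))
  structure(values[std], class = "hydropathy_scale")
}

#' Hydropathy of a single residue
#'
#' Scale lookup for one standard residue. Unknown (`X`) and absent
#' (`-`) residues are rejected: pocket scoring requires known residues
#' at every position.
#'
#' @param residue One-letter residue code.
#' @param scale A hydropathy scale (default Kyte-Doolittle).
#' @return Signed hydropathy value.
#' @export
hydropathy <- function(residue, scale = kd_scale()) {
  stopifnot(length(residue) == 1L)
  if (!residue %in% names(scale))
    stop("no hydropathy value for residue '", residue,
         "' (unknown or absent residues cannot be scored)")
  unname(scale[[residue]])
}

# round half away from zero (so 8.5 -> 9, -8.5 -> -9)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Active-site cleft hydrophobicity of one isoform
#'
#' Sums the hydropathy values of one isoform's residues over all table
#' positions — the total used to rank isoform active sites from
#' hydrophilic to hydrophobic. The raw sum is reported to one decimal;
#' the total is additionally rounded half away from zero to an integer.
#' Any absent residue (`-`) in the column makes the total undefined and
#' is an error naming the position.
#'
#' @param table A `residue_table` (e.g. the bundled cleft fixture).
#' @param isoform Isoform column label.
#' @param scale Hydropathy scale (default Kyte-Doolittle).
#' @return An object of class `pocket_score`: fields `isoform`, `raw`
#'   (one decimal), `rounded` (integer), `positions`, `residues`.
#' @examples
#' t4 <- read_residue_table(isopocket_fixture("cleft"))
#' pocket_hydrophobicity(t4, "II")$rounded  # 26
#' @export
pocket_hydrophobicity <- function(table, isoform, scale = kd_scale()) {
  if (!isoform %in% table$isoforms)
    stop("isoform '", isoform, "' not in table")
  res <- table$residues[, isoform]
  absent <- table$positions[res == "-"]
  if (length(absent) > 0)
    stop("isoform '", isoform, "' has no residue at position(s) ",
         paste(absent, collapse = ", "), "; total undefined")
  vals <- vapply(res, hydropathy, 0, scale = scale)
  raw <- round(sum(vals), 1)
  structure(list(isoform = isoform, raw = raw,
                 rounded = as.integer(round_half_away(raw)),
                 positions = table$positions, residues = unname(res)),
            class = "pocket_score")
}

#' @export
print.pocket_score <- function(x, ...) {
  cat(sprintf("<pocket_score> %s: raw %.1f, rounded %d (%s)\n",
              x$isoform, x$raw, x$rounded, paste(x$residues, collapse = "")))
  invisible(x)
}

#' Cleft hydrophobicity score report for a whole table
#'
#' Applies [pocket_hydrophobicity()] to every isoform column. When
#' reference totals are supplied (e.g. previously published values),
#' each computed total is compared against them and disagreements are
#' flagged in the `flag` column — computed values are always reported
#' as computed, never adjusted to match.
#'
#' @param table A `residue_table`.
#' @param scale Hydropathy scale.
#' @param reference_totals Optional named numeric vector of reference
#'   totals (names = isoform labels).
#' @return A data.frame with columns `isoform`, `raw_sum`,
#'   `rounded_total`, and, when reference totals are given,
#'   `reference_total` and `flag` (`TRUE` where computed != reference).
#' @export
score_report <- function(table, scale = kd_scale(), reference_totals = NULL) {
  scores <- lapply(table$isoforms, pocket_hydrophobicity,
                   table = table, scale = scale)
  df <- data.frame(isoform = table$isoforms,
                   raw_sum = vapply(scores, `[[`, 0, "raw"),
                   rounded_total = vapply(scores, `[[`, 0L, "rounded"))
  if (!is.null(reference_totals)) {
    df$reference_total <- unname(reference_totals[df$isoform])
    df$flag <- !is.na(df$reference_total) &
      df$rounded_total != df$reference_total
  }
  df
}

column_residues <- function(table, position) {
  i <- match(position, table$positions)
  if (is.na(i)) stop("position ", position, " not in table")
  res <- table$residues[i, ]
  res <- res[res != "-"]
  if (length(res) == 0)
    stop("position ", position, ": no residues present (all absent)")
  res
}

#' Distinct residue count at a table position
#'
#' Number of distinct residues observed across isoforms at one
#' reference position, absent cells excluded. Fully conserved columns
#' score 1.
#'
#' @param table A `residue_table`.
#' @param position Reference position.
#' @return Integer count (>= 1).
#' @export
column_distinct <- function(table, position) {
  length(unique(column_residues(table, position)))
}

#' Shannon entropy of a table column
#'
#' Entropy (base 2, bits) of the residue frequency distribution at one
#' position; 0 for a fully conserved column, `log2(n)` when every
#' isoform differs.
#'
#' @inheritParams column_distinct
#' @return Entropy in bits.
#' @export
column_entropy <- function(table, position) {
  res <- column_residues(table, position)
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Hydropathy range of a table column
#'
#' Maximum minus minimum hydropathy over the residues observed at one
#' position — a physical-property counterpart to the symbolic
#' variability measures (a position holding both Ile and Arg spans the
#' full 9.0 units of the Kyte-Doolittle scale).
#'
#' @inheritParams column_distinct
#' @param scale Hydropathy scale.
#' @return Non-negative range.
#' @export
hydropathy_range <- function(table, position, scale = kd_scale()) {
  vals <- vapply(unique(column_residues(table, position)), hydropathy, 0,
                 scale = scale)
  max(vals) - min(vals)
}

# default cleft-face annotation sets (reference numbering); metadata
# only, they never affect scores or classification
CLEFT_HYDROPHILIC <- c(7L, 62L, 64L, 67L, 199L, 200L)
CLEFT_HYDROPHOBIC <- c(121L, 143L, 198L, 207L, 209L)

#' Per-position conservation profiles
#'
#' Computes, for every position of a residue table: the residue
#' multiset, the number of isoforms observed, the distinct-residue
#' count, Shannon entropy (bits), the hydropathy range, and the cleft
#' face annotation (hydrophilic / hydrophobic / none, from the default
#' annotation sets or user-supplied ones).
#'
#' @param table A `residue_table`.
#' @param scale Hydropathy scale.
#' @param hydrophilic,hydrophobic Integer vectors of reference
#'   positions annotated as the hydrophilic / hydrophobic cleft faces.
#' @return A data.frame, one row per position, with columns `position`,
#'   `residues`, `n`, `distinct`, `entropy_bits`, `hydropathy_range`,
#'   `cleft`.
#' @seealso [classify_positions()]
#' @export
position_profiles <- function(table, scale = kd_scale(),
                              hydrophilic = CLEFT_HYDROPHILIC,
                              hydrophobic = CLEFT_HYDROPHOBIC) {
  rows <- lapply(table$positions, function(p) {
    res <- column_residues(table, p)
    data.frame(position = p,
               residues = paste(res, collapse = ""),
               n = length(res),
               distinct = column_distinct(table, p),
               entropy_bits = column_entropy(table, p),
               hydropathy_range = hydropathy_range(table, p, scale))
  })
  df <- do.call(rbind, rows)
  df$cleft <- ifelse(df$position %in% hydrophilic, "hydrophilic",
                     ifelse(df$position %in% hydrophobic, "hydrophobic",
                            "none"))
  df
}

#' Classify positions as conserved, variable, or selective
#'
#' Classification rules: a position is `conserved` when its entropy is
#' zero (a single residue across the family), `variable` when its
#' entropy reaches the threshold, and `selective` when it is variable
#' *and* belongs to the ligand-contact set (rim positions whose
#' residues touch bound ligands — supplied explicitly or derived from a
#' structure with [ligand_contacts()]). Positions between the two
#' entropy regimes are labelled `intermediate`. Composition statistics
#' alone cannot decide selectivity: two positions can share an
#' identical residue-count profile while only one lines the ligand rim,
#' which is why the contact set is an explicit input. Positions with
#' fewer than two observed residues are reported but left
#' `unclassified`.
#'
#' Rows are ranked by decreasing (distinct count, entropy); rank 1 is
#' the family's variability hot-spot.
#'
#' @param profiles A profile data.frame from [position_profiles()].
#' @param entropy_threshold Entropy (bits) at or above which a position
#'   counts as variable; default 1.0 bit.
#' @param contact_positions Integer vector of ligand-contact reference
#'   positions gating the selective call (default 67, 91, 131 — the
#'   rim contact set of the carbonic anhydrase family).
#' @return The input data.frame with `classification` and `rank`
#'   columns added, ordered by rank.
#' @examples
#' t3 <- read_residue_table(isopocket_fixture("active_site"))
#' cls <- classify_positions(position_profiles(t3))
#' cls$position[cls$classification == "selective"]
#' @export
classify_positions <- function(profiles, entropy_threshold = 1.0,
                               contact_positions = c(67L, 91L, 131L)) {
  stopifnot(entropy_threshold >= 0)
  cls <- ifelse(profiles$n < 2, "unclassified",
         ifelse(profiles$entropy_bits == 0, "conserved",
         ifelse(profiles$entropy_bits >= entropy_threshold, "variable",
                "intermediate")))
  cls[cls == "variable" & profiles$position %in% contact_positions] <-
    "selective"
  profiles$classification <- cls
  ord <- order(-profiles$distinct, -profiles$entropy_bits, profiles$position)
  profiles$rank <- match(seq_len(nrow(profiles)), ord)
  profiles[ord, , drop = FALSE]
}

#' Count fully conserved positions of a table
#'
#' @param table A non-empty `residue_table`.
#' @return Number of positions whose distinct-residue count is 1.
#' @export
conserved_position_count <- function(table) {
  if (length(table$positions) == 0) stop("empty table")
  sum(vapply(table$positions, column_distinct, 0L, table = table) == 1L)
}
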