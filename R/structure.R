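site_structure_new <- function(label, atoms, metal = NA_integer_,
                               ligand = integer(0)) {
  stopifnot(is.data.frame(atoms),
            all(c("type", "element", "name", "resname", "chain", "resno",
                  "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) > 0 &&
      !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  structure(list(label = label, atoms = atoms, metal = metal,
                 ligand = ligand),
            class = "site_structure")
}

#' @export
print.site_structure <- function(x, ...) {
  cat(sprintf("<site_structure> %s: %d atoms, %d residues%s%s\n",
              x$label, nrow(x$atoms),
              nrow(unique(x$atoms[x$atoms$type == "ATOM",
                                  c("chain", "resno")])),
              if (!is.na(x$metal)) sprintf(", metal %s",
                                           x$atoms$element[x$metal]) else "",
              if (length(x$ligand) > 0)
                sprintf(", %d ligand atoms", length(x$ligand)) else ""))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeping only the first
#' model, dropping alternate locations other than blank/`A` and all
#' hydrogens. A HETATM zinc is auto-designated as the catalytic metal
#' center when it is unique; with multiple zincs the metal is left
#' unset and must be chosen by the caller. HETATM atoms that are
#' neither water nor the metal are recorded as ligand atoms.
#'
#' @param path Path to a PDB-format file.
#' @param label Structure label (default: file name without extension).
#' @return An object of class `site_structure`: fields `label`,
#'   `atoms` (data.frame: type, element, name, resname, chain, resno,
#'   x, y, z), `metal` (atom row index or `NA`), `ligand` (atom row
#'   indices).
#' @export
read_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0 || !any(at$type == "ATOM"))
    stop("no ATOM records in ", path)
  keep <- (is.na(at$alt) | at$alt %in% c("", "A")) &
    toupper(at$elesy) != "H"
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(type = at$type, element = toupper(at$elesy),
                      name = at$elety, resname = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = as.integer(at$resno),
                      x = at$x, y = at$y, z = at$z)
  zn <- which(atoms$type == "HETATM" & atoms$element == "ZN")
  metal <- if (length(zn) == 1) zn else NA_integer_
  if (length(zn) > 1)
    warning(length(zn), " zinc atoms in ", path,
            "; metal center left unset")
  ligand <- which(atoms$type == "HETATM" & !atoms$resname %in% c("HOH", "WAT"))
  ligand <- setdiff(ligand, metal)
  site_structure_new(label, atoms, metal, ligand)
}

#' Write a site structure as a PDB file
#'
#' Minimal fixed-column ATOM/HETATM writer used to round-trip
#' structures (including generated toy sites) through the standard
#' format. Coordinates are written to three decimals.
#'
#' @param s A `site_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  name <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                 sprintf("%-4s", a$name))
  lines <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$type, seq_len(nrow(a)), name, a$resname,
                   substr(a$chain, 1, 1), a$resno, a$x, a$y, a$z, 1, 0,
                   a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the RMSD
#' between two matched point sets, via singular value decomposition of
#' the cross-covariance matrix. When the SVD solution would be a
#' reflection, the sign of the smallest singular vector is flipped so
#' the result is always a proper rotation (determinant +1).
#'
#' @param moving,fixed Numeric n x 3 coordinate matrices with matched
#'   rows (n >= 3, not collinear).
#' @return An object of class `superposition`: `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length 3), `rmsd` (Angstrom,
#'   over the transformed moving set), `n` (matched points). Apply as
#'   `moving %*% t(rotation) + translation` (rows).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' th <- pi / 3
#' R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' kabsch_superpose(p %*% t(R) + 5, p)$rmsd  # ~0
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)))
    stop("point sets differ in size: ", nrow(moving), " vs ", nrow(fixed))
  if (ncol(moving) != 3) stop("coordinates must be n x 3")
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 matched points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  # collinearity check: centered sets must span a plane
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1]) ||
      svd(Q)$d[2] < 1e-8 * max(1, svd(Q)$d[1]))
    stop("degenerate (collinear) point set")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cf - R %*% cm)
  moved <- moving %*% t(R) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd, n = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d matched atoms, RMSD %.3f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Alpha-carbon coordinates of a structure
#'
#' @param s A `site_structure`.
#' @return Numeric matrix (n x 3) of CA coordinates, rownames = residue
#'   numbers.
#' @export
ca_coords <- function(s) {
  i <- which(s$atoms$type == "ATOM" & s$atoms$name == "CA")
  m <- as.matrix(s$atoms[i, c("x", "y", "z")])
  rownames(m) <- s$atoms$resno[i]
  m
}

#' Superpose one structure onto another by shared residue numbers
#'
#' Matches the alpha-carbons of residues present (under the same
#' numbering) in both structures and runs [kabsch_superpose()]. This is
#' the sequence-map-driven matched-atom choice appropriate for
#' homologous structures sharing a reference numbering.
#'
#' @param moving,fixed `site_structure` objects.
#' @return A `superposition` (see [kabsch_superpose()]).
#' @export
superpose_sites <- function(moving, fixed) {
  cm <- ca_coords(moving); cf <- ca_coords(fixed)
  shared <- intersect(rownames(cm), rownames(cf))
  if (length(shared) < 3)
    stop("fewer than 3 shared residue numbers with CA atoms")
  kabsch_superpose(cm[shared, , drop = FALSE], cf[shared, , drop = FALSE])
}

#' Residues within a cutoff of the catalytic center
#'
#' Returns the residues having at least one (non-hydrogen) atom within
#' `cutoff` of the center — by default the designated metal center,
#' with the default radius matching the ~15 Angstrom active-site
#' cavity.
#'
#' @param s A `site_structure`.
#' @param center Length-3 numeric center; default the metal atom.
#' @param cutoff Radius in Angstrom (> 0), default 15.
#' @return data.frame with columns `chain`, `resno`, `resname`, one
#'   row per residue, sorted by residue number.
#' @export
site_residues <- function(s, center = NULL, cutoff = 15) {
  stopifnot(cutoff > 0)
  if (is.null(center)) {
    if (is.na(s$metal))
      stop("no metal center designated and no center supplied")
    center <- as.numeric(s$atoms[s$metal, c("x", "y", "z")])
  }
  a <- s$atoms[s$atoms$type == "ATOM", , drop = FALSE]
  d2 <- (a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2
  hit <- a[d2 <= cutoff^2, c("chain", "resno", "resname")]
  hit <- unique(hit)
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Reference positions contacted by a bound ligand
#'
#' Finds protein residues with any atom within `cutoff` of any ligand
#' atom and maps their residue numbers to reference positions — this is
#' the ligand-contact set that gates the selective-pocket call in
#' [classify_positions()].
#'
#' @param s A `site_structure`.
#' @param ligand Atom row indices of the ligand; default the ligand
#'   atoms identified at parse time.
#' @param cutoff Heavy-atom contact distance in Angstrom, default 4.0.
#' @param position_map Optional named integer vector mapping the
#'   structure's residue numbers to reference positions (e.g. from
#'   [member_position_map()]). `NULL` means the structure is already
#'   reference-numbered. Residues without a mapping are reported in a
#'   warning and dropped, never fatal.
#' @return Sorted integer vector of reference positions.
#' @export
ligand_contacts <- function(s, ligand = s$ligand, cutoff = 4.0,
                            position_map = NULL) {
  if (length(ligand) == 0) stop("no ligand atoms")
  stopifnot(cutoff > 0)
  lig <- as.matrix(s$atoms[ligand, c("x", "y", "z")])
  a <- s$atoms[s$atoms$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) return(integer(0))
  prot <- as.matrix(a[, c("x", "y", "z")])
  near <- rep(FALSE, nrow(prot))
  for (k in seq_len(nrow(lig))) {
    d2 <- (prot[, 1] - lig[k, 1])^2 + (prot[, 2] - lig[k, 2])^2 +
      (prot[, 3] - lig[k, 3])^2
    near <- near | d2 <= cutoff^2
  }
  resno <- sort(unique(a$resno[near]))
  if (is.null(position_map)) return(as.integer(resno))
  mapped <- position_map[as.character(resno)]
  if (anyNA(mapped))
    warning("residue number(s) with no reference position: ",
            paste(resno[is.na(mapped)], collapse = ", "))
  sort(as.integer(mapped[!is.na(mapped)]))
}
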