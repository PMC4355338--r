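#' Configuration for a synthetic isoform family
#'
#' The generator emulates the architecture of an isoform family built
#' around a conserved catalytic core: a reference sequence is drawn
#' uniformly; every member copies it, substitutes residues at a
#' background per-site rate outside the special positions, holds the
#' invariant (catalytic, e.g. metal-coordinating) positions fixed, and
#' draws the planted variable ("selective pocket") positions uniformly
#' from per-position residue alphabets. Optionally one member carries a
#' planted insertion. Everything is reproducible from the seed.
#'
#' Defaults mirror the carbonic anhydrase study family: 12 members,
#' invariant positions 94/96/119 (the metal-coordinating triad in
#' reference numbering), one planted variable position 91 with the
#' 8-residue alphabet observed there, and a 5% background substitution
#' rate.
#'
#' @param n_isoforms Number of members (>= 2).
#' @param length Sequence length; all special positions must fit.
#' @param background_rate Per-site substitution probability in `[0, 1]`
#'   outside the special positions.
#' @param invariant_positions Integer positions held fixed in every
#'   member.
#' @param variable_positions Named list: element names are positions,
#'   values are character vectors (the residue alphabet drawn from,
#'   with replacement).
#' @param insertion `NULL`, or `list(member =, position =, length =)`
#'   planting an insertion of random residues after `position` in one
#'   member.
#' @param seed Integer random seed.
#' @return A `family_config` list.
#' @export
family_config <- function(n_isoforms = 12L, length = 150L,
                          background_rate = 0.05,
                          invariant_positions = c(94L, 96L, 119L),
                          variable_positions = list(
                            "91" = c("I", "F", "R", "K", "Q", "L", "T", "A")),
                          insertion = NULL, seed = 1L) {
  stopifnot(n_isoforms >= 2, length >= 1,
            background_rate >= 0, background_rate <= 1)
  var_pos <- as.integer(names(variable_positions))
  special <- c(invariant_positions, var_pos)
  if (anyDuplicated(special))
    stop("invariant and variable position sets must be disjoint")
  if (any(special < 1 | special > length))
    stop("special positions must lie within 1..length")
  if (!is.null(insertion)) {
    stopifnot(all(c("member", "position", "length") %in% names(insertion)),
              insertion$member >= 1, insertion$member <= n_isoforms,
              insertion$position >= 0, insertion$position <= length,
              insertion$length >= 1)
  }
  structure(list(n_isoforms = as.integer(n_isoforms),
                 length = as.integer(length),
                 background_rate = background_rate,
                 invariant_positions = as.integer(invariant_positions),
                 variable_positions = variable_positions,
                 insertion = insertion, seed = as.integer(seed)),
            class = "family_config")
}

STD_AA <- setdiff(AA_CODES, "X")

#' Generate a synthetic isoform family with known ground truth
#'
#' See [family_config()] for the generative model. Member labels are
#' `iso01`, `iso02`, ...; `iso01` shares the reference's numbering
#' (give it no planted insertion) and is the natural reference row for
#' downstream mapping.
#'
#' @param cfg A [family_config()].
#' @return A list with `family` (list of [isoform_sequence()]) and
#'   `truth`: the reference sequence, the realized residues drawn at
#'   each planted position per member (realized, not nominal,
#'   compositions), the invariant positions with their residue, the
#'   insertion spec, and the seed.
#' @examples
#' fam <- generate_family(family_config(seed = 7))
#' identity_matrix(fam$family)$identity["iso01", "iso02"]
#' @export
generate_family <- function(cfg) {
  with_seed(cfg$seed, {
    L <- cfg$length
    ref <- sample(STD_AA, L, replace = TRUE)
    var_pos <- as.integer(names(cfg$variable_positions))
    special <- c(cfg$invariant_positions, var_pos)
    labels <- sprintf("iso%02d", seq_len(cfg$n_isoforms))
    planted <- lapply(cfg$variable_positions, function(alpha)
      setNames(sample(alpha, cfg$n_isoforms, replace = TRUE), labels))
    family <- vector("list", cfg$n_isoforms)
    for (i in seq_len(cfg$n_isoforms)) {
      s <- ref
      bg <- setdiff(which(stats::runif(L) < cfg$background_rate), special)
      for (p in bg) s[p] <- sample(setdiff(STD_AA, s[p]), 1)
      for (k in seq_along(var_pos)) s[var_pos[k]] <- planted[[k]][i]
      if (!is.null(cfg$insertion) && cfg$insertion$member == i) {
        ins <- sample(STD_AA, cfg$insertion$length, replace = TRUE)
        s <- append(s, ins, after = cfg$insertion$position)
      }
      family[[i]] <- isoform_sequence(labels[i], paste(s, collapse = ""))
    }
    truth <- list(reference = paste(ref, collapse = ""),
                  planted = planted,
                  invariant_positions = cfg$invariant_positions,
                  invariant_residues = setNames(
                    ref[cfg$invariant_positions],
                    cfg$invariant_positions),
                  insertion = cfg$insertion, seed = cfg$seed)
    list(family = family, truth = truth)
  })
}

#' Configuration for a synthetic toy site structure
#'
#' Residues (one alpha-carbon each) are placed on directions of a
#' deterministic spherical (Fibonacci) lattice at planted distances
#' from a metal center at the origin; one ligand atom is placed 3.0
#' Angstrom radially outward of each planted contact residue; an
#' optional rigid motion (axis-angle rotation plus translation) and
#' Gaussian coordinate noise are applied to all atoms.
#'
#' @param distances Numeric vector of planted metal-to-residue
#'   distances (Angstrom, > 0); one residue per entry, residue numbers
#'   `1..n` unless `resno` is given.
#' @param resno Optional integer residue numbers.
#' @param contact_positions Residue numbers receiving a planted ligand
#'   atom.
#' @param axis,angle Rotation axis (length 3) and angle (radians).
#' @param translation Length-3 translation vector.
#' @param noise_sd Gaussian coordinate noise standard deviation (>= 0).
#' @param seed Integer random seed (used only for the noise).
#' @return A `structure_config` list.
#' @export
structure_config <- function(distances, resno = seq_along(distances),
                             contact_positions = integer(0),
                             axis = c(0, 0, 1), angle = 0,
                             translation = c(0, 0, 0),
                             noise_sd = 0, seed = 1L) {
  stopifnot(all(distances > 0), length(resno) == length(distances),
            noise_sd >= 0, length(axis) == 3, length(translation) == 3,
            all(contact_positions %in% resno))
  structure(list(distances = distances, resno = as.integer(resno),
                 contact_positions = as.integer(contact_positions),
                 axis = axis / sqrt(sum(axis^2)), angle = angle,
                 translation = translation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "structure_config")
}

rotation_from_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# deterministic well-separated unit directions (Fibonacci sphere)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a toy site structure with known ground truth
#'
#' See [structure_config()] for the construction. The returned truth
#' record stores the applied rotation matrix and translation and the
#' planted distance and contact sets, so superposition and
#' site-extraction results can be checked exactly.
#'
#' @param cfg A [structure_config()].
#' @return A list with `structure` (a `site_structure` whose metal is
#'   the zinc at the — possibly moved — origin) and `truth` (rotation,
#'   translation, distances, contact_positions, and the unmoved
#'   coordinates).
#' @export
generate_toy_structure <- function(cfg) {
  n <- length(cfg$distances)
  dirs <- fibonacci_directions(n)
  ca <- dirs * cfg$distances
  lig <- dirs[match(cfg$contact_positions, cfg$resno), , drop = FALSE] *
    (cfg$distances[match(cfg$contact_positions, cfg$resno)] + 3.0)
  coords <- rbind(ca, c(0, 0, 0), lig)
  unmoved <- coords
  R <- rotation_from_axis_angle(cfg$axis, cfg$angle)
  coords <- coords %*% t(R) +
    matrix(cfg$translation, nrow(coords), 3, byrow = TRUE)
  if (cfg$noise_sd > 0)
    coords <- coords + with_seed(cfg$seed,
      matrix(stats::rnorm(length(coords), sd = cfg$noise_sd), nrow(coords), 3))
  nlig <- length(cfg$contact_positions)
  atoms <- data.frame(
    type = c(rep("ATOM", n), "HETATM", rep("HETATM", nlig)),
    element = c(rep("C", n), "ZN", rep("C", nlig)),
    name = c(rep("CA", n), "ZN", sprintf("C%d", seq_len(nlig))),
    resname = c(rep("GLY", n), "ZN", rep("LIG", nlig)),
    chain = "A",
    resno = c(cfg$resno, 999L, rep(998L, nlig)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  s <- site_structure_new("toy", atoms, metal = n + 1L,
                          ligand = if (nlig > 0) n + 1L + seq_len(nlig)
                                   else integer(0))
  truth <- list(rotation = R, translation = cfg$translation,
                distances = setNames(cfg$distances, cfg$resno),
                contact_positions = cfg$contact_positions,
                unmoved = unmoved, seed = cfg$seed)
  list(structure = s, truth = truth)
}
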