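# Independent oracles and small fixture builders used across the suite.

# Substitution lookup shared by the oracles (BLOSUM62 with X zeroed,
# same score set the package uses -- the oracle independence is in the
# algorithm, not the score table).
oracle_submatrix <- function() {
  env <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

# Brute-force global affine-gap alignment score: plain recursive
# enumeration of every monotone alignment path (no dynamic
# programming, no memoization). A gap run of length k costs
# open + k * extend. Only feasible for short sequences.
brute_force_score <- function(a, b, sm, open, ext) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sm[ac[i], bc[j]] + rec(i + 1, j + 1, "d"))
    }
    if (i <= n) {
      cost <- if (prev == "u") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "u"))
    }
    if (j <= m) {
      cost <- if (prev == "l") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "l"))
    }
    best
  }
  rec(1, 1, "d")
}

random_peptide <- function(len) {
  paste(sample(setdiff(isopocket:::AA_CODES, "X"), len, replace = TRUE),
        collapse = "")
}

# Build a residue_table directly from a named list of residue strings
# (names = row labels like "N67"), bypassing file I/O.
make_table <- function(rows, isoforms) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c(paste(c("residue", isoforms), collapse = "\t"),
               vapply(names(rows), function(lab)
                 paste(c(lab, strsplit(rows[[lab]], "")[[1]]),
                       collapse = "\t"), "")),
             tmp)
  read_residue_table(tmp)
}

# Rotation-search oracle for superposition: minimize RMSD over Euler
# angles (translation handled by centroid matching) with multi-start
# BFGS; independent of the SVD route.
rotation_search_rmsd <- function(moving, fixed, starts = 8) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  euler <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(euler(ang)) - Q)^2)))
  best <- Inf
  for (s in seq_len(starts)) {
    a0 <- runif(3, -pi, pi)
    fit <- optim(a0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

table3 <- function() read_residue_table(isopocket_fixture("active_site"))
table4 <- function() read_residue_table(isopocket_fixture("cleft"))

table4_printed <- function() {
  df <- read.table(isopocket_fixture("cleft_printed_totals"),
                   header = TRUE, sep = "\t")
  setNames(df$printed_total, df$isoform)
}
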