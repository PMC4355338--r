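#' Convert an identity matrix to a distance matrix
#'
#' Distance between two isoforms is `100 - percent identity`, the
#' standard conversion for clustering a family by sequence similarity.
#' The diagonal is zero.
#'
#' @param m An [identity_matrix()].
#' @return An object of class `distance_matrix` with fields `labels`
#'   and `matrix` (symmetric, zero diagonal).
#' @export
identity_to_distance <- function(m) {
  d <- 100 - m$identity
  diag(d) <- 0
  structure(list(labels = m$labels, matrix = d), class = "distance_matrix")
}

#' Construct a distance matrix from a plain numeric matrix
#'
#' @param mat Symmetric numeric matrix with zero diagonal; dimnames
#'   supply the labels unless `labels` is given.
#' @param labels Optional character vector of labels.
#' @return A `distance_matrix`.
#' @export
distance_matrix <- function(mat, labels = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(labels)) stop("labels required (no dimnames on matrix)")
  if (!isSymmetric(unname(mat), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(diag(mat) != 0)) stop("distance matrix must have zero diagonal")
  if (any(mat < 0)) stop("distances must be non-negative")
  dimnames(mat) <- list(labels, labels)
  structure(list(labels = labels, matrix = mat), class = "distance_matrix")
}

# UPGMA agglomeration returning the merge list: each element has
# $left / $right (member label vectors) and $height (half the merge
# distance). Ties are broken by the lexicographically smallest pair of
# cluster representative labels, so the result is deterministic.
upgma_merges <- function(d, labels) {
  n <- length(labels)
  clusters <- as.list(labels)
  sizes <- rep(1, n)
  heights <- rep(0, n)
  D <- d
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        dij <- D[i, j]
        reps <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        keyv <- paste(reps, collapse = "\r")
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 && keyv < best_key)) {
          best_d <- dij; best <- c(i, j); best_key <- keyv
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    merges[[step]] <- list(left = clusters[[i]], right = clusters[[j]],
                           height = h,
                           height_left = heights[i], height_right = heights[j])
    # weighted-average (UPGMA) update
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    heights <- c(heights[keep], h)
  }
  merges
}

#' UPGMA cladogram from a distance matrix
#'
#' Standard unweighted pair-group (average linkage) agglomeration. The
#' height of each internal node is half the distance at which its two
#' children are merged, so the tree is ultrametric: every root-to-leaf
#' path has the same length. Ties in merge distance are resolved by the
#' lexicographically smallest pair of cluster labels, making the
#' topology deterministic under label permutation.
#'
#' @param d A `distance_matrix` (from [identity_to_distance()] or
#'   [distance_matrix()]).
#' @return A rooted `phylo` tree (see the ape package) with branch
#'   lengths equal to parent height minus child height.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(distance_matrix(m))
#' write_newick(tr)
#' @export
upgma <- function(d) {
  if (length(d$labels) < 2) stop("need at least two labels")
  merges <- upgma_merges(d$matrix, d$labels)
  frag <- setNames(as.list(d$labels), d$labels)
  hgt <- setNames(rep(0, length(d$labels)), d$labels)
  key <- function(members) paste(sort(members), collapse = "\r")
  names(frag) <- vapply(d$labels, key, "")
  names(hgt) <- names(frag)
  for (m in merges) {
    kl <- key(m$left); kr <- key(m$right)
    bl <- m$height - hgt[[kl]]
    br <- m$height - hgt[[kr]]
    k <- key(c(m$left, m$right))
    frag[[k]] <- sprintf("(%s:%.10g,%s:%.10g)", frag[[kl]], bl, frag[[kr]], br)
    hgt[[k]] <- m$height
  }
  newick <- paste0(frag[[key(d$labels)]], ";")
  ape::read.tree(text = newick)
}

#' Serialize a cladogram to Newick
#'
#' Branch lengths are parent height minus child height; the string is
#' terminated by `;`. Round-tripping through [ape::read.tree()]
#' recovers topology and heights.
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Root-to-leaf path lengths of a tree
#'
#' Utility for checking ultrametricity: returns the summed branch
#' length from the root to each tip.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Named numeric vector, one entry per tip.
#' @export
leaf_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  setNames(depths[seq_len(nt)], tree$tip.label)
}
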