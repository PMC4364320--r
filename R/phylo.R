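# Distance-based phylogenetics: pairwise p-distances from global alignments
# and a classical neighbor-joining implementation with deterministic
# tie-breaking, returning standard `ape` trees.

#' Pairwise p-distance matrix
#'
#' Each pair is globally aligned and the p-distance is the proportion of
#' mismatching columns among compared columns, gap columns excluded
#' (pairwise deletion). p-distances lie in [0, 1]; they are not guaranteed
#' to satisfy the triangle inequality.
#'
#' @param sequences Named character vector (>= 3 nucleotide sequences).
#' @param scoring Alignment scoring as in [global_identity()].
#' @return Symmetric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(sequences, scoring = DEFAULT_ALN) {
  n <- length(sequences)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  set <- Biostrings::DNAStringSet(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (j in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      set[seq_len(j - 1L)], set[[j]], type = "global",
      substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    ps <- as.character(Biostrings::alignedPattern(aln))
    ss <- as.character(Biostrings::alignedSubject(aln))
    for (i in seq_len(j - 1L)) {
      p <- strsplit(ps[i], "")[[1]]
      s <- strsplit(ss[i], "")[[1]]
      keep <- p != "-" & s != "-"
      d[i, j] <- d[j, i] <- sum(p[keep] != s[keep]) / sum(keep)
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must carry taxon labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  if (any(!is.finite(d)) || any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop("distances must be finite, nonnegative, with zero diagonal")
  }
  invisible(d)
}

#' Neighbor-joining tree reconstruction
#'
#' Classical NJ (Q-matrix pair selection and the standard branch-length
#' formulas). On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly. Ties in the Q minimization are
#' broken by the lexicographically smallest taxon pair (each cluster ranked
#' by its smallest leaf label), and negative branch lengths are clamped to
#' zero with the deficit moved to the sibling branch, so reconstruction is
#' fully deterministic.
#'
#' @param d Symmetric distance matrix with taxon labels (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  frag <- labs
  key <- labs
  D <- d
  fmt <- function(x) sprintf("%.6f", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    best <- cand[order(pair_key)[1], ]
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- pmax(dk, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(D2) <- colnames(D2) <- key
    D <- D2
  }
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(x), frag[2], fmt(y), frag[3], fmt(z))
  ape::read.tree(text = nwk)
}

#' Monophyly of leaf labels on an unrooted tree
#'
#' A label is monophyletic when some edge bipartition of the tree separates
#' exactly its leaves from the rest (single-leaf labels are trivially
#' monophyletic).
#'
#' @param tree An `ape::phylo` tree.
#' @param labels Named character vector mapping every tip label to a group
#'   label.
#' @return Named logical vector, one entry per group label.
#' @export
check_monophyly <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    stop("unlabeled leaf/leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  }
  labels <- labels[tips]
  n <- length(tips)
  # tip sets below each node (postorder accumulation over the edge matrix)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(po$edge))
  for (t in seq_len(n)) desc[[t]] <- t
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  parts <- unique(lapply(po$edge[, 2], function(ch) sort(desc[[ch]])))
  out <- logical(0)
  for (lab in unique(labels)) {
    set <- sort(unname(which(labels == lab)))
    ok <- length(set) %in% c(1L, n) ||
      any(vapply(parts, function(p) {
        identical(p, set) || identical(p, sort(setdiff(seq_len(n), set)))
      }, logical(1)))
    out[lab] <- ok
  }
  out
}
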