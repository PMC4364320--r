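# Independent oracles used only by tests: a small affine-gap global aligner
# and an exhaustive least-squares topology search.

# Needleman-Wunsch with affine gaps (Gotoh), returning the aligned strings.
# O(nm) in plain R; intended for short oracle sequences only.
nw_align <- function(a, b, match = 2, mismatch = -3, gap_open = 7, gap_extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  # traceback
  ai <- character(); bi <- character()
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1 && i > 1 && j > 1) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      ai <- c(x[i - 1], ai); bi <- c(y[j - 1], bi)
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2 || j == 1) {
      from_m <- isTRUE(all.equal(X[i, j], M[i - 1, j] - gap_open - gap_extend))
      ai <- c(x[i - 1], ai); bi <- c("-", bi)
      i <- i - 1
      state <- if (from_m) 1 else 2
    } else {
      from_m <- isTRUE(all.equal(Y[i, j], M[i, j - 1] - gap_open - gap_extend))
      ai <- c("-", ai); bi <- c(y[j - 1], bi)
      j <- j - 1
      state <- if (from_m) 1 else 3
    }
  }
  list(a = paste(ai, collapse = ""), b = paste(bi, collapse = ""),
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

nw_identity <- function(a, b, ...) {
  al <- nw_align(a, b, ...)
  p <- strsplit(al$a, "")[[1]]; s <- strsplit(al$b, "")[[1]]
  sum(p == s & p != "-") / length(p)
}

# Ordinary-least-squares branch lengths of a fixed topology for a distance
# matrix; returns the residual sum of squares.
ls_fit_rss <- function(topology, d) {
  tips <- topology$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  nedge <- nrow(topology$edge)
  A <- matrix(0, nrow(pairs), nedge)
  # edges on the path between two tips: via node paths to the root
  parent_of <- integer(max(topology$edge))
  edge_of <- integer(max(topology$edge))
  for (e in seq_len(nedge)) {
    parent_of[topology$edge[e, 2]] <- topology$edge[e, 1]
    edge_of[topology$edge[e, 2]] <- e
  }
  root <- setdiff(unique(topology$edge[, 1]), topology$edge[, 2])
  path_to_root <- function(v) {
    out <- integer()
    while (v != root) {
      out <- c(out, edge_of[v])
      v <- parent_of[v]
    }
    out
  }
  paths <- lapply(seq_len(n), path_to_root)
  for (k in seq_len(nrow(pairs))) {
    e1 <- paths[[pairs[k, 1]]]; e2 <- paths[[pairs[k, 2]]]
    onpath <- union(setdiff(e1, e2), setdiff(e2, e1))
    A[k, onpath] <- 1
  }
  b <- d[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- stats::lm.fit(A, b)
  sum(fit$residuals^2)
}

# random unrooted tree with positive branch lengths and labelled tips
random_additive_tree <- function(n, min_len = 0.1, max_len = 1) {
  t0 <- ape::rtree(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
  t0$edge.length <- stats::runif(length(t0$edge.length), min_len, max_len)
  t0
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
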