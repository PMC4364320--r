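# Clustering of cloned sequences into genes and named allelic variants.
#
# Genes are single-linkage components at a global nucleotide identity
# threshold, so allelic series differing by repeat-domain length chain into
# one gene; within a gene every distinct sequence is a variant. Naming
# follows the fragment-size convention: the gene takes the LMWGS1 size of
# its most frequent variant, and same-size variants are distinguished by
# letters in descending frequency order.

DEFAULT_ALN <- list(match = 2, mismatch = -3, gap_open = 7, gap_extend = 1)

#' Global pairwise identity of two nucleotide sequences
#'
#' End-to-end alignment with affine gaps; identity is matches divided by
#' alignment columns, gap columns counted in the denominator, so long indels
#' lower identity proportionally. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return List with `identity` (fraction) and `alignment` (the
#'   `PairwiseAlignments` object).
#' @export
global_identity <- function(seq_a, seq_b, scoring = DEFAULT_ALN) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(identity = sum(p == s & p != "-") / length(p), alignment = aln)
}

#' Pairwise global identity matrix
#'
#' @param sequences Named character vector (>= 2 sequences).
#' @param scoring As in [global_identity()].
#' @return Symmetric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(sequences, scoring = DEFAULT_ALN) {
  n <- length(sequences)
  stopifnot(n >= 2L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  set <- Biostrings::DNAStringSet(sequences)
  idm <- matrix(1, n, n, dimnames = list(names(sequences), names(sequences)))
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
      idm[i, j] <- idm[j, i] <- sum(p == s & p != "-") / length(p)
    }
  }
  idm
}

# connected components of the >= threshold graph (single linkage)
identity_components <- function(idm, threshold) {
  n <- nrow(idm)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(idm[v, ] >= threshold & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cluster sequences into genes and named allelic variants
#'
#' @param sequences Named character vector of distinct variant sequences
#'   (duplicates are collapsed, accumulating their accession counts).
#' @param lmwgs1_sizes Named integer vector of LMWGS1 fragment sizes (from
#'   the marker module or truth); `NA` allowed (theoretical naming falls back
#'   to the representative's size).
#' @param accession_counts Named numeric vector: accessions carrying each
#'   sequence.
#' @param t_gene Single-linkage identity threshold for gene membership.
#' @param naming_prefix Prefix for gene/variant display names.
#' @param identity Optional precomputed [identity_matrix()] (must cover all
#'   sequence names); when supplied no alignment is run.
#' @param scoring Alignment scoring, as [global_identity()].
#' @return Object of class `lmwgs_catalog`: list with `genes` and `variants`
#'   tibbles, `naming_prefix`, `t_gene`.
#' @export
cluster_variants <- function(sequences, lmwgs1_sizes, accession_counts,
                             t_gene = 0.95, naming_prefix = "TuA3-",
                             identity = NULL, scoring = DEFAULT_ALN) {
  if (length(sequences) == 0) stop("no sequences to cluster")
  ids <- sort(names(sequences))
  sequences <- sequences[ids]
  lmwgs1_sizes <- lmwgs1_sizes[ids]
  accession_counts <- accession_counts[ids]
  if (length(sequences) == 1L) {
    comp <- 1L
  } else {
    idm <- if (is.null(identity)) identity_matrix(sequences, scoring) else {
      identity[ids, ids, drop = FALSE]
    }
    comp <- identity_components(idm, t_gene)
  }
  v <- tibble::tibble(sequence_id = ids,
                      size = as.integer(lmwgs1_sizes),
                      accession_count = as.numeric(accession_counts),
                      component = comp)
  genes <- vector("list", max(comp))
  variants <- vector("list", max(comp))
  for (k in sort(unique(comp))) {
    g <- v[v$component == k, ]
    # representative: most frequent, ties by smaller size then lexicographic id
    g <- g[order(-g$accession_count, g$size, g$sequence_id), ]
    rep_size <- g$size[1]
    if (is.na(rep_size)) rep_size <- min(g$size, na.rm = TRUE)
    gene_name <- paste0(naming_prefix, rep_size)
    # letter suffixes for same-size variants, descending frequency
    g$variant_name <- NA_character_
    for (s in unique(g$size)) {
      idx <- which(g$size == s)
      base <- paste0(naming_prefix, ifelse(is.na(s), paste0("x", k), s))
      g$variant_name[idx] <- if (length(idx) == 1L) base else {
        paste0(base, letters[seq_along(idx)])
      }
    }
    genes[[k]] <- tibble::tibble(gene_name = gene_name,
                                 representative_variant = g$variant_name[1],
                                 n_variants = nrow(g),
                                 accession_count = sum(g$accession_count))
    g$gene_name <- gene_name
    variants[[k]] <- g[, c("gene_name", "variant_name", "sequence_id",
                           "size", "accession_count")]
  }
  genes <- dplyr::bind_rows(genes)
  genes <- genes[order(genes$gene_name), ]
  variants <- dplyr::bind_rows(variants)
  variants <- variants[order(variants$gene_name, variants$variant_name), ]
  structure(list(genes = genes, variants = variants,
                 naming_prefix = naming_prefix, t_gene = t_gene),
            class = "lmwgs_catalog")
}

#' @export
print.lmwgs_catalog <- function(x, ...) {
  cat(sprintf("<lmwgs_catalog> %d genes, %d variants (t_gene = %.2f)\n",
              nrow(x$genes), nrow(x$variants), x$t_gene))
  print(x$genes)
  invisible(x)
}

#' Per-variant accession counts and population percentages
#'
#' @param genotype_table Accession-level genotype table with a `variants`
#'   list-column (e.g. from [table2_fixture()]).
#' @param variants Character vector of catalog variant names (or an
#'   `lmwgs_catalog`); genotypes referencing unknown variants raise a
#'   consistency error.
#' @return Tibble `variant`, `count`, `percent` (2 decimals, half-up).
#' @export
variant_frequencies <- function(genotype_table, variants) {
  if (inherits(variants, "lmwgs_catalog")) variants <- variants$variants$variant_name
  carried <- unlist(genotype_table$variants)
  orphan <- setdiff(unique(carried), variants)
  if (length(orphan) > 0) {
    stop("genotype table references variant(s) absent from the catalog: ",
         paste(orphan, collapse = ", "))
  }
  n <- nrow(genotype_table)
  counts <- unname(vapply(variants, function(v) {
    sum(vapply(genotype_table$variants, function(set) v %in% set, logical(1)))
  }, numeric(1)))
  tibble::tibble(variant = variants,
                 count = as.integer(counts),
                 percent = round_half_up(100 * counts / n, 2))
}

#' Variant groups with identical accession support (candidate haplotypes)
#'
#' Variants whose supporting accession sets coincide exactly co-segregate;
#' groups of two or more are reported with their support counts.
#'
#' @param genotype_table As in [variant_frequencies()].
#' @return Tibble `variants` (list-column), `n_variants`, `support`.
#' @export
haplotype_cosegregation <- function(genotype_table) {
  carried <- unique(unlist(genotype_table$variants))
  supp <- lapply(carried, function(v) {
    genotype_table$accession_id[
      vapply(genotype_table$variants, function(set) v %in% set, logical(1))]
  })
  key <- vapply(supp, function(s) paste(sort(s), collapse = ","), character(1))
  out <- lapply(unique(key[duplicated(key)]), function(k) {
    members <- sort(carried[key == k])
    tibble::tibble(variants = list(members),
                   n_variants = length(members),
                   support = length(strsplit(k, ",", fixed = TRUE)[[1]]))
  })
  if (length(out) == 0) {
    return(tibble::tibble(variants = list(), n_variants = integer(),
                          support = integer()))
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$support), ]
}

# round-half-up to `digits` decimals (matches printed-table style)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
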