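# Readers/writers for the package's external formats: FASTA, TSV, Newick.

#' Read gene sequences from a FASTA file
#'
#' Accepts wrapped or unwrapped records and IUPAC nucleotide codes; malformed
#' records are rejected with the offending line number.
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA at line ", nonempty[1], ": expected a '>' header")
  }
  ids <- character(); seqs <- character(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      id <- trimws(sub("^>", "", ln))
      if (!nzchar(id)) stop("malformed FASTA at line ", i, ": empty header")
      ids <- c(ids, id); seqs <- c(seqs, ""); cur <- length(seqs)
    } else {
      up <- toupper(ln)
      if (grepl("[^ACGTRYSWKMBDHVN]", up)) {
        stop("illegal sequence character at line ", i, ": '",
             regmatches(up, regexpr("[^ACGTRYSWKMBDHVN]", up)), "'")
      }
      seqs[cur] <- paste0(seqs[cur], up)
    }
  }
  if (any(!nzchar(seqs))) {
    stop("FASTA record without sequence: ", ids[which(!nzchar(seqs))[1]])
  }
  stats::setNames(seqs, ids)
}

#' Write gene sequences to a wrapped FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line wrap (default 60 columns).
#' @return Invisibly, `path`.
#' @export
write_gene_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read/write tab-separated tables with headers
#' @param path File path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' @param x Data frame.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write Newick trees
#' @param path File path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @param tree An `ape::phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
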