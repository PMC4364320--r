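# Realization of a configured population as sequences with full truth labels.

# Deterministic per-variant edits: the representative variant of each gene is
# the unedited template; every other variant carries a variant-specific set of
# third-position SNPs, and pseudo-gene variants carry TAG stops at fixed
# offsets inside their reported domains.
STOP_OFFSETS <- c("repetitive" = 19L, "C-terminal I" = 25L,
                  "C-terminal II" = 10L, "C-terminal III" = 20L)

variant_template <- function(config, gene, type, size) {
  gene_template(gene, type, size = size,
                repeat_motif = config$motifs[[gene]],
                absent_sets = config$absent_sets[[gene]] %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SNP-eligible codon indices (1-based aa in the full protein): repetitive
# domain beyond its first two residues, plus unprotected non-cysteine
# C-terminal positions. Primer anchors and the type-diagnostic N-terminus are
# excluded so designed variants never disturb genotyping or typing.
snp_eligible <- function(asm) {
  t <- asm$template
  pre <- 20L + nchar(t$n_terminal)
  rep_len <- nchar(t$repeat_intro) + 8L * t$repeat_count
  rep_idx <- seq(pre + 3L, pre + rep_len)
  ct_start <- pre + rep_len
  ct1 <- ct_start + setdiff(seq_len(CTERM1_LEN), CTERM1_PROTECTED)
  ct2 <- ct_start + CTERM1_LEN + seq_len(CTERM2_LEN - 1L)
  ct3 <- ct_start + CTERM1_LEN + CTERM2_LEN + setdiff(seq_len(CTERM3_LEN), 10L)
  c(rep_idx, ct1, ct2, ct3)
}

variant_edits <- function(asm, variant, n_snps, stop_domains) {
  snps <- integer()
  if (n_snps > 0) {
    elig <- snp_eligible(asm)
    u <- lcg_runif(length(elig), mix_seed(salt_hash("variant-snp"), variant))
    snps <- elig[order(u)][seq_len(min(n_snps, length(elig)))]
  }
  stops <- integer()
  if (!is.na(stop_domains) && stop_domains != "none" && nzchar(stop_domains)) {
    for (dom in strsplit(stop_domains, ";", fixed = TRUE)[[1]]) {
      dom <- trimws(dom)
      d <- asm$domains[[dom]]
      if (is.null(d)) stop("unknown stop domain '", dom, "' for ", variant)
      mature0 <- d[1] + STOP_OFFSETS[[dom]]
      stops <- c(stops, mature0 + asm$mature_start + 1L)
    }
  }
  list(snps = snps, stops = stops)
}

# Number of designed SNPs per variant: 0 for the representative, 3 + 2j for
# the j-th other variant of the gene (alphabetical order).
variant_n_snps <- function(config) {
  v <- config$variants
  n <- integer(nrow(v))
  for (g in unique(v$gene)) {
    idx <- which(v$gene == g)
    non_rep <- idx[!v$representative[idx]]
    non_rep <- non_rep[order(v$variant[non_rep])]
    n[non_rep] <- 3L + 2L * (seq_along(non_rep) - 1L)
  }
  n
}

# Assemble the designed (pre-mutation) sequence of configured variant i.
designed_assembly <- function(config, i, n_snps) {
  v <- config$variants
  t <- variant_template(config, v$gene[i], v$type[i], v$size[i])
  ed <- variant_edits(assemble_gene(t), v$variant[i], n_snps[i], v$stop_domains[i])
  assemble_gene(t, snps = ed$snps, stops = ed$stops)
}

# Build the deterministic base sequence of every configured variant.
build_variant_sequences <- function(config) {
  v <- config$variants
  n_snps <- variant_n_snps(config)
  out <- character(nrow(v))
  truths <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    asm <- designed_assembly(config, i, n_snps)
    out[i] <- asm$dna
    truths[[i]] <- gene_truth(asm, variant_id = v$variant[i])
  }
  seqs <- stats::setNames(out, v$variant)
  if (anyDuplicated(seqs)) {
    stop("internal error: designed variant sequences are not all distinct")
  }
  list(sequences = seqs, truth = dplyr::bind_rows(truths))
}

#' Generate a synthetic LMW-GS population
#'
#' Realizes a [population_config()] as per-accession sets of gene sequences:
#' every configured allelic variant gets a deterministic base sequence
#' (identical for all carriers at zero mutation), genotypes are expanded into
#' accessions by the regional counts, and the mutation model is applied per
#' accession and gene on top of the designed variant differences.
#'
#' @param config An `lmwgs_popconfig`.
#' @param mutations A [mutation_spec()]; the default applies no mutation, so
#'   two runs are byte-identical and downstream analyses recover the
#'   configured truth exactly.
#' @return A list of class `lmwgs_population`:
#'   * `accessions`: tibble `accession_id`, `region`, `genotype`.
#'   * `sequences`: named list, accession -> named character vector of gene
#'     sequences (names are variant labels).
#'   * `variant_truth`: per-variant truth annotation tibble.
#'   * `sequence_truth`: one truth row per emitted sequence.
#' @export
make_population <- function(config, mutations = mutation_spec()) {
  stopifnot(inherits(config, "lmwgs_popconfig"))
  base <- build_variant_sequences(config)
  acc <- expand_accessions(config$region_counts)
  vsets <- split(config$genotype_variants$variant, config$genotype_variants$genotype)
  v <- config$variants
  n_snps <- variant_n_snps(config)
  mutate_any <- mutations$snp_rate > 0 || mutations$indel_rate > 0 ||
    mutations$premature_stop_probability > 0

  seqs <- vector("list", nrow(acc))
  seq_truth <- vector("list", nrow(acc))
  for (a in seq_len(nrow(acc))) {
    vars <- sort(vsets[[acc$genotype[a]]])
    if (!mutate_any) {
      seqs[[a]] <- base$sequences[vars]
      st <- base$truth[match(vars, base$truth$variant_id), ]
    } else {
      got <- character(length(vars))
      rows <- vector("list", length(vars))
      for (k in seq_along(vars)) {
        i <- match(vars[k], v$variant)
        # re-derive the designed base, then mutate in a per-(accession, gene)
        # stream so generation order is irrelevant
        asm <- designed_assembly(config, i, n_snps)
        stream <- mix_seed(mix_seed(mutations$seed, acc$accession_id[a]), vars[k])
        mut <- apply_mutations(asm, mutations, stream)
        got[k] <- mut$dna
        rows[[k]] <- gene_truth(asm, mut, variant_id = vars[k])
      }
      seqs[[a]] <- stats::setNames(got, vars)
      st <- dplyr::bind_rows(rows)
    }
    st$accession_id <- acc$accession_id[a]
    seq_truth[[a]] <- st
  }
  names(seqs) <- acc$accession_id
  structure(list(accessions = acc, sequences = seqs,
                 variant_truth = base$truth,
                 sequence_truth = dplyr::bind_rows(seq_truth),
                 config = config),
            class = "lmwgs_population")
}

#' @export
print.lmwgs_population <- function(x, ...) {
  cat(sprintf("<lmwgs_population> %d accessions, %d configured variants, %d genes\n",
              nrow(x$accessions), nrow(x$config$variants),
              length(unique(x$config$variants$gene))))
  invisible(x)
}

#' Write a population to disk
#'
#' One wrapped FASTA per accession, a metadata TSV (`accession_id`, `region`)
#' and a truth TSV.
#'
#' @param population An `lmwgs_population`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in names(population$sequences)) {
    s <- population$sequences[[a]]
    set <- Biostrings::DNAStringSet(s)
    names(set) <- paste0(a, "|", names(s))
    Biostrings::writeXStringSet(set, file.path(dir, paste0(a, ".fasta")), width = 60L)
  }
  utils::write.table(population$accessions[, c("accession_id", "region")],
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- population$sequence_truth
  tr$domains <- vapply(tr$domains, function(d) {
    paste(sprintf("%s:%d-%d", names(d), vapply(d, `[`, integer(1), 1),
                  vapply(d, `[`, integer(1), 2)), collapse = ";")
  }, character(1))
  tr$cys_positions <- vapply(tr$cys_positions, paste, character(1), collapse = ",")
  utils::write.table(tr, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
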