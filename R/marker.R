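# In-silico reproduction of the three-primer-set LMW-GS molecular marker
# system: theoretical amplicon sizes, per-accession fragment profiles with
# cross-set correspondence triplets, and genotype calling.

#' The three conserved marker primer sets
#'
#' Forward primers sit in the conserved block upstream of the start codon;
#' reverse primers (given 5'->3' on the minus strand) land in the two
#' invariant anchor blocks of the C-terminal I domain. These are the primer
#' sequences embedded by the synthetic generator, so the marker system is
#' closed: real primer sequences may be supplied in the same format.
#'
#' @return Tibble with columns `name`, `forward`, `reverse`.
#' @export
lmwgs_primer_sets <- function() {
  blk <- shared_5p_block()
  anchor_nt <- encode_protein(substr(paste0(CTERM1_ANCH_A, CTERM1_MID,
                                            CTERM1_ANCH_B), 1L, 47L))
  tibble::tibble(
    name = names(F_WINDOWS),
    forward = vapply(names(F_WINDOWS), function(s) {
      w <- F_WINDOWS[[s]]; substr(blk, w[1], w[2])
    }, character(1)),
    reverse = vapply(names(F_WINDOWS), function(s) {
      w <- R_WINDOWS[[s]]; revcomp(substr(anchor_nt, w[1], w[2]))
    }, character(1))
  )
}

#' Theoretical amplicon size of one primer set on one gene
#'
#' Exact-match search for the forward primer and the reverse complement of
#' the reverse primer; the size is the length of the amplified interval,
#' inclusive of both primers. A missing or mutated landing site yields `NA`
#' (the "N" sentinel: not amplified).
#'
#' @param dna Gene sequence.
#' @param primer_set One row of [lmwgs_primer_sets()] (or a list with
#'   `name`, `forward`, `reverse`).
#' @return Integer size in bp, or `NA_integer_` for N.
#' @export
virtual_amplicon <- function(dna, primer_set) {
  if (nchar(primer_set$forward) < 15L || nchar(primer_set$reverse) < 15L) {
    stop("primer shorter than 15 nt in set ", primer_set$name)
  }
  fhits <- gregexpr(primer_set$forward, dna, fixed = TRUE)[[1]]
  rsite <- revcomp(primer_set$reverse)
  rhits <- gregexpr(rsite, dna, fixed = TRUE)[[1]]
  if (fhits[1] == -1L || rhits[1] == -1L) return(NA_integer_)
  if (length(fhits) > 1L) {
    stop("ambiguous amplification: multiple forward sites at positions ",
         paste(fhits, collapse = ", "), " (", primer_set$name, ")")
  }
  if (length(rhits) > 1L) {
    stop("ambiguous amplification: multiple reverse sites at positions ",
         paste(rhits, collapse = ", "), " (", primer_set$name, ")")
  }
  end <- rhits[1] + nchar(rsite) - 1L
  if (end <= fhits[1]) return(NA_integer_)
  as.integer(end - fhits[1] + 1L)
}

#' Fragment profile of one accession
#'
#' Applies all three primer sets to every gene sequence of an accession.
#' Fragments originating from the same gene form a correspondence triplet
#' (size1, size2, size3) with `NA` for sets that do not amplify the gene.
#'
#' @param sequences Named character vector of the accession's gene sequences.
#' @param primer_sets Tibble as [lmwgs_primer_sets()].
#' @param accession_id Label stored in the profile.
#' @return List of class `lmwgs_profile` with `accession_id`, `sizes` (named
#'   list of sorted per-set fragment multisets) and `triplets` (tibble).
#' @export
build_profile <- function(sequences, primer_sets = lmwgs_primer_sets(),
                          accession_id = "accession") {
  sets <- primer_sets$name
  if (length(sequences) == 0) {
    return(structure(list(accession_id = accession_id,
                          sizes = stats::setNames(rep(list(integer()), length(sets)), sets),
                          triplets = tibble::tibble(sequence_id = character(),
                                                    LMWGS1 = integer(),
                                                    LMWGS2 = integer(),
                                                    LMWGS3 = integer())),
                     class = "lmwgs_profile"))
  }
  m <- vapply(seq_len(nrow(primer_sets)), function(k) {
    vapply(sequences, virtual_amplicon,
           primer_set = primer_sets[k, ], integer(1))
  }, integer(length(sequences)))
  m <- matrix(m, nrow = length(sequences), dimnames = list(names(sequences), sets))
  sizes <- lapply(sets, function(s) sort(m[!is.na(m[, s]), s]))
  names(sizes) <- sets
  trip <- tibble::as_tibble(as.data.frame(m))
  trip <- tibble::add_column(trip, sequence_id = rownames(m), .before = 1)
  structure(list(accession_id = accession_id, sizes = sizes, triplets = trip),
            class = "lmwgs_profile")
}

#' @export
print.lmwgs_profile <- function(x, ...) {
  cat("<lmwgs_profile>", x$accession_id, "-", nrow(x$triplets), "genes\n")
  for (s in names(x$sizes)) {
    cat(" ", s, ":", paste(x$sizes[[s]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Profiles for a whole population
#'
#' @param population An `lmwgs_population` (or a named list of named
#'   sequence vectors).
#' @param primer_sets As [lmwgs_primer_sets()].
#' @return Named list of `lmwgs_profile` objects.
#' @export
population_profiles <- function(population, primer_sets = lmwgs_primer_sets()) {
  seqs <- if (inherits(population, "lmwgs_population")) population$sequences else population
  out <- lapply(names(seqs), function(a) {
    build_profile(seqs[[a]], primer_sets, accession_id = a)
  })
  stats::setNames(out, names(seqs))
}

profile_signature <- function(profile) {
  paste(vapply(names(profile$sizes), function(s) {
    paste0(s, ":", paste(profile$sizes[[s]], collapse = ","))
  }, character(1)), collapse = ";")
}

#' Call marker genotypes for a population
#'
#' Accessions with identical fragment-size multisets (all three primer sets)
#' share a provisional genotype. When sequences are supplied, size-identical
#' groups whose sequence content differs are split and flagged as
#' SNP-discriminated. Labels `U1, U2, ...` are assigned in descending
#' frequency, ties broken by first occurrence after sorting accession IDs,
#' so the calling is invariant to input order.
#'
#' @param profiles Named list of `lmwgs_profile` (one per accession).
#' @param sequences Optional named list (accession -> named sequence vector)
#'   enabling SNP-level discrimination.
#' @return Tibble `accession_id`, `genotype`, `snp_discriminated`.
#' @export
call_genotypes <- function(profiles, sequences = NULL) {
  if (length(profiles) == 0) stop("no profiles supplied")
  ids <- sort(vapply(profiles, `[[`, character(1), "accession_id"))
  profiles <- profiles[match(ids, vapply(profiles, `[[`, character(1), "accession_id"))]
  sig <- vapply(profiles, profile_signature, character(1))
  key <- sig
  snp_flag <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(sequences)) {
    content <- vapply(ids, function(a) {
      paste(sort(unname(sequences[[a]])), collapse = "|")
    }, character(1))
    key <- paste0(sig, "##", content)
    for (s in unique(sig)) {
      members <- ids[sig == s]
      if (length(unique(key[sig == s])) > 1L) snp_flag[members] <- TRUE
    }
  }
  first_occ <- match(unique(key), key)
  counts <- table(key)[unique(key)]
  ord <- order(-as.integer(counts), first_occ)
  labels <- stats::setNames(paste0("U", seq_along(ord)), unique(key)[ord])
  tibble::tibble(accession_id = ids,
                 genotype = unname(labels[key]),
                 snp_discriminated = unname(snp_flag[ids]))
}
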