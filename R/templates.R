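#' Construct a synthetic LMW-GS gene template
#'
#' A template fixes the protein architecture of one gene: the 20-residue
#' signal peptide, the type-diagnostic N-terminal region (absent for i-type,
#' starting with Met for m-type, carrying `MENSHIPGLEKPS` for s-type), a
#' glutamine/proline-rich repetitive domain built from a short motif, and the
#' three C-terminal domains housing 6, 1 and 1 cysteines. Encoded genes embed
#' landing sites for the three marker primer sets (`LMWGS1`-`LMWGS3`) so that
#' the theoretical LMWGS1 amplicon equals `size` base pairs exactly.
#'
#' @param gene_id Text label for the gene (e.g. `"TuA3-502"`).
#' @param subunit_type One of `"i"`, `"m"`, `"s"`.
#' @param size Target LMWGS1 amplicon size in bp; determines the repeat count
#'   and a small non-coding spacer. Alternatively supply `repeat_count` and
#'   `spacer_len` directly.
#' @param repeat_motif Amino-acid motif (length 8, so indels step by 24 bp)
#'   tandemly repeated in the repetitive domain.
#' @param repeat_count,spacer_len Explicit layout (ignored when `size` given).
#' @param cterm1,cterm2,cterm3 C-terminal domain sequences; defaults are the
#'   per-type, per-gene diversified scaffolds.
#' @param absent_sets Character vector of primer-set names whose forward
#'   landing site is disrupted in this gene (the amplicon reports `N`).
#' @param flank5_len,flank3_len Lengths of gene-specific non-coding flanks.
#' @return An object of class `lmwgs_template`.
#' @export
gene_template <- function(gene_id, subunit_type, size = NULL,
                          repeat_motif = "QQPPFSQQ",
                          repeat_count = NULL, spacer_len = 0L,
                          cterm1 = NULL, cterm2 = NULL, cterm3 = NULL,
                          absent_sets = character(),
                          flank5_len = 80L, flank3_len = 150L) {
  subunit_type <- match.arg(subunit_type, c("i", "m", "s"))
  if (nchar(repeat_motif) != 8L) {
    stop("repeat_motif must have 8 residues (24 coding nucleotides)")
  }
  if (is.null(cterm1) || is.null(cterm2) || is.null(cterm3)) {
    ct <- default_cterms(subunit_type, gene_id)
    if (is.null(cterm1)) cterm1 <- ct$cterm1
    if (is.null(cterm2)) cterm2 <- ct$cterm2
    if (is.null(cterm3)) cterm3 <- ct$cterm3
  }
  nterm_full <- NTERM_FULL[[subunit_type]]
  intro <- REPEAT_INTRO[[subunit_type]]
  pre_aa <- 20L + nchar(nterm_full) + nchar(intro)
  if (!is.null(size)) {
    x <- size - 92L - 3L * pre_aa
    if (x < 3L * 24L) {
      stop("size ", size, " too small for a ", subunit_type,
           "-type template (needs >= ", 92L + 3L * pre_aa + 72L, " bp)")
    }
    repeat_count <- x %/% 24L
    spacer_len <- x %% 24L
  }
  if (is.null(repeat_count) || repeat_count < 1L) {
    stop("repeat_count must be a positive integer")
  }
  t <- structure(list(
    gene_id = gene_id,
    subunit_type = subunit_type,
    signal_peptide = SIGNAL_AA,
    n_terminal = nterm_full,
    repeat_intro = intro,
    repeat_motifs = list(repeat_motif),
    repeat_count = as.integer(repeat_count),
    spacer_len = as.integer(spacer_len),
    cterm1 = cterm1, cterm2 = cterm2, cterm3 = cterm3,
    absent_sets = absent_sets,
    flank5 = dna_without_atg(flank5_len, mix_seed(salt_hash("flank5"), gene_id)),
    flank3 = dna_without_stops(flank3_len, mix_seed(salt_hash("flank3"), gene_id)),
    primer_sites = NULL
  ), class = "lmwgs_template")
  t$primer_sites <- template_primer_sites(t)
  validate_template(t)
  t
}

# Primer landing anchors as embedded in the encoded DNA: per set a
# (forward, reverse) pair of plus-strand nucleotide strings.
template_primer_sites <- function(t) {
  blk <- shared_5p_block()
  cterm_nt <- encode_protein(substr(t$cterm1, 1L, 48L))
  lapply(stats::setNames(nm = names(F_WINDOWS)), function(set) {
    if (set %in% t$absent_sets) return(NULL)
    fw <- F_WINDOWS[[set]]; rw <- R_WINDOWS[[set]]
    list(forward = substr(blk, fw[1], fw[2]),
         reverse = substr(cterm_nt, rw[1], rw[2]))
  })
}

#' @export
print.lmwgs_template <- function(x, ...) {
  cat(sprintf("<lmwgs_template> %s (%s-type): %d x %s repeats, spacer %d nt\n",
              x$gene_id, x$subunit_type, x$repeat_count,
              x$repeat_motifs[[1]], x$spacer_len))
  invisible(x)
}

count_cys <- function(aa) {
  lengths(regmatches(aa, gregexpr("C", aa, fixed = TRUE)))
}

validate_template <- function(t) {
  for (dom in c("cterm1", "cterm2", "cterm3")) {
    want <- c(cterm1 = 6L, cterm2 = 1L, cterm3 = 1L)[[dom]]
    got <- count_cys(t[[dom]])
    if (got != want) {
      stop(sprintf("template %s: %s carries %d cysteines, expected %d",
                   t$gene_id, dom, got, want))
    }
  }
  mature_start <- if (t$subunit_type == "s") {
    substr(NTERM_MATURE$s, 1L, 1L)
  } else if (t$subunit_type == "i") {
    substr(t$repeat_intro, 1L, 1L)
  } else {
    substr(t$n_terminal, 1L, 1L)
  }
  ok <- switch(t$subunit_type,
    i = t$n_terminal == "" && mature_start == "I",
    m = mature_start == "M",
    s = startsWith(t$n_terminal, "MENSHIPGLEKPS"))
  if (!ok) stop("template ", t$gene_id, ": ", t$subunit_type,
                "-type N-terminal rule violated")
  invisible(t)
}

# Deterministic divergence of a scaffold: substitute a fraction of the
# unprotected residues, never creating or destroying a cysteine.
diversify_protein <- function(aa, rate, salt, protected = integer()) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- lcg_runif(n, mix_seed(salt_hash("diversify"), salt))
  alt <- strsplit("GASTPLVIFQNHEDKR", "")[[1]]
  pick <- lcg_sample(n, length(alt), mix_seed(salt_hash("diversify-pick"), salt))
  for (i in seq_len(n)) {
    if (i %in% protected || chars[i] == "C") next
    if (u[i] < rate) {
      r <- alt[pick[i]]
      if (r == chars[i]) r <- alt[(pick[i] %% length(alt)) + 1L]
      chars[i] <- r
    }
  }
  paste(chars, collapse = "")
}

# Per-type archetypes diverged from the common scaffold, then per-gene
# divergence on top. The s-type archetype is derived from the m-type one so
# that s-type genes fall in the m-type clade, and i-type genes form their own.
default_cterms <- function(type, gene_id) {
  base1 <- paste0(CTERM1_ANCH_A, CTERM1_MID, CTERM1_ANCH_B, CTERM1_TAIL)
  arch <- function(ty) {
    if (ty == "s") {
      m <- arch("m")
      list(cterm1 = diversify_protein(m$cterm1, 0.10, "ctype-s1", CTERM1_PROTECTED),
           cterm2 = diversify_protein(m$cterm2, 0.10, "ctype-s2", 25L),
           cterm3 = diversify_protein(m$cterm3, 0.10, "ctype-s3", 10L))
    } else {
      list(cterm1 = diversify_protein(base1, 0.22, paste0("ctype-", ty, "1"), CTERM1_PROTECTED),
           cterm2 = diversify_protein(CTERM2_BASE, 0.22, paste0("ctype-", ty, "2"), 25L),
           cterm3 = diversify_protein(CTERM3_BASE, 0.22, paste0("ctype-", ty, "3"), 10L))
    }
  }
  a <- arch(type)
  list(
    cterm1 = diversify_protein(a$cterm1, 0.12, paste0("cgene1-", gene_id), CTERM1_PROTECTED),
    cterm2 = diversify_protein(a$cterm2, 0.12, paste0("cgene2-", gene_id), 25L),
    cterm3 = diversify_protein(a$cterm3, 0.12, paste0("cgene3-", gene_id), 10L)
  )
}
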