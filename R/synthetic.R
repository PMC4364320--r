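#' Mutation model for synthetic gene generation
#'
#' @param snp_rate Substitutions per site.
#' @param indel_rate Expected indel events per sequence (Poisson).
#' @param indel_unit Indel size in nucleotides; must be a positive multiple of
#'   3 (default 24, one repeat motif).
#' @param premature_stop_probability Per-sequence probability of one injected
#'   in-frame stop codon.
#' @param seed Integer stream seed; per-sequence sub-streams are derived from
#'   it and the sequence label, so generation order does not matter.
#' @return An object of class `lmwgs_mutations`.
#' @export
mutation_spec <- function(snp_rate = 0, indel_rate = 0, indel_unit = 24L,
                          premature_stop_probability = 0, seed = 1L) {
  if (any(c(snp_rate, premature_stop_probability) < 0) ||
      any(c(snp_rate, premature_stop_probability) > 1) || indel_rate < 0) {
    stop("mutation rates must lie in [0, 1] (indel_rate >= 0)")
  }
  if (indel_unit %% 3L != 0L || indel_unit <= 0L) {
    stop("indel_unit must be a positive multiple of 3")
  }
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_unit = as.integer(indel_unit),
                 premature_stop_probability = premature_stop_probability,
                 seed = seed),
            class = "lmwgs_mutations")
}

# ---- assembly --------------------------------------------------------------

# Build the unmutated DNA of a template plus a coordinate map used for truth
# bookkeeping. Optional deterministic variant edits: `snps` (1-based aa codon
# indices, third-position transition) and `stops` (1-based aa indices whose
# codon becomes TAG).
assemble_gene <- function(template, snps = integer(), stops = integer()) {
  t <- template
  motif <- t$repeat_motifs[[1]]
  rep_region <- paste0(t$repeat_intro, strrep(motif, t$repeat_count))
  prot <- paste0(t$signal_peptide, t$n_terminal, rep_region,
                 t$cterm1, t$cterm2, t$cterm3)
  cds <- paste0(encode_protein(prot), "TAA")
  spacer <- dna_without_atg(t$spacer_len, mix_seed(salt_hash("spacer"), t$gene_id))
  blk <- shared_5p_block()
  # disrupt forward landing sites of configured-absent primer sets (without
  # ever creating a spurious upstream ATG)
  for (set in t$absent_sets) {
    w <- F_WINDOWS[[set]]
    for (mid in seq(w[1] + 9L, w[2] - 1L)) {
      cand <- blk
      substr(cand, mid, mid + 1L) <- chartr("ACGT", "TGCA",
                                            substr(cand, mid, mid + 1L))
      if (!grepl("ATG", cand, fixed = TRUE)) { blk <- cand; break }
    }
  }
  # the flank, shared block and spacer are individually ATG-free, but an ATG
  # can form across their junctions; break any such ATG outside the primer
  # block so the true start codon is always the first
  prefix <- paste0(t$flank5, blk, spacer)
  n5 <- nchar(t$flank5); nb <- nchar(blk)
  repeat {
    p <- regexpr("ATG", prefix, fixed = TRUE)[1]
    if (p == -1L) break
    idx <- (p:(p + 2L))[p:(p + 2L) <= n5 | p:(p + 2L) > n5 + nb][1]
    substr(prefix, idx, idx) <- "C"
  }
  atg <- nchar(prefix) + 1L
  n_aa <- nchar(prot)

  # deterministic edits on the coding sequence
  if (length(snps) > 0) {
    for (i in snps) {
      p <- 3L * i     # third position of codon i within the CDS
      base <- substr(cds, p, p)
      substr(cds, p, p) <- chartr("AGCT", "GATC", base)
    }
  }
  if (length(stops) > 0) {
    for (i in stops) substr(cds, 3L * i - 2L, 3L * i) <- "TAG"
  }
  dna <- paste0(prefix, cds, t$flank3)

  nterm_mat <- NTERM_MATURE[[t$subunit_type]]
  rep_len <- nchar(rep_region)
  mature_start <- if (t$subunit_type == "s") 23L else 20L   # 0-based
  size1 <- 92L + t$spacer_len + 3L * (20L + nchar(t$n_terminal) + rep_len)
  sizes <- c(LMWGS1 = size1, LMWGS2 = size1 + 117L, LMWGS3 = size1 - 28L)
  sizes[t$absent_sets] <- NA_integer_

  # global 1-based nt windows of all primer landing sites
  blk_off <- nchar(t$flank5)
  ct_off <- atg - 1L + 3L * (20L + nchar(t$n_terminal) + rep_len)
  pw <- list()
  for (set in names(F_WINDOWS)) {
    if (set %in% t$absent_sets) next
    pw[[set]] <- rbind(blk_off + F_WINDOWS[[set]], ct_off + R_WINDOWS[[set]])
  }

  nterm_len <- nchar(nterm_mat)
  R <- nterm_len + nchar(t$repeat_intro) + 8L * t$repeat_count
  mature_len <- n_aa - mature_start
  domains <- list(
    "N-terminal" = c(0L, nterm_len),
    "repetitive" = c(nterm_len, R),
    "C-terminal I" = c(R, R + CTERM1_LEN),
    "C-terminal II" = c(R + CTERM1_LEN, R + CTERM1_LEN + CTERM2_LEN),
    "C-terminal III" = c(R + CTERM1_LEN + CTERM2_LEN, mature_len)
  )

  list(dna = dna, template = t, atg = atg, n_aa = n_aa,
       mature_start = mature_start, mature_len = mature_len,
       domains = domains, cys = R + CYS_OFFSETS, sizes = sizes,
       primer_windows = pw,
       repeat_nt = c(atg + 3L * (20L + nchar(t$n_terminal)),
                     atg - 1L + 3L * (20L + nchar(t$n_terminal) + rep_len)),
       stop_aa = stops)
}

# Map a 0-based mature-protein index to its domain name (signal for indices
# upstream of the mature start when given full-protein coordinates).
domain_of <- function(mature_index, domains) {
  for (nm in names(domains)) {
    d <- domains[[nm]]
    if (mature_index >= d[1] && mature_index < d[2]) return(nm)
  }
  "none"
}

# Poisson draw by inversion from one uniform stream.
lcg_rpois <- function(lambda, seed) {
  if (lambda <= 0) return(0L)
  u <- lcg_runif(1, seed)
  p <- exp(-lambda); cdf <- p; k <- 0L
  while (u > cdf && k < 1000L) {
    k <- k + 1L
    p <- p * lambda / k
    cdf <- cdf + p
  }
  k
}

# Apply stochastic mutations to an assembled gene; returns the mutated DNA
# plus truth adjustments (net repeat indel, SNP positions, injected stop).
apply_mutations <- function(asm, mutations, stream) {
  dna <- asm$dna
  net_indel <- 0L
  snp_pos <- integer()
  stop_inj <- NA_integer_

  # indels: motif-unit events at codon boundaries inside the repetitive domain
  n_ind <- lcg_rpois(mutations$indel_rate, mix_seed(stream, "n-indel"))
  unit <- mutations$indel_unit
  for (e in seq_len(n_ind)) {
    r <- asm$repeat_nt + c(0L, net_indel)
    span <- r[2] - r[1] + 1L
    if (span < 2L * unit) break
    slots <- (span - unit) %/% 3L
    off <- 3L * (lcg_sample(1, slots, mix_seed(stream, paste0("indel-pos-", e))) - 1L)
    at <- r[1] + off
    ins <- lcg_runif(1, mix_seed(stream, paste0("indel-dir-", e))) < 0.5
    if (ins) {
      block <- substr(dna, at, at + unit - 1L)
      dna <- paste0(substr(dna, 1L, at - 1L), block, substr(dna, at, nchar(dna)))
      net_indel <- net_indel + unit
    } else {
      dna <- paste0(substr(dna, 1L, at - 1L), substr(dna, at + unit, nchar(dna)))
      net_indel <- net_indel - unit
    }
  }

  # SNPs: per-site substitutions over the whole sequence
  if (mutations$snp_rate > 0) {
    n <- nchar(dna)
    u <- lcg_runif(n, mix_seed(stream, "snp-sites"))
    snp_pos <- which(u < mutations$snp_rate)
    if (length(snp_pos) > 0) {
      picks <- lcg_sample(length(snp_pos), 3L, mix_seed(stream, "snp-base"))
      chars <- strsplit(dna, "")[[1]]
      for (j in seq_along(snp_pos)) {
        p <- snp_pos[j]
        alt <- setdiff(c("A", "C", "G", "T"), chars[p])[picks[j]]
        chars[p] <- alt
      }
      dna <- paste(chars, collapse = "")
    }
  }

  # premature stop injection at a codon boundary within a named domain
  if (lcg_runif(1, mix_seed(stream, "stop-draw")) <
      mutations$premature_stop_probability) {
    doms <- asm$domains
    elig <- unlist(lapply(c("repetitive", "C-terminal I", "C-terminal II",
                            "C-terminal III"), function(nm) {
      d <- doms[[nm]]
      lo <- d[1] + 3L; hi <- d[2] - 3L
      if (hi <= lo) integer() else seq(lo, hi)
    }))
    elig <- setdiff(elig, asm$cys)
    pick <- elig[lcg_sample(1, length(elig), mix_seed(stream, "stop-pos"))]
    # full-protein aa index (1-based), then nt position allowing for indels
    aa_full <- pick + asm$mature_start + 1L
    nt <- asm$atg + 3L * (aa_full - 1L)
    if (nt > asm$repeat_nt[2]) nt <- nt + net_indel
    substr(dna, nt, nt + 2L) <- "TAG"
    stop_inj <- pick
  }

  list(dna = dna, net_indel = net_indel, snp_pos = snp_pos, stop_inj = stop_inj)
}

# Truth for a (possibly mutated) assembled gene, computed from construction
# knowledge: codon scan for ORF status, arithmetic for sizes and boundaries.
gene_truth <- function(asm, mut = NULL, variant_id = NA_character_) {
  dna <- if (is.null(mut)) asm$dna else mut$dna
  net <- if (is.null(mut)) 0L else mut$net_indel
  k_extra <- net %/% 3L

  # shift domain boundaries downstream of the repetitive domain
  domains <- asm$domains
  for (nm in c("C-terminal I", "C-terminal II", "C-terminal III")) {
    domains[[nm]] <- domains[[nm]] + k_extra
  }
  domains[["repetitive"]][2] <- domains[["repetitive"]][2] + k_extra
  cys <- asm$cys + k_extra
  mature_len <- asm$mature_len + k_extra

  # ORF scan from the (known) start codon
  atg <- asm$atg
  if (substr(dna, atg, atg + 2L) != "ATG") {
    orf <- "no_start"; stop_dom <- "none"; n_stop <- NA_integer_
  } else {
    cds_len <- 3L * (asm$n_aa + k_extra + 1L)
    codons <- substring(dna, seq(atg, atg + cds_len - 3L, 3L),
                        seq(atg + 2L, atg + cds_len - 1L, 3L))
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    internal <- which(is_stop[-length(is_stop)])
    n_stop <- length(internal)
    if (n_stop == 0L) {
      orf <- "active"; stop_dom <- "none"
    } else {
      orf <- "pseudo"
      mi <- internal[1] - 1L - asm$mature_start   # 0-based mature index
      stop_dom <- if (mi < 0) "signal" else domain_of(mi, domains)
    }
  }

  sizes <- asm$sizes
  sizes[!is.na(sizes)] <- sizes[!is.na(sizes)] + net
  if (!is.null(mut) && length(mut$snp_pos) > 0) {
    for (set in names(asm$primer_windows)) {
      w <- asm$primer_windows[[set]]
      w[2, ] <- w[2, ] + ifelse(w[2, ] > asm$repeat_nt[2], net, 0L)
      hit <- any(vapply(seq_len(nrow(w)), function(i) {
        any(mut$snp_pos >= w[i, 1] & mut$snp_pos <= w[i, 2])
      }, logical(1)))
      if (hit) sizes[set] <- NA_integer_
    }
  }

  tibble::tibble(
    gene_id = asm$template$gene_id,
    variant_id = variant_id,
    subunit_type = asm$template$subunit_type,
    orf_status = orf,
    stop_domain = stop_dom,
    n_internal_stops = n_stop,
    mature_start = asm$mature_start,
    mature_length = mature_len,
    domains = list(domains),
    cys_positions = list(cys),
    size_LMWGS1 = sizes[["LMWGS1"]],
    size_LMWGS2 = sizes[["LMWGS2"]],
    size_LMWGS3 = sizes[["LMWGS3"]]
  )
}

#' Generate one synthetic LMW-GS gene
#'
#' Encodes the template protein with the package's fixed codon table, applies
#' the mutation model, and returns the DNA together with a truth row recording
#' post-mutation ORF status, domain coordinates and theoretical amplicon sizes.
#'
#' @param template A [gene_template()].
#' @param mutations A [mutation_spec()].
#' @param label Sequence label used both as FASTA-style name and to derive the
#'   per-sequence mutation stream.
#' @param snps Deterministic designed edits applied before stochastic
#'   mutation: 1-based codon indices receiving a third-position transition.
#' @param stops 1-based codon indices whose codon becomes TAG (designed
#'   premature stops, e.g. to build a pseudo-gene variant).
#' @return List with elements `dna` (character) and `truth` (one-row tibble).
#' @export
make_gene <- function(template, mutations = mutation_spec(),
                      label = template$gene_id,
                      snps = integer(), stops = integer()) {
  validate_template(template)
  asm <- assemble_gene(template, snps = snps, stops = stops)
  stream <- mix_seed(mutations$seed, label)
  mut <- apply_mutations(asm, mutations, stream)
  list(dna = mut$dna, truth = gene_truth(asm, mut, variant_id = label))
}
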