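# Annotation of LMW-GS gene sequences: ORF and pseudo-gene status, signal
# cleavage and i/m/s typing, cysteine-anchored domain segmentation, molecular
# weight and isoelectric point.

genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a gene from its first ATG, reading through premature stops
#'
#' Translation starts at the first ATG and continues in frame through any
#' premature stop codon (reported as `*`), ending at the last in-frame stop
#' of the sequence; read-through keeps pseudo-gene proteins alignable so the
#' premature stop can be localized to a domain.
#'
#' @param dna Nucleotide string (IUPAC upper case).
#' @return List with `protein` (amino acids, internal stops as `*`),
#'   `internal_stops` (1-based residue indices) and `start` (1-based position
#'   of the ATG in `dna`).
#' @export
find_orf <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) < 3L) stop("sequence shorter than one codon")
  if (grepl("[^ACGTRYSWKMBDHVN]", dna)) {
    bad <- regmatches(dna, regexpr("[^ACGTRYSWKMBDHVN]", dna))
    stop("non-IUPAC character '", bad, "' in sequence")
  }
  atg <- regexpr("ATG", dna, fixed = TRUE)[1]
  if (atg == -1L) stop("no ORF: sequence contains no ATG start codon")
  n_cod <- (nchar(dna) - atg + 1L) %/% 3L
  codons <- substring(dna, atg + 3L * (seq_len(n_cod) - 1L),
                      atg + 3L * seq_len(n_cod) - 1L)
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) > 0) {
    aa <- aa[seq_len(stops[length(stops)] - 1L)]
    stops <- stops[-length(stops)]
  }
  list(protein = paste(aa, collapse = ""),
       internal_stops = stops,
       start = as.integer(atg))
}

# Mature-start motifs searched within the cleavage window (residues 16-31).
CLEAVAGE_MOTIFS <- c("ISQ", "MET", "MEN")
CLEAVAGE_WINDOW <- c(16L, 31L)
S_TYPE_NTERM <- "MENSHIPGLEKPS"

#' Remove the signal peptide and call the i/m/s subunit type
#'
#' The cleavage point is the earliest occurrence of a type-diagnostic
#' mature-start motif (`ISQ`, `MET`, `MEN`) within residues 16-31; when no
#' motif is found, cleavage falls back to after residue 20. If the
#' post-signal region begins with the s-type block `MENSHIPGLEKPS`, the MEN
#' tripeptide is removed together with the signal and the subunit is s-type;
#' otherwise the type follows the first mature residue (Ile, Met or Ser).
#'
#' @param protein Amino-acid string from [find_orf()] (at least 30 residues).
#' @return List with `mature`, `subunit_type` (`"i"`, `"m"`, `"s"` or
#'   `"unknown"`) and `mature_start` (0-based index into `protein`).
#' @export
cleave_and_type <- function(protein) {
  if (nchar(protein) < 30L) stop("protein too short to annotate (< 30 aa)")
  cut <- NA_integer_
  for (pos in seq(CLEAVAGE_WINDOW[1], CLEAVAGE_WINDOW[2])) {
    tri <- substr(protein, pos, pos + 2L)
    if (tri %in% CLEAVAGE_MOTIFS) { cut <- pos; break }
  }
  if (is.na(cut)) cut <- 21L
  post <- substr(protein, cut, nchar(protein))
  if (startsWith(post, S_TYPE_NTERM)) {
    mature <- substr(post, 4L, nchar(post))
    type <- "s"
  } else {
    mature <- post
    type <- switch(substr(mature, 1L, 1L), I = "i", M = "m", S = "s", "unknown")
  }
  if (nchar(mature) < 10L) stop("mature region shorter than 10 residues")
  list(mature = mature,
       subunit_type = type,
       mature_start = nchar(protein) - nchar(mature))
}

#' Segment a mature LMW-GS protein into its conserved domains
#'
#' Boundaries follow cysteine ordinals: the repetitive domain runs from the
#' end of the N-terminal domain to the residue before the first cysteine;
#' C-terminal I spans cysteines 1-6, C-terminal II ends at cysteine 7 and
#' C-terminal III runs to the end of the protein. The N-terminal domain is
#' absent for i-type subunits and otherwise ends at the first `QQ` dipeptide
#' (the head of the repetitive domain). Intact subunits carry 8 cysteines
#' (6/1/1 across the C-terminal domains); deviations are flagged.
#'
#' @param mature Mature protein from [cleave_and_type()].
#' @param subunit_type `"i"`, `"m"` or `"s"`.
#' @return List with `domains` (named list of 0-based half-open `[start, end)`
#'   intervals tiling the mature protein), `cys_positions` (0-based),
#'   `cys_counts` (per C-terminal domain) and `n_cys`.
#' @export
segment_domains <- function(mature, subunit_type = "m") {
  len <- nchar(mature)
  chars <- strsplit(mature, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C") - 1L          # 0-based
  n_cys <- length(cys)
  if (n_cys < 8L) {
    warning("atypical cysteine architecture: ", n_cys,
            " cysteines (expected 8); using available ordinals")
  } else if (n_cys > 8L) {
    warning("extra cysteine residue(s) at mature position(s) ",
            paste(cys[-(1:8)] + 1L, collapse = ", "))
  }
  if (subunit_type == "i") {
    nterm_end <- 0L
  } else {
    qq <- regexpr("QQ", mature, fixed = TRUE)[1]
    nterm_end <- if (qq == -1L) 0L else qq - 1L
    if (n_cys > 0 && nterm_end > cys[1]) nterm_end <- 0L
  }
  c1 <- if (n_cys >= 1L) cys[1] else len
  c6 <- if (n_cys >= 6L) cys[6] else if (n_cys >= 1L) cys[n_cys] else len - 1L
  c7 <- if (n_cys >= 7L) cys[7] else c6
  domains <- list(
    "N-terminal" = c(0L, nterm_end),
    "repetitive" = c(nterm_end, c1),
    "C-terminal I" = c(c1, min(c6 + 1L, len)),
    "C-terminal II" = c(min(c6 + 1L, len), min(c7 + 1L, len)),
    "C-terminal III" = c(min(c7 + 1L, len), len)
  )
  counts <- vapply(domains[c("C-terminal I", "C-terminal II", "C-terminal III")],
                   function(d) sum(cys >= d[1] & cys < d[2]), integer(1))
  list(domains = domains, cys_positions = cys, cys_counts = counts, n_cys = n_cys)
}

#' Average molecular weight of a protein in Daltons
#'
#' Sum of average residue masses plus one water; the residue-mass table is
#' versioned in the package.
#'
#' @param protein Amino-acid string (standard alphabet; no `*`).
#' @return Mass in Da.
#' @export
molecular_weight <- function(protein) {
  if (nchar(protein) == 0L) return(WATER_MASS)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  m <- RESIDUE_MASS[chars]
  if (anyNA(m)) {
    stop("unknown residue '", chars[which(is.na(m))[1]], "' at position ",
         which(is.na(m))[1])
  }
  sum(m) + WATER_MASS
}

# Net charge at a given pH under the packaged pKa set.
net_charge <- function(protein, ph) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  pos <- PKA_SET$positive
  neg <- PKA_SET$negative
  q <- 1 / (1 + 10^(ph - PKA_SET$nterm)) - 1 / (1 + 10^(PKA_SET$cterm - ph))
  for (r in names(pos)) q <- q + sum(chars == r) / (1 + 10^(ph - pos[[r]]))
  for (r in names(neg)) q <- q - sum(chars == r) / (1 + 10^(neg[[r]] - ph))
  q
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' @param protein Amino-acid string (standard alphabet).
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein, tol = 0.01) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(RESIDUE_MASS))
  if (length(bad) > 0) {
    stop("unknown residue '", bad[1], "' at position ",
         which(chars == bad[1])[1])
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Localize a pseudo-gene's premature stop codon to a domain
#'
#' Globally aligns the read-through protein of a pseudo-gene against the
#' annotated protein of an intact variant of the same gene and maps the first
#' internal stop's aligned column into the reference domain map. Stops within
#' the signal peptide report `"signal"`. Without a reference the stop is
#' localized on the pseudo sequence's own (partial) cysteine ordinals and the
#' result is flagged self-referenced.
#'
#' @param pseudo_protein Read-through protein (with `*`) from [find_orf()].
#' @param reference Annotation of an active variant ([annotate_gene()]
#'   result), or `NULL`.
#' @return List with `stop_domain` and `self_referenced`.
#' @export
localize_stop <- function(pseudo_protein, reference = NULL) {
  stop_idx <- regexpr("*", pseudo_protein, fixed = TRUE)[1]
  if (stop_idx == -1L) stop("protein carries no internal stop")
  if (stop_idx <= 20L) {
    return(list(stop_domain = "signal", self_referenced = is.null(reference)))
  }
  if (is.null(reference)) {
    cl <- cleave_and_type(pseudo_protein)
    seg <- suppressWarnings(segment_domains(cl$mature, cl$subunit_type))
    dom <- domain_of(stop_idx - 1L - cl$mature_start, seg$domains)
    return(list(stop_domain = dom, self_referenced = TRUE))
  }
  ref_prot <- reference$protein
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pseudo_protein), Biostrings::AAString(ref_prot),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi_ <- cumsum(p != "-")
  si_ <- cumsum(s != "-")
  col <- which(pi_ == stop_idx & p != "-")[1]
  ref_idx <- si_[col]                       # 1-based index into ref protein
  mi <- ref_idx - 1L - reference$mature_start
  dom <- if (mi < 0) "signal" else domain_of(mi, reference$domains)
  list(stop_domain = dom, self_referenced = FALSE)
}

#' Full annotation of one gene sequence
#'
#' Runs [find_orf()], [cleave_and_type()], [segment_domains()],
#' [molecular_weight()] and [isoelectric_point()] and assembles a
#' `GeneAnnotation`-style record.
#'
#' @param dna Nucleotide string.
#' @param reference Optional annotation of an intact variant of the same gene
#'   for premature-stop localization.
#' @return List of class `lmwgs_annotation` with fields `orf_status`,
#'   `stop_domain`, `subunit_type`, `mature_start`, `mature`, `protein`,
#'   `domains`, `cys_positions`, `cys_counts`, `mw_da`, `pi`,
#'   `self_referenced_stop`.
#' @export
annotate_gene <- function(dna, reference = NULL) {
  orf <- find_orf(dna)
  cl <- cleave_and_type(orf$protein)
  seg <- suppressWarnings(segment_domains(cl$mature, cl$subunit_type))
  clean <- gsub("*", "", cl$mature, fixed = TRUE)
  pseudo <- length(orf$internal_stops) > 0
  if (pseudo) {
    loc <- localize_stop(orf$protein, reference)
    stop_dom <- loc$stop_domain
    selfref <- loc$self_referenced
  } else {
    stop_dom <- "none"; selfref <- FALSE
  }
  structure(list(
    orf_status = if (pseudo) "pseudo" else "active",
    stop_domain = stop_dom,
    subunit_type = cl$subunit_type,
    mature_start = cl$mature_start,
    protein = orf$protein,
    mature = cl$mature,
    internal_stops = orf$internal_stops,
    domains = seg$domains,
    cys_positions = seg$cys_positions,
    cys_counts = seg$cys_counts,
    mw_da = molecular_weight(clean),
    pi = isoelectric_point(clean),
    self_referenced_stop = selfref
  ), class = "lmwgs_annotation")
}

#' @export
print.lmwgs_annotation <- function(x, ...) {
  cat(sprintf("<lmwgs_annotation> %s-type, %s%s; mature %d aa, %d Cys (%s), %.2f kDa, pI %.2f\n",
              x$subunit_type, x$orf_status,
              if (x$orf_status == "pseudo") paste0(" (stop: ", x$stop_domain, ")") else "",
              nchar(x$mature), length(x$cys_positions),
              paste(x$cys_counts, collapse = "/"), x$mw_da / 1000, x$pi))
  invisible(x)
}

#' Annotate a set of sequences into a summary table
#'
#' @param sequences Named character vector of gene sequences.
#' @param references Optional named character vector mapping each sequence
#'   name to the name of an intact reference sequence (for stop localization).
#' @return Tibble with one annotation row per sequence.
#' @export
annotate_set <- function(sequences, references = NULL) {
  anns <- lapply(sequences, annotate_gene)
  if (!is.null(references)) {
    for (nm in names(sequences)) {
      ref_nm <- references[[nm]]
      if (!is.null(ref_nm) && !is.na(ref_nm) && ref_nm %in% names(anns) &&
          anns[[nm]]$orf_status == "pseudo") {
        orf <- find_orf(sequences[[nm]])
        loc <- localize_stop(orf$protein, anns[[ref_nm]])
        anns[[nm]]$stop_domain <- loc$stop_domain
        anns[[nm]]$self_referenced_stop <- loc$self_referenced
      }
    }
  }
  tibble::tibble(
    sequence_id = names(sequences),
    subunit_type = unname(vapply(anns, `[[`, character(1), "subunit_type")),
    orf_status = unname(vapply(anns, `[[`, character(1), "orf_status")),
    stop_domain = unname(vapply(anns, `[[`, character(1), "stop_domain")),
    mature_length = unname(vapply(anns, function(a) nchar(a$mature), integer(1))),
    n_cys = unname(vapply(anns, function(a) length(a$cys_positions), integer(1))),
    cys_c1 = unname(vapply(anns, function(a) a$cys_counts[[1]], integer(1))),
    cys_c2 = unname(vapply(anns, function(a) a$cys_counts[[2]], integer(1))),
    cys_c3 = unname(vapply(anns, function(a) a$cys_counts[[3]], integer(1))),
    mw_da = unname(vapply(anns, `[[`, numeric(1), "mw_da")),
    pi = unname(vapply(anns, `[[`, numeric(1), "pi")),
    annotation = unname(anns)
  )
}
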