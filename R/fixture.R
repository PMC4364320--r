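#' Packaged population fixture: genotypes and geography of Glu-A3 LMW-GS genes
#'
#' Returns the encoded published genotype table for the 157-accession diploid
#' wheat (*Triticum urartu*) population: 15 genotypes (U1-U15) over 8 LMW-GS
#' genes and 39 allelic variants, per-genotype collection-region counts, and
#' per-variant expression status (active vs. pseudo-gene) with the domain
#' location of premature stop codons where reported.
#'
#' @return A list with elements:
#'   * `variants`: tibble of the 39 variants (`gene`, `variant`, `type`,
#'     `size`, `active`, `stop_domains`).
#'   * `genotype_variants`: long tibble mapping each genotype to its variant
#'     multiset (one row per gene carried).
#'   * `region_counts`: tibble of per-genotype accession counts by region.
#'   * `genotypes`: accession-level genotype table (one row per accession,
#'     with `variants` and `active_variants` list-columns).
#'   * `naming_prefix`: `"TuA3-"`.
#' @export
table2_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "lmwgs", mustWork = TRUE)
  rd <- function(f) tibble::as_tibble(utils::read.delim(path(f), check.names = FALSE,
                                                        stringsAsFactors = FALSE))
  variants <- rd("tua3_variants.tsv")
  gv <- rd("tua3_genotype_variants.tsv")
  rc <- rd("tua3_genotype_regions.tsv")
  stopifnot(sum(rc$n) == 157L, nrow(variants) == 39L)
  acc <- expand_accessions(rc)
  vsets <- split(gv$variant, gv$genotype)
  active <- variants$variant[variants$active]
  acc$variants <- unname(vsets[acc$genotype])
  acc$active_variants <- lapply(acc$variants, function(v) intersect(v, active))
  list(variants = variants, genotype_variants = gv, region_counts = rc,
       genotypes = acc, naming_prefix = "TuA3-")
}

# Expand per-genotype, per-region counts into one accession row each, with
# deterministic IDs TU001.. in genotype-number then region order.
expand_accessions <- function(region_counts) {
  rc <- region_counts
  if (!all(rc$region %in% REGION_LEVELS)) {
    stop("unknown region label(s): ",
         paste(setdiff(unique(rc$region), REGION_LEVELS), collapse = ", "))
  }
  if (any(rc$n < 0)) stop("region counts must be >= 0")
  gnum <- suppressWarnings(as.integer(sub("^U", "", rc$genotype)))
  ord <- order(if (anyNA(gnum)) rank(rc$genotype) else gnum,
               match(rc$region, REGION_LEVELS))
  rc <- rc[ord, ]
  acc <- tibble::tibble(
    genotype = rep(rc$genotype, rc$n),
    region = rep(rc$region, rc$n)
  )
  acc$accession_id <- sprintf("TU%03d", seq_len(nrow(acc)))
  acc[, c("accession_id", "region", "genotype")]
}

# Per-gene repeat motifs and marker behaviour of the fixture templates. The
# s-type gene is configured as not amplified by LMWGS3, exercising the "N"
# sentinel end-to-end.
FIXTURE_MOTIFS <- c(
  "TuA3-385" = "QQPPFSQQ", "TuA3-391" = "QQPILSHQ", "TuA3-397" = "QQTVFPQQ",
  "TuA3-400" = "QQPAFLPQ", "TuA3-460" = "QQPFSQPQ", "TuA3-502" = "QQSQIPVQ",
  "TuA3-538" = "QQPGQLVS", "TuA3-576" = "QQLPVTSQ"
)
FIXTURE_ABSENT <- list("TuA3-460" = "LMWGS3")

#' Population generator configuration
#'
#' Bundles the variant inventory, genotype definitions and regional accession
#' counts that [make_population()] turns into sequences. Defaults for motifs
#' and primer-set behaviour follow the packaged fixture architecture.
#'
#' @param variants Tibble with columns `gene`, `variant`, `type`, `size`,
#'   `active`, `stop_domains` (`"none"` or `;`-separated domain names).
#' @param genotype_variants Long tibble `genotype`, `variant` (the genotype's
#'   variant multiset).
#' @param region_counts Tibble `genotype`, `region`, `n`.
#' @param motifs Named character vector of per-gene repeat motifs.
#' @param absent_sets Named list: gene -> primer sets that do not amplify it.
#' @param naming_prefix Prefix used for display names.
#' @return An object of class `lmwgs_popconfig`.
#' @export
population_config <- function(variants, genotype_variants, region_counts,
                              motifs = FIXTURE_MOTIFS,
                              absent_sets = FIXTURE_ABSENT,
                              naming_prefix = "TuA3-") {
  undef <- setdiff(genotype_variants$variant, variants$variant)
  if (length(undef) > 0) {
    stop("genotype references undefined variant(s): ",
         paste(undef, collapse = ", "))
  }
  miss <- setdiff(unique(variants$gene), names(motifs))
  if (length(miss) > 0) stop("no repeat motif configured for gene(s): ",
                             paste(miss, collapse = ", "))
  # representative variant per gene = the one carried by most accessions
  tot <- stats::setNames(
    vapply(split(region_counts$n, region_counts$genotype), sum, numeric(1)),
    names(split(region_counts$n, region_counts$genotype)))
  gv <- genotype_variants
  gv$n <- tot[gv$genotype]
  counts <- vapply(split(gv$n, gv$variant), sum, numeric(1))
  variants$accession_count <- unname(counts[variants$variant])
  variants$accession_count[is.na(variants$accession_count)] <- 0
  reps <- vapply(split(seq_len(nrow(variants)), variants$gene), function(idx) {
    v <- variants[idx, ]
    idx[order(-v$accession_count, v$size, v$variant)][1]
  }, integer(1))
  variants$representative <- seq_len(nrow(variants)) %in% reps
  structure(list(variants = variants, genotype_variants = genotype_variants,
                 region_counts = region_counts, motifs = motifs,
                 absent_sets = absent_sets, naming_prefix = naming_prefix),
            class = "lmwgs_popconfig")
}

#' Configuration reproducing the packaged population fixture
#' @return An `lmwgs_popconfig` for the 157-accession, 15-genotype fixture.
#' @export
fixture_population_config <- function() {
  fx <- table2_fixture()
  population_config(fx$variants, fx$genotype_variants, fx$region_counts,
                    naming_prefix = fx$naming_prefix)
}
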