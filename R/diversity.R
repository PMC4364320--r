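# Genotype frequency, expression-status and geographic-diversity summaries.

#' Per-genotype accession counts and shares
#'
#' @param genotype_table Accession-level table with `accession_id`,
#'   `genotype` (and optionally `region`).
#' @return Tibble `genotype`, `count`, `share_percent`, sorted by descending
#'   count (ties by genotype label).
#' @export
genotype_summary <- function(genotype_table) {
  if (nrow(genotype_table) == 0) stop("empty genotype table")
  tab <- table(genotype_table$genotype)
  out <- tibble::tibble(genotype = names(tab),
                        count = as.integer(tab))
  out <- out[order(-out$count, out$genotype), ]
  out$share_percent <- round_half_up(100 * out$count / sum(out$count), 2)
  out
}

#' Active-gene census by subunit type
#'
#' Counts intact-ORF (active) genes per accession and reports the population
#' share of accessions whose three i-type genes are all active — the pattern
#' distinguishing this diploid population from common wheat, where only one
#' or two i-type genes are typically expressed.
#'
#' @param genotype_table Accession-level table with `variants` and
#'   `active_variants` list-columns.
#' @param variant_info Tibble with `variant`, `type` (i/m/s) for every
#'   variant occurring in the table (e.g. `table2_fixture()$variants` renamed,
#'   or derived from a catalog plus annotations).
#' @return List with `per_accession` (tibble `accession_id`, `genotype`,
#'   `n_active`, `n_active_i`, `three_active_i`) and
#'   `three_active_i_percent`.
#' @export
active_gene_census <- function(genotype_table, variant_info) {
  types <- stats::setNames(variant_info$type, variant_info$variant)
  carried <- unique(unlist(genotype_table$variants))
  missing <- setdiff(carried, names(types))
  if (length(missing) > 0) {
    stop("no annotation/type available for variant(s): ",
         paste(missing, collapse = ", "))
  }
  per <- tibble::tibble(
    accession_id = genotype_table$accession_id,
    genotype = genotype_table$genotype,
    n_active = lengths(genotype_table$active_variants),
    n_active_i = vapply(genotype_table$active_variants, function(v) {
      sum(types[v] == "i")
    }, integer(1)),
    n_i = vapply(genotype_table$variants, function(v) {
      sum(types[v] == "i")
    }, integer(1))
  )
  per$three_active_i <- per$n_active_i >= 3L
  list(per_accession = per,
       three_active_i_percent = round_half_up(100 * mean(per$three_active_i), 2))
}

#' Regional richness of genes, variants and genotypes
#'
#' @param genotype_table Accession-level table with `region`, `genotype` and
#'   `variants` list-column; regions must come from the package's controlled
#'   vocabulary.
#' @param variant_info Tibble `variant`, `gene` mapping variants to genes.
#' @return Tibble with one row per observed region: accession, gene, variant
#'   and genotype richness, counts of region-unique variants and genotypes,
#'   and `rank` by (variant richness, genotype richness). An attribute
#'   `unique_genotypes` carries the per-region unique genotype labels.
#' @export
regional_summary <- function(genotype_table, variant_info) {
  if (!all(genotype_table$region %in% REGION_LEVELS)) {
    stop("unknown region label(s): ",
         paste(setdiff(unique(genotype_table$region), REGION_LEVELS),
               collapse = ", "))
  }
  genes <- stats::setNames(variant_info$gene, variant_info$variant)
  regions <- intersect(REGION_LEVELS, unique(genotype_table$region))
  per_region <- lapply(regions, function(r) {
    rows <- genotype_table[genotype_table$region == r, ]
    vars <- unique(unlist(rows$variants))
    list(region = r, accessions = nrow(rows),
         variants = vars, genotypes = unique(rows$genotype),
         genes = unique(unname(genes[vars])))
  })
  names(per_region) <- regions
  uniq <- function(field) {
    lapply(regions, function(r) {
      own <- per_region[[r]][[field]]
      elsewhere <- unique(unlist(lapply(setdiff(regions, r), function(o) {
        per_region[[o]][[field]]
      })))
      sort(setdiff(own, elsewhere))
    })
  }
  uv <- uniq("variants"); ug <- uniq("genotypes")
  out <- tibble::tibble(
    region = regions,
    n_accessions = unname(vapply(per_region, `[[`, numeric(1), "accessions")),
    n_genes = unname(vapply(per_region, function(p) length(p$genes), integer(1))),
    n_variants = unname(vapply(per_region, function(p) length(p$variants), integer(1))),
    n_genotypes = unname(vapply(per_region, function(p) length(p$genotypes), integer(1))),
    n_unique_variants = unname(lengths(uv)),
    n_unique_genotypes = unname(lengths(ug))
  )
  out$rank <- rank(-(out$n_variants * 1000 + out$n_genotypes), ties.method = "min")
  out <- out[order(out$rank), ]
  attr(out, "unique_variants") <- stats::setNames(uv, regions)[out$region]
  attr(out, "unique_genotypes") <- stats::setNames(ug, regions)[out$region]
  out
}
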