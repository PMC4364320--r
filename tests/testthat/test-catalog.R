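test_that("global identity handles identical, indel and unrelated pairs", {
  set.seed(3)
  a <- random_dna(300)
  expect_equal(global_identity(a, a)$identity, 1.0)
  expect_error(global_identity("", a), "empty")
  # one 24-nt deletion: identity (L-24)/L when aligned as a single gap
  del <- paste0(substr(a, 1, 99), substr(a, 124, 300))
  expect_equal(global_identity(a, del)$identity, (300 - 24) / 300,
               tolerance = 1e-9)
  # agreement with an independent small-case affine-gap aligner
  for (r in 1:5) {
    x <- random_dna(60)
    y <- paste0(substr(x, 1, 20), substr(x, 33, 60))  # 12-nt deletion
    expect_equal(global_identity(x, y)$identity, nw_identity(x, y),
                 tolerance = 1e-9)
  }
  # symmetry
  b <- random_dna(280)
  expect_equal(global_identity(a, b)$identity, global_identity(b, a)$identity,
               tolerance = 1e-9)
})

test_that("unrelated random sequences fall well below the gene threshold", {
  set.seed(4)
  ids <- replicate(200, global_identity(random_dna(300), random_dna(300))$identity)
  expect_lt(max(ids), 0.6)
})

test_that("clustering merges repeat-length variants and separates genes", {
  vt <- fixture_variants()
  a <- vt$sequences[["TuA3-538a"]]
  # 24-bp repeat indel + a couple of substitutions: same gene, two variants
  motif_nt <- lmwgs:::encode_protein("QQPGQLVS")
  at <- regexpr(motif_nt, a, fixed = TRUE)[1]
  b <- paste0(substr(a, 1, at - 1), motif_nt, substr(a, at, nchar(a)))
  substr(b, 900, 900) <- chartr("ACGT", "TGCA", substr(b, 900, 900))
  sizes <- c(s1 = 538L, s2 = 562L)
  cat2 <- cluster_variants(c(s1 = a, s2 = b), sizes, c(s1 = 10, s2 = 2),
                           t_gene = 0.95)
  expect_equal(nrow(cat2$genes), 1L)
  expect_equal(nrow(cat2$variants), 2L)
  # sequences of a different gene stay apart even at a permissive threshold
  c_ <- vt$sequences[["TuA3-397a"]]
  cat3 <- cluster_variants(c(s1 = a, s3 = c_), c(s1 = 538L, s3 = 397L),
                           c(s1 = 10, s3 = 5), t_gene = 0.85)
  expect_equal(nrow(cat3$genes), 2L)
})

test_that("fixture clustering recovers 8 genes and 39 variants with stable names", {
  vt <- fixture_variants()
  cfg <- fixture_population_config()
  counts <- stats::setNames(cfg$variants$accession_count, cfg$variants$variant)
  sizes <- stats::setNames(cfg$variants$size, cfg$variants$variant)
  idm <- fixture_idm()
  cat <- cluster_variants(vt$sequences, sizes, counts, t_gene = 0.85,
                          identity = idm)
  expect_equal(nrow(cat$genes), 8L)
  expect_equal(nrow(cat$variants), 39L)
  # gene partition equals the configured gene assignment
  truth_gene <- cfg$variants$gene[match(cat$variants$sequence_id,
                                        cfg$variants$variant)]
  expect_equal(length(unique(paste(cat$variants$gene_name, truth_gene))), 8L)
  # majority-variant naming: most frequent variants anchor the gene names
  expect_true(all(c("TuA3-502", "TuA3-538", "TuA3-576", "TuA3-385",
                    "TuA3-397", "TuA3-460") %in% cat$genes$gene_name))
  # letter suffixes in descending frequency: the 48%-frequency variant of the
  # 502 gene takes the 'a' suffix
  v502 <- cat$variants[cat$variants$gene_name == "TuA3-502" &
                         cat$variants$size == 502L, ]
  expect_equal(v502$sequence_id[v502$variant_name == "TuA3-502a"], "TuA3-502a")
  # re-running yields identical names (naming is a pure function)
  cat_b <- cluster_variants(vt$sequences, sizes, counts, t_gene = 0.85,
                            identity = idm)
  expect_identical(cat$variants, cat_b$variants)
})

test_that("clustering is invariant under input permutation", {
  vt <- fixture_variants()
  cfg <- fixture_population_config()
  counts <- stats::setNames(cfg$variants$accession_count, cfg$variants$variant)
  sizes <- stats::setNames(cfg$variants$size, cfg$variants$variant)
  idm <- fixture_idm()
  ref <- cluster_variants(vt$sequences, sizes, counts, t_gene = 0.85,
                          identity = idm)
  set.seed(7)
  for (r in 1:20) {
    perm <- sample(length(vt$sequences))
    got <- cluster_variants(vt$sequences[perm], sizes[perm], counts[perm],
                            t_gene = 0.85, identity = idm)
    expect_identical(got$variants, ref$variants)
    expect_identical(got$genes, ref$genes)
  }
  # end-to-end (alignment included) on a small subset
  sub <- c("TuA3-502a", "TuA3-502b", "TuA3-520", "TuA3-397a", "TuA3-397b",
           "TuA3-385a")
  ref_s <- cluster_variants(vt$sequences[sub], sizes[sub], counts[sub],
                            t_gene = 0.85)
  for (r in 1:3) {
    perm <- sample(length(sub))
    got_s <- cluster_variants(vt$sequences[sub][perm], sizes[sub][perm],
                              counts[sub][perm], t_gene = 0.85)
    expect_identical(got_s$variants, ref_s$variants)
  }
})

test_that("variant frequencies reproduce the published population shares", {
  fx <- table2_fixture()
  freqs <- variant_frequencies(fx$genotypes, fx$variants$variant)
  pct <- stats::setNames(freqs$percent, freqs$variant)
  expect_equal(unname(pct["TuA3-397a"]), 87.26)
  expect_equal(unname(pct["TuA3-502a"]), 48.41)
  expect_equal(unname(pct["TuA3-502b"]), 22.29)
  expect_equal(unname(pct["TuA3-576b"]), 9.55)
  cnt <- stats::setNames(freqs$count, freqs$variant)
  expect_equal(round_538abc <- sum(pct[c("TuA3-538a", "TuA3-538b", "TuA3-538c")]),
               85.35, tolerance = 0.011)
  # s-type gene variant counts: 21 / 3 / 4 accessions
  expect_equal(unname(cnt[c("TuA3-460", "TuA3-463", "TuA3-474")]), c(21L, 3L, 4L))
  # a variant absent from every genotype counts zero
  f2 <- variant_frequencies(fx$genotypes, c(fx$variants$variant, "TuA3-998"))
  expect_equal(f2$count[f2$variant == "TuA3-998"], 0L)
  expect_equal(f2$percent[f2$variant == "TuA3-998"], 0)
  # orphan variants in the table raise a consistency error
  broken <- fx$genotypes
  broken$variants[[1]] <- c(broken$variants[[1]], "TuA3-777")
  expect_error(variant_frequencies(broken, fx$variants$variant), "absent from")
})

test_that("co-segregating variant groups are recovered with their supports", {
  fx <- table2_fixture()
  h <- haplotype_cosegregation(fx$genotypes)
  keys <- vapply(h$variants, function(v) paste(sort(v), collapse = "+"),
                 character(1))
  expect_true("TuA3-406+TuA3-502b+TuA3-538c" %in% keys)
  expect_equal(h$support[keys == "TuA3-406+TuA3-502b+TuA3-538c"], 35L)
  expect_true("TuA3-498+TuA3-535+TuA3-597" %in% keys)
  expect_equal(h$support[keys == "TuA3-498+TuA3-535+TuA3-597"], 5L)
  # all-distinct supports produce no groups
  toy <- tibble::tibble(
    accession_id = c("a", "b", "c"),
    variants = list(c("v1", "v2"), c("v2", "v3"), c("v3", "v1")))
  expect_equal(nrow(haplotype_cosegregation(toy)), 0L)
})
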