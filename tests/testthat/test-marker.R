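test_that("virtual amplicon sizes equal the generator's theoretical sizes", {
  vt <- fixture_variants()
  ps <- lmwgs_primer_sets()
  expect_true(all(nchar(c(ps$forward, ps$reverse)) >= 15))
  for (i in seq_len(nrow(vt$truth))) {
    dna <- vt$sequences[[vt$truth$variant_id[i]]]
    for (k in seq_len(nrow(ps))) {
      want <- vt$truth[[paste0("size_", ps$name[k])]][i]
      expect_equal(virtual_amplicon(dna, ps[k, ]), want,
                   label = paste(vt$truth$variant_id[i], ps$name[k]))
    }
  }
  # the s-type gene is the non-amplified (N) case for LMWGS3
  s_var <- vt$truth$variant_id[vt$truth$subunit_type == "s"]
  expect_true(all(is.na(vt$truth$size_LMWGS3[vt$truth$variant_id %in% s_var])))
})

test_that("a SNP in a primer landing site abolishes amplification", {
  vt <- fixture_variants()
  dna <- vt$sequences[["TuA3-502a"]]
  ps <- lmwgs_primer_sets()
  p1 <- ps[ps$name == "LMWGS1", ]
  pos <- regexpr(p1$forward, dna, fixed = TRUE)[1]
  hit <- pos + nchar(p1$forward) - 1L   # 3' end of the forward site
  mutated <- dna
  substr(mutated, hit, hit) <- chartr("ACGT", "TGCA", substr(dna, hit, hit))
  expect_true(is.na(virtual_amplicon(mutated, p1)))
  expect_false(is.na(virtual_amplicon(dna, p1)))
})

test_that("a 24-bp repeat-domain insertion grows the amplicon by 24 bp", {
  vt <- fixture_variants()
  dna <- vt$sequences[["TuA3-538a"]]
  p1 <- lmwgs_primer_sets()[1, ]
  base <- virtual_amplicon(dna, p1)
  motif_nt <- lmwgs:::encode_protein("QQPGQLVS")   # this gene's repeat unit
  at <- regexpr(motif_nt, dna, fixed = TRUE)[1]
  expect_gt(at, 0)
  longer <- paste0(substr(dna, 1, at - 1), motif_nt, substr(dna, at, nchar(dna)))
  expect_equal(virtual_amplicon(longer, p1), base + 24L)
})

test_that("duplicated landing sites raise an ambiguous-amplification error", {
  vt <- fixture_variants()
  dna <- vt$sequences[["TuA3-397a"]]
  expect_error(virtual_amplicon(paste0(dna, dna), lmwgs_primer_sets()[1, ]),
               "ambiguous amplification")
})

test_that("profiles carry one correspondence triplet per gene", {
  pop <- fixture_pop()
  profs <- fixture_profiles()
  # a U14 accession (the sequenced-accession genotype) has seven genes
  u14 <- pop$accessions$accession_id[pop$accessions$genotype == "U14"][1]
  expect_equal(nrow(profs[[u14]]$triplets), 7L)
  expect_equal(length(profs[[u14]]$sizes$LMWGS1), 7L)
  # the s-gene triplet of a U10 accession has N in the LMWGS3 slot
  u10 <- pop$accessions$accession_id[pop$accessions$genotype == "U10"][1]
  tt <- profs[[u10]]$triplets
  expect_true(is.na(tt$LMWGS3[tt$sequence_id == "TuA3-460"]))
  expect_false(anyNA(tt$LMWGS1))
  # each fragment participates in at most one triplet: per-set sizes unique
  # within this accession
  expect_equal(anyDuplicated(tt$LMWGS1), 0L)
  # empty accession gives an empty profile
  ep <- build_profile(character(0), accession_id = "none")
  expect_equal(nrow(ep$triplets), 0L)
  expect_true(all(lengths(ep$sizes) == 0))
})

test_that("genotype calling groups by size multiset and splits by SNPs", {
  vt <- fixture_variants()
  s <- vt$sequences
  mk <- function(id, vars) build_profile(s[vars], accession_id = id)
  # identical accessions collapse to one genotype
  p <- list(mk("a1", c("TuA3-385a", "TuA3-502a")),
            mk("a2", c("TuA3-385a", "TuA3-502a")))
  expect_equal(length(unique(call_genotypes(p)$genotype)), 1L)
  # one differing fragment size separates genotypes
  p2 <- list(mk("a1", c("TuA3-385a", "TuA3-502a")),
             mk("a2", c("TuA3-385a", "TuA3-520")))
  expect_equal(length(unique(call_genotypes(p2)$genotype)), 2L)
  # same sizes, different sequences: split only when sequences are given
  p3 <- list(mk("a1", c("TuA3-385a", "TuA3-502a")),
             mk("a2", c("TuA3-385a", "TuA3-502b")))
  expect_equal(length(unique(call_genotypes(p3)$genotype)), 1L)
  seqs <- list(a1 = s[c("TuA3-385a", "TuA3-502a")],
               a2 = s[c("TuA3-385a", "TuA3-502b")])
  calls3 <- call_genotypes(p3, seqs)
  expect_equal(length(unique(calls3$genotype)), 2L)
  expect_true(all(calls3$snp_discriminated))
})

test_that("fixture genotyping finds 15 genotypes with one SNP-discriminated pair", {
  pop <- fixture_pop()
  calls <- fixture_calls()
  expect_equal(length(unique(calls$genotype)), 15L)
  truth <- pop$accessions$genotype[match(calls$accession_id,
                                         pop$accessions$accession_id)]
  # called partition equals the configured genotype partition
  expect_equal(length(unique(paste(calls$genotype, truth))), 15L)
  flagged <- sort(unique(truth[calls$snp_discriminated]))
  expect_equal(flagged, c("U5", "U6"))
  # invariance to accession input order
  profs <- fixture_profiles()
  set.seed(99)
  perm <- sample(length(profs))
  calls_perm <- call_genotypes(profs[perm], pop$sequences[perm])
  expect_identical(calls, calls_perm)
})
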