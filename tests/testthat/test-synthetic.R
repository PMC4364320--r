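test_that("zero-mutation templates produce intact, correctly typed genes", {
  cases <- list(list(type = "i", size = 520, start = "I"),
                list(type = "m", size = 400, start = "M"),
                list(type = "s", size = 463, start = "S"))
  for (cs in cases) {
    g <- make_gene(gene_template("gX", cs$type, size = cs$size))
    expect_equal(g$truth$orf_status, "active")
    expect_equal(g$truth$n_internal_stops, 0L)
    expect_equal(g$truth$size_LMWGS1, cs$size)
    orf <- find_orf(g$dna)
    expect_length(orf$internal_stops, 0)
    cl <- cleave_and_type(orf$protein)
    expect_equal(cl$subunit_type, cs$type)
    expect_equal(substr(cl$mature, 1, 1), cs$start)
    if (cs$type == "i") {
      seg <- segment_domains(cl$mature, "i")
      expect_equal(diff(seg$domains[["N-terminal"]]), 0L)
    }
  }
})

test_that("templates with the wrong cysteine census are rejected by domain name", {
  expect_error(gene_template("bad", "m", size = 400, cterm2 = "QQPQQPQ"),
               "cterm2")
  expect_error(gene_template("bad", "m", size = 400,
                             cterm3 = "CQPQCQPQLV"),
               "cterm3")
})

test_that("designed premature stops are truth-labelled with their domain", {
  t <- gene_template("gM", "m", size = 430)
  # repetitive domain: mature index = nterm (11) + offset, full index + 21
  g_rep <- make_gene(t, stops = 20L + 11L + 6L)
  expect_equal(g_rep$truth$orf_status, "pseudo")
  expect_equal(g_rep$truth$stop_domain, "repetitive")
  # C-terminal II: full-protein index just after C-I
  rep_len <- 8L * t$repeat_count
  ct2 <- 20L + 11L + rep_len + 105L + 5L
  g_ct2 <- make_gene(t, stops = ct2)
  expect_equal(g_ct2$truth$stop_domain, "C-terminal II")
  expect_equal(g_ct2$truth$n_internal_stops, 1L)
})

test_that("truth domain boundaries tile the mature protein", {
  vt <- fixture_variants()$truth
  for (i in seq_len(nrow(vt))) {
    d <- vt$domains[[i]]
    widths <- vapply(d, function(x) x[2] - x[1], integer(1))
    expect_equal(sum(widths), vt$mature_length[i])
    ends <- vapply(d, `[`, integer(1), 2)
    starts <- vapply(d, `[`, integer(1), 1)
    expect_equal(unname(starts[-1]), unname(ends[-length(ends)]))
  }
})

test_that("population expansion matches configured counts and is deterministic", {
  pop <- fixture_pop()
  expect_equal(nrow(pop$accessions), 157L)
  regions <- c("Iraq", "Iran", "Armenia", "NE Lebanon", "Syria", "SE Turkey")
  expect_equal(as.integer(table(pop$accessions$region)[regions]),
               c(1L, 1L, 5L, 82L, 5L, 63L))
  expect_true(all(lengths(pop$sequences) %in% 6:7))
  # single-genotype, single-accession config reproduces its multiset exactly
  fx <- table2_fixture()
  cfg1 <- population_config(
    fx$variants,
    fx$genotype_variants[fx$genotype_variants$genotype == "U6", ],
    tibble::tibble(genotype = "U6", region = "Syria", n = 1L))
  p1 <- make_population(cfg1)
  expect_equal(sort(names(p1$sequences[[1]])),
               sort(fx$genotype_variants$variant[fx$genotype_variants$genotype == "U6"]))
  # byte-identical regeneration
  p2 <- make_population(fixture_population_config())
  expect_identical(pop$sequences, p2$sequences)
})

test_that("genotypes referencing undefined variants are a configuration error", {
  fx <- table2_fixture()
  gv <- rbind(fx$genotype_variants,
              tibble::tibble(genotype = "U1", gene = "TuA3-999",
                             variant = "TuA3-999x"))
  expect_error(population_config(fx$variants, gv, fx$region_counts),
               "undefined variant")
})

test_that("the packaged fixture reproduces the published table structure", {
  fx <- table2_fixture()
  expect_equal(length(unique(fx$genotype_variants$genotype)), 15L)
  expect_equal(length(unique(fx$variants$gene)), 8L)
  expect_equal(nrow(fx$variants), 39L)
  expect_equal(sum(fx$region_counts$n), 157L)
  expect_equal(nrow(fx$genotypes), 157L)
  expect_equal(sum(fx$variants$active), 21L)
  expect_equal(sort(unique(fx$variants$type)), c("i", "m", "s"))
  # i-type genes lack an N-terminal domain by construction; every genotype
  # carries the three i-type genes
  itype <- fx$variants$variant[fx$variants$type == "i"]
  per_geno <- split(fx$genotype_variants$variant, fx$genotype_variants$genotype)
  expect_true(all(vapply(per_geno, function(v) sum(v %in% itype) == 3L, logical(1))))
})

test_that("stochastic mutations are seed-reproducible and truth-consistent", {
  t <- gene_template("gMut", "i", size = 540)
  mut <- mutation_spec(snp_rate = 0.002, indel_rate = 1.5, indel_unit = 24L,
                       premature_stop_probability = 0.5, seed = 11L)
  g1 <- make_gene(t, mut, label = "a1")
  g2 <- make_gene(t, mut, label = "a1")
  expect_identical(g1$dna, g2$dna)
  g3 <- make_gene(t, mut, label = "a2")
  expect_false(identical(g1$dna, g3$dna))
  # truth amplicon arithmetic agrees with exact-match measurement
  ps <- lmwgs_primer_sets()
  hits <- 0L
  for (lab in paste0("acc", 1:25)) {
    g <- make_gene(t, mut, label = lab)
    for (k in seq_len(nrow(ps))) {
      want <- g$truth[[paste0("size_", ps$name[k])]]
      got <- tryCatch(virtual_amplicon(g$dna, ps[k, ]),
                      error = function(e) NA_integer_)
      if (!is.na(want)) {
        expect_equal(got, want)
        hits <- hits + 1L
      }
    }
    # indels shift sizes by whole motif units
    if (!is.na(g$truth$size_LMWGS1)) {
      expect_equal((g$truth$size_LMWGS1 - 540L) %% 24L, 0L)
    }
  }
  expect_gt(hits, 30L)
})
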