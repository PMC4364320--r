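test_that("translation starts at the first ATG and reads through premature stops", {
  orf <- find_orf("ATGGGTTGA")
  expect_equal(orf$protein, "MG")
  expect_length(orf$internal_stops, 0)

  orf2 <- find_orf("ATGTAGGGTTGA")
  expect_equal(orf2$protein, "M*G")
  expect_equal(orf2$internal_stops, 2L)

  expect_error(find_orf("CCCCCCTTT"), "no ORF")
  expect_error(find_orf("ATG!GGTTT"), "non-IUPAC")
  expect_error(find_orf("AT"), "shorter")
})

test_that("signal cleavage and typing follow the diagnostic mature-start motifs", {
  sig <- lmwgs:::SIGNAL_AA
  filler <- strrep("QQPPFSQQ", 10)
  tail <- paste0(filler, "CAAAAACAAAAAC")
  s_prot <- paste0(sig, "MENSHIPGLEKPS", tail)
  cs <- cleave_and_type(s_prot)
  expect_equal(cs$subunit_type, "s")
  expect_true(startsWith(cs$mature, "SHIPGLEKPS"))

  i_prot <- paste0(sig, "ISQQ", tail)
  ci <- cleave_and_type(i_prot)
  expect_equal(ci$subunit_type, "i")
  expect_equal(substr(ci$mature, 1, 1), "I")

  m_prot <- paste0(sig, "METSHIPGLER", tail)
  cm <- cleave_and_type(m_prot)
  expect_equal(cm$subunit_type, "m")
  expect_equal(substr(cm$mature, 1, 4), "METS")

  expect_error(cleave_and_type("MKT"), "too short")
})

test_that("domain segmentation puts 6/1/1 cysteines in the C-terminal domains", {
  vt <- fixture_variants()
  ann <- annotate_set(vt$sequences)
  expect_true(all(ann$n_cys == 8L))
  expect_true(all(ann$cys_c1 == 6L))
  expect_true(all(ann$cys_c2 == 1L))
  expect_true(all(ann$cys_c3 == 1L))
  # i-type subunits lack the N-terminal domain
  for (i in which(ann$subunit_type == "i")) {
    d <- ann$annotation[[i]]$domains
    expect_equal(diff(d[["N-terminal"]]), 0L)
  }
  # tiling: domains are contiguous and cover the mature protein
  for (i in seq_len(nrow(ann))) {
    a <- ann$annotation[[i]]
    widths <- vapply(a$domains, function(x) x[2] - x[1], integer(1))
    expect_equal(sum(widths), nchar(a$mature))
  }
  # annotation matches generator truth exactly at zero mutation
  tr <- vt$truth
  expect_equal(unname(ann$subunit_type),
               tr$subunit_type[match(ann$sequence_id, tr$variant_id)])
  expect_equal(unname(ann$orf_status),
               tr$orf_status[match(ann$sequence_id, tr$variant_id)])
})

test_that("atypical cysteine architectures are flagged but segmented", {
  mat <- paste0("METSHIPGLER", strrep("QQPPFSQQ", 8), "CAAAAACAAAAA")
  expect_warning(seg <- segment_domains(mat, "m"), "atypical")
  expect_equal(seg$n_cys, 2L)
  mat9 <- paste0("METSHIPGLER", strrep("QQPPFSQQ", 8),
                 "C", strrep("QAC", 8))
  expect_warning(seg9 <- segment_domains(mat9, "m"), "extra cysteine")
  expect_equal(seg9$n_cys, 9L)
})

test_that("pseudo-gene status is equivalent to internal stops and stops localize", {
  vt <- fixture_variants()
  fx <- table2_fixture()
  ann <- lapply(vt$sequences, annotate_gene)
  for (v in names(ann)) {
    orf <- find_orf(vt$sequences[[v]])
    expect_equal(ann[[v]]$orf_status == "pseudo", length(orf$internal_stops) > 0)
  }
  # reference-based localization: TuA3-402 stop sits in C-terminal II, with
  # the intact TuA3-400 as reference
  orf402 <- find_orf(vt$sequences[["TuA3-402"]])
  loc <- localize_stop(orf402$protein, ann[["TuA3-400"]])
  expect_equal(loc$stop_domain, "C-terminal II")
  expect_false(loc$self_referenced)
  # all-pseudo gene falls back to self-referenced localization
  orf385 <- find_orf(vt$sequences[["TuA3-385a"]])
  loc385 <- localize_stop(orf385$protein, NULL)
  expect_equal(loc385$stop_domain, "repetitive")
  expect_true(loc385$self_referenced)
  # a stop within the signal peptide reports "signal"
  expect_equal(localize_stop(paste0("MKTFLVLAL*", strrep("Q", 40)))$stop_domain,
               "signal")
  # annotated stop domains agree with the fixture's reported domains (first
  # reported domain when a variant carries two stops)
  first_dom <- vapply(strsplit(fx$variants$stop_domains, ";"), `[`, character(1), 1)
  names(first_dom) <- fx$variants$variant
  for (v in names(ann)) {
    if (ann[[v]]$orf_status == "pseudo") {
      expect_equal(ann[[v]]$stop_domain, unname(first_dom[v]), label = v)
    }
  }
})

test_that("molecular weight is additive over the packaged residue masses", {
  expect_equal(molecular_weight(""), 18.0153, tolerance = 1e-6)
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecular_weight("ACDE"), 436.44, tolerance = 0.01)
  expect_error(molecular_weight("AXZ"), "position 2")
  set.seed(1)
  aas <- names(lmwgs:::RESIDUE_MASS)
  for (r in 1:10) {
    a <- paste(sample(aas, 12, TRUE), collapse = "")
    b <- paste(sample(aas, 7, TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("isoelectric point is bracketed, ordered and matches a grid scan", {
  expect_gt(isoelectric_point("K"), isoelectric_point("D"))
  expect_gt(lmwgs:::net_charge("ACDEKR", 0), 0)
  expect_lt(lmwgs:::net_charge("ACDEKR", 14), 0)
  set.seed(2)
  aas <- names(lmwgs:::RESIDUE_MASS)
  for (r in 1:6) {
    p <- paste(sample(aas, 30, TRUE), collapse = "")
    grid <- seq(0, 14, by = 0.001)
    charges <- vapply(grid, function(ph) lmwgs:::net_charge(p, ph), numeric(1))
    pi_grid <- grid[which.min(abs(charges))]
    expect_equal(isoelectric_point(p), pi_grid, tolerance = 0.02)
  }
})
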