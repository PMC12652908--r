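test_that("identical sequences give zero divergence and an undefined ratio", {
  cds <- random_cds(20)
  r <- ng86(cds, cds)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_identical(r$status, "ks_zero")
})

test_that("a lone synonymous difference lands entirely in Sd", {
  r <- ng86("TTT", "TTC")  # Phe -> Phe
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
})

test_that("site counts conserve S + N = 3 x codons and ng86 is symmetric", {
  set.seed(41)
  for (i in 1:10) {
    a <- random_cds(40)
    b <- random_cds(40)
    ra <- ng86(a, b)
    rb <- ng86(b, a)
    expect_equal(ra$S + ra$N, 3 * ra$n_codons, tolerance = 1e-12)
    expect_equal(ra[c("S", "N", "Sd", "Nd", "pS", "pN")],
                 rb[c("S", "N", "Sd", "Nd", "pS", "pN")], tolerance = 1e-12)
  }
})

test_that("gapped and ambiguous codon columns are dropped pairwise", {
  a <- "ATG---GCTNNNAAA"
  b <- "ATGCCCGCCGGGAAA"
  r <- ng86(a, b)
  expect_equal(r$n_codons, 3)  # ATG/ATG, GCT/GCC, AAA/AAA
  expect_equal(r$Sd, 1)        # GCT -> GCC synonymous
  expect_equal(r$Nd, 0)
})

test_that("counting matches the exhaustive pathway oracle on random codon pairs", {
  set.seed(42)
  sense <- panfam:::.SENSE_CODONS
  for (i in 1:150) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    got <- ng86(c1, c2)
    want <- oracle_ng86_pair(c1, c2)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  }
})

test_that("stop-blocked pathways are excluded from the averaging", {
  # TGT (Cys) <-> TGG (Trp) would not traverse a stop; but TAT <-> TGG has
  # the intermediate TAG/TGG... enumerate one known case: AGA <-> TGG, where
  # path via TGA (stop) must be dropped. Oracle applies the same rule
  # independently.
  for (pair in list(c("AGA", "TGG"), c("TCA", "TTG"), c("AGG", "TGT"))) {
    got <- ng86(pair[1], pair[2])
    want <- oracle_ng86_pair(pair[1], pair[2])
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction saturates gracefully", {
  # single codon with one synonymous difference: pS = 1 / (S ~ 1/3) >= 3/4
  r <- ng86("TTT", "TTC")
  expect_identical(r$status, "saturated")
  expect_true(is.na(r$ratio))
})

test_that("codon back-threading preserves structure and catches mismatches", {
  th <- backthread_codons("M-A", "MKA", "ATGGCT", "ATGAAAGCA")
  expect_equal(nchar(th$codon_a), 9)
  expect_identical(th$codon_a, "ATG---GCT")
  expect_identical(th$codon_b, "ATGAAAGCA")

  cds <- random_cds(5)
  prot <- translate_cds(cds)
  same <- backthread_codons(prot, prot, cds, cds)
  expect_identical(same$codon_a, cds)

  expect_error(backthread_codons("MA", "MK", "ATGGCT", "ATGCCC"),
               "does not translate")
})

test_that("kaks_pair aligns, threads and estimates in one step", {
  set.seed(43)
  cds <- random_cds(60)
  # introduce a few synonymous third-position changes
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  syn_sub <- function(codon) {
    for (nt in c("A", "C", "G", "T")) {
      alt <- paste0(substr(codon, 1, 2), nt)
      if (alt != codon &&
          panfam:::.GENETIC_CODE[[alt]] == panfam:::.GENETIC_CODE[[codon]])
        return(alt)
    }
    codon
  }
  codons2 <- codons
  codons2[1:10] <- vapply(codons[1:10], syn_sub, "")
  cds2 <- paste(codons2, collapse = "")
  r <- kaks_pair(cds, cds2)
  expect_equal(r$Nd, 0)
  expect_true(r$Sd > 0)
  expect_equal(r$Ka, 0)
})

test_that("orthogroup Ka/Ks enumerates cross-genome pairs and summarises", {
  set.seed(44)
  cds <- setNames(replicate(4, random_cds(30)), c("a", "b", "c", "d"))
  og <- ogset_of(list(c("a", "b", "c")))
  g2g <- c(a = "G1", b = "G2", c = "G3", d = "G1")
  res <- og_kaks(og, cds, g2g)
  expect_equal(nrow(res$pairs), 3)  # C(3,2), all cross-genome
  expect_equal(res$summary$n_pairs, 3)

  # same-genome pairs skipped
  og2 <- ogset_of(list(c("a", "d", "b")))
  res2 <- og_kaks(og2, cds, g2g)
  expect_equal(nrow(res2$pairs), 2)  # a-d share G1

  og3 <- ogset_of(list(c("a", "b")), singletons = "c")
  expect_message(og_kaks(og3, cds["a"], g2g), "fewer than 2")
})
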