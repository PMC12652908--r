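motif_row <- function(name, iupac, category) {
  data.frame(name = name, iupac = iupac, category = category,
             stringsAsFactors = FALSE)
}

test_that("direct and reverse-complement matches are both counted", {
  motifs <- motif_row("CGTCA-motif", "CGTCA", "hormone")
  expect_equal(unname(scan_motifs(c(s = "CGTCA"), motifs)[1, 1]), 1)
  expect_equal(unname(scan_motifs(c(s = "TGACG"), motifs)[1, 1]), 1)
  expect_equal(unname(scan_motifs(c(s = "AAAAA"), motifs)[1, 1]), 0)
  # palindromic context: forward + reverse occurrences accumulate
  expect_equal(unname(scan_motifs(c(s = "CGTCATGACG"), motifs)[1, 1]), 2)
})

test_that("N in the scanned sequence matches nothing", {
  motifs <- motif_row("m", "ACGTG", "stress")
  expect_equal(unname(scan_motifs(c(s = "ACGTG"), motifs)[1, 1]), 1)
  expect_equal(unname(scan_motifs(c(s = "ACGNG"), motifs)[1, 1]), 0)
  expect_error(scan_motifs(c(s = "ACGXG"), motifs), "invalid character")
})

test_that("IUPAC degeneracy in the motif is honoured", {
  motifs <- motif_row("deg", "RCGTW", "stress")
  expect_equal(unname(scan_motifs(c(s = "ACGTA"), motifs)[1, 1]),
               oracle_count_both("ACGTA", "RCGTW"))
  expect_equal(unname(scan_motifs(c(s = "GCGTT"), motifs)[1, 1]),
               oracle_count_both("GCGTT", "RCGTW"))
})

test_that("scanning equals the sliding-window oracle and is strand-symmetric", {
  set.seed(51)
  motifs <- read_motif_table()
  seqs <- setNames(vapply(rep(300, 25), random_dna, ""),
                   paste0("p", 1:25))
  got <- scan_motifs(seqs, motifs)
  for (i in seq_along(seqs)) for (j in seq_len(nrow(motifs))) {
    expect_identical(got[i, j],
                     as.integer(oracle_count_both(seqs[[i]],
                                                  motifs$iupac[j])))
  }
  rcs <- setNames(vapply(seqs, revcomp, ""), names(seqs))
  expect_identical(unname(scan_motifs(rcs, motifs)), unname(got))
})

test_that("per-orthogroup category proportions are member fractions", {
  motifs <- rbind(motif_row("m1", "CGTCA", "hormone"),
                  motif_row("m2", "GGGCGG", "light"))
  hits <- matrix(c(2L, 0L,
                   1L, 0L,
                   1L, 0L,
                   0L, 0L), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), c("m1", "m2")))
  og <- ogset_of(list(paste0("g", 1:4)))
  prof <- og_category_profile(hits, motifs, og)
  expect_equal(prof["OG001", "hormone"], 0.75)
  expect_equal(prof["OG001", "light"], 0)
  expect_error(og_category_profile(hits, motifs,
                                   ogset_of(list(c("g1", "g9")))),
               "no motif scan")
})

test_that("planted promoter motifs are recovered from simulated genomes", {
  # long planted motifs so background hits are essentially impossible
  mspec <- data.frame(
    name = c("plantA", "plantB"),
    iupac = c("AGGCCATTGCAT", "TTGACCTTGACC"),
    category = c("hormone", "stress"),
    rate = c(1.0, 0.0),
    stringsAsFactors = FALSE)
  spec <- default_og_spec()[1:4, ]
  spec$p <- 1
  cfg <- sim_config(n_genomes = 6, og_spec = spec, motif_spec = mspec,
                    og_motif_rates = list(sim02 = c(plantB = 1.0)),
                    seed = 77)
  d <- file.path(tempdir(), "regsim")
  sim <- simulate_pan_genome(cfg, d)
  # re-extract promoters through the scan path
  fam <- do.call(rbind, lapply(seq_len(nrow(sim$paths)), function(i) {
    g <- sim$paths[i, ]
    sf <- scan_family(read_fasta(g$fasta), read_gff3(g$gff),
                      read_domtblout(g$hits), g$genome_id)
    data.frame(gene_id = names(sf$upstream), up = unname(sf$upstream),
               stringsAsFactors = FALSE)
  }))
  up <- setNames(fam$up, fam$gene_id)
  hits <- scan_motifs(up, mspec)
  truth <- sim$truth$genes
  ogs <- split(truth$gene_id, truth$og_id)
  og <- structure(list(ogs = ogs, singletons = character()),
                  class = "orthogroup_set")
  prof <- og_category_profile(hits[truth$gene_id, , drop = FALSE],
                              mspec, og)
  expect_equal(unname(prof[, "hormone"]), rep(1, 4))  # rate 1.0 everywhere
  expect_equal(prof["sim02", "stress"], 1)            # per-OG override
  # scanning can only add background chance hits on top of planted copies
  planted <- sim$truth$motif_counts
  rownames(planted) <- planted$gene_id
  planted <- as.matrix(planted[rownames(hits), c("plantA", "plantB")])
  expect_true(all(hits >= planted))
  expect_gte(mean(hits == planted), 0.95)
})
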