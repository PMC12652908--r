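small_spec <- function(n = 6, p = 1, omega = 0.3, size = 1L, len = 60L) {
  data.frame(og_id = sprintf("sim%02d", seq_len(n)), p = p, size = size,
             omega = omega, codon_length = len,
             chrom = paste0("chr", (seq_len(n) - 1L) %% 2L + 1L),
             jrl = c(TRUE, rep(FALSE, n - 1L)), stringsAsFactors = FALSE)
}

test_that("configuration validation enforces probabilities and the seed", {
  expect_error(sim_config(n_genomes = 3), "seed")
  bad <- small_spec(); bad$p[1] <- 1.4
  expect_error(sim_config(og_spec = bad, seed = 1))
  bad2 <- small_spec(); bad2$omega[2] <- -1
  expect_error(sim_config(og_spec = bad2, seed = 1))
})

test_that("identical seeds reproduce byte-identical study files", {
  cfg <- sim_config(n_genomes = 3, og_spec = small_spec(), seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_pan_genome(cfg, d1)
  simulate_pan_genome(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("presence probability one fills the presence matrix", {
  cfg <- sim_config(n_genomes = 4, og_spec = small_spec(p = 1), seed = 11)
  sim <- simulate_pan_genome(cfg, tempfile())
  expect_true(all(sim$truth$presence == 1L))
})

test_that("realized presence tracks the planted probability binomially", {
  spec <- small_spec(n = 2)
  spec$p <- c(0.5, 1)
  cfg <- sim_config(n_genomes = 16, og_spec = spec, seed = 13)
  sim <- simulate_pan_genome(cfg, tempfile())
  k <- sum(sim$truth$presence["sim01", ])
  expect_gte(k, qbinom(0.001, 16, 0.5))
  expect_lte(k, qbinom(0.999, 16, 0.5))
  expect_equal(sum(sim$truth$presence["sim02", ]), 16)
})

test_that("scanning the emitted files reproduces the planted membership", {
  cfg <- sim_config(n_genomes = 3, og_spec = small_spec(p = 0.8), seed = 15)
  sim <- simulate_pan_genome(cfg, tempfile())
  for (i in seq_len(nrow(sim$paths))) {
    g <- sim$paths[i, ]
    fam <- scan_family(read_fasta(g$fasta), read_gff3(g$gff),
                       read_domtblout(g$hits), g$genome_id,
                       jrl_hits = read_domtblout(g$jrl_hits))
    want <- sim$truth$genes[sim$truth$genes$genome_id == g$genome_id, ]
    expect_setequal(fam$genes$gene_id, want$gene_id)
    m <- merge(fam$genes, want, by = "gene_id")
    expect_equal(m$chrom.x, m$chrom.y)
    expect_equal(m$start.x, m$start.y)
    expect_equal(m$end.x, m$end.y)
    expect_equal(m$strand.x, m$strand.y)
    expect_equal(m$has_jrl.x, m$has_jrl.y)
    # CDS extracted through the reader translates cleanly
    expect_true(all(!grepl("\\*", fam$proteins)))
  }
})

test_that("omega = 0 yields zero nonsynonymous divergence between genomes", {
  cfg <- sim_config(n_genomes = 3, og_spec = small_spec(omega = 0),
                    subs_per_codon = 0.4, seed = 17)
  sim <- simulate_pan_genome(cfg, tempfile())
  fams <- lapply(seq_len(nrow(sim$paths)), function(i) {
    g <- sim$paths[i, ]
    scan_family(read_fasta(g$fasta), read_gff3(g$gff),
                read_domtblout(g$hits), g$genome_id)
  })
  cds <- unlist(lapply(fams, `[[`, "cds"))
  truth <- sim$truth$genes
  for (og in unique(truth$og_id)) {
    members <- truth$gene_id[truth$og_id == og]
    if (length(members) < 2) next
    pr <- utils::combn(members, 2)
    for (p in seq_len(min(3, ncol(pr)))) {
      r <- kaks_pair(cds[[pr[1, p]]], cds[[pr[2, p]]])
      expect_equal(r$Nd, 0)
      expect_equal(r$Ka, 0)
    }
  }
})

test_that("population simulation is seed-stable and respects site limits", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 100L,
                      end = 2000L, n_sites = 2L, n_haps = 5L, skew = 1,
                      stringsAsFactors = FALSE)
  expect_error(simulate_population(genes, n_lines = 20, seed = 1),
               "fewer variant sites")
  genes$n_haps <- 4L
  a <- simulate_population(genes, n_lines = 30, seed = 2)
  b <- simulate_population(genes, n_lines = 30, seed = 2)
  expect_identical(a$vcf_lines, b$vcf_lines)
  expect_identical(a$clusters, b$clusters)
})

test_that("uniform (skew 0) haplotypes land near equal frequency", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 1L,
                      end = 5000L, n_sites = 6L, n_haps = 2L, skew = 0,
                      stringsAsFactors = FALSE)
  pop <- simulate_population(genes, n_lines = 200, n_clusters = 4, seed = 3)
  counts <- table(pop$truth$g$hap_of_line)
  # binomial(200, 0.5) bounds at 0.001 tails
  expect_gte(min(counts), qbinom(0.001, 200, 0.5))
  expect_lte(max(counts), qbinom(0.999, 200, 0.5))
})
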