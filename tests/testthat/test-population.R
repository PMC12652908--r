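vcf_fixture <- function(rows, samples) {
  write_tmp(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), ".vcf")
}

test_that("haplotypes enumerate allele strings in position order", {
  f <- vcf_fixture(c(
    "chr1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/0\t1/1",
    "chr1\t120\t.\tC\tT\t.\t.\t.\tGT\t0/0\t0/0\t1/1"),
    c("L1", "L2", "L3"))
  v <- read_vcf_minimal(f)
  tab <- call_haplotypes(v, "chr1", 100, 200, min_count = 1)
  expect_equal(tab$positions, c(120L, 150L))
  expect_equal(tab$haplotypes$haplotype, c("Hap1", "Hap2"))
  expect_equal(tab$haplotypes$count, c(2L, 1L))
  expect_equal(tab$haplotypes$alleles, c("00", "11"))
})

test_that("lines with missing calls are excluded and counted", {
  f <- vcf_fixture(c(
    "chr1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t160\t.\tC\tT\t.\t.\t.\tGT\t0/0\t0/0\t1/1"),
    c("L1", "L2", "L3"))
  v <- read_vcf_minimal(f)
  tab <- call_haplotypes(v, "chr1", 100, 200, min_count = 1)
  expect_equal(tab$n_excluded, 1L)
  expect_equal(sum(tab$haplotypes$count), 2L)
  expect_false("L2" %in% names(tab$line_haplotype))
})

test_that("identical lines collapse to a single haplotype; rares merge", {
  f <- vcf_fixture(
    "chr1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/0\t0/0\t0/0",
    paste0("L", 1:4))
  v <- read_vcf_minimal(f)
  tab <- call_haplotypes(v, "chr1", 100, 200)
  expect_equal(nrow(tab$haplotypes), 1)
  expect_equal(tab$haplotypes$count, 4L)

  f2 <- vcf_fixture(c(
    "chr1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/0\t1/1\t0/0",
    "chr1\t160\t.\tC\tT\t.\t.\t.\tGT\t0/0\t0/0\t0/0\t1/1"),
    paste0("L", 1:4))
  v2 <- read_vcf_minimal(f2)
  tab2 <- call_haplotypes(v2, "chr1", 100, 200, min_count = 2)
  expect_equal(tab2$haplotypes$haplotype, c("Hap1", "rare"))
  expect_equal(tab2$haplotypes$count, c(2L, 2L))
  expect_equal(unname(tab2$line_haplotype[c("L3", "L4")]),
               c("rare", "rare"))
})

test_that("an empty region warns and returns an empty table", {
  f <- vcf_fixture("chr1\t150\t.\tA\tG\t.\t.\t.\tGT\t0/0", "L1")
  v <- read_vcf_minimal(f)
  expect_warning(tab <- call_haplotypes(v, "chr1", 500, 900),
                 "no variant sites")
  expect_equal(nrow(tab$haplotypes), 0)
})

test_that("cluster proportions are arithmetic and permutation-invariant", {
  line_hap <- setNames(rep(c("Hap1", "Hap2"), c(10, 5)), paste0("L", 1:15))
  tab <- structure(list(
    haplotypes = data.frame(haplotype = c("Hap1", "Hap2"),
                            alleles = c("0", "1"), count = c(10L, 5L)),
    line_haplotype = line_hap, positions = 1L, n_excluded = 0L),
    class = "haplotype_table")
  clusters <- setNames(rep(c("HG4", "HG5"), c(8, 7)), paste0("L", 1:15))
  dist <- cluster_distribution(tab, clusters)
  expect_equal(dist["Hap1", "HG4"], 0.8)
  expect_equal(dist["Hap1", "HG5"], 0.2)
  expect_equal(unname(rowSums(dist)), c(1, 1))
  # renaming clusters permutes columns, never changes values
  ren <- setNames(c(Z = "Z", A = "A")[ifelse(clusters == "HG4", "Z", "A")],
                  names(clusters))
  dist2 <- cluster_distribution(tab, ren)
  expect_equal(unname(dist2[, c("Z", "A")]), unname(dist[, c("HG4", "HG5")]))
  expect_error(cluster_distribution(tab, clusters[-1]), "missing from cluster")
})

test_that("the permutation skew test is valid, seeded and powered", {
  genes <- data.frame(gene_id = c("gSkew", "gNull"), chrom = "chr1",
                      start = c(1000L, 9000L), end = c(4000L, 12000L),
                      n_sites = 8L, n_haps = 7L, skew = c(1, 0),
                      stringsAsFactors = FALSE)
  pop <- simulate_population(genes, n_lines = 150, n_clusters = 7, seed = 19)
  v <- local({
    f <- write_tmp(pop$vcf_lines, ".vcf")
    read_vcf_minimal(f)
  })
  tab_skew <- call_haplotypes(v, "chr1", 1000, 4000)
  tab_null <- call_haplotypes(v, "chr1", 9000, 12000)
  sk <- skew_statistic(tab_skew, pop$clusters, perms = 999, seed = 3)
  nu <- skew_statistic(tab_null, pop$clusters, perms = 999, seed = 3)
  expect_lte(sk$p_value, 0.01)
  expect_gt(nu$p_value, 0.05)
  expect_gte(nu$p_value, 1 / 1000)
  # reproducible under the seed
  sk2 <- skew_statistic(tab_skew, pop$clusters, perms = 999, seed = 3)
  expect_identical(sk, sk2)

  # skew = 1: each haplotype is carried by exactly one cluster
  dist <- cluster_distribution(tab_skew, pop$clusters)
  expect_true(all(apply(dist, 1, max) == 1))
})
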