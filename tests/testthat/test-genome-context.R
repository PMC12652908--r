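genes_df <- function(ids, chrom, rank, start = NULL, end = NULL) {
  data.frame(gene_id = ids, chrom = chrom, rank = rank,
             start = if (is.null(start)) rank * 1000L else start,
             end = if (is.null(end)) rank * 1000L + 500L else end,
             stringsAsFactors = FALSE)
}

test_that("tandem clusters require same orthogroup, chromosome and rank gap", {
  og <- ogset_of(list(c("a1", "a2", "a3"), c("b1", "b2")))
  g <- genes_df(c("a1", "a2", "a3", "b1", "b2"),
                chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                rank = c(10L, 11L, 30L, 12L, 12L))
  td <- find_tandem(g, og, max_intervening = 5L)
  expect_equal(nrow(td), 1)
  expect_equal(td$members, "a1,a2")  # a3 is 19 ranks away; b1/b2 split chroms
  expect_equal(td$n_members, 2)
})

test_that("transitive closure chains near-adjacent copies", {
  og <- ogset_of(list(c("x1", "x2", "x3")))
  g <- genes_df(c("x1", "x2", "x3"), "chr2", rank = c(5L, 7L, 9L))
  td <- find_tandem(g, og, max_intervening = 1L)
  expect_equal(td$n_members, 3)
  td0 <- find_tandem(g, og, max_intervening = 0L)
  expect_equal(nrow(td0), 0)
})

test_that("tandem clustering is invariant under input row order", {
  set.seed(61)
  og <- ogset_of(list(paste0("t", 1:6), paste0("u", 1:3)))
  g <- genes_df(c(paste0("t", 1:6), paste0("u", 1:3)),
                chrom = rep(c("chr1", "chr3"), c(6, 3)),
                rank = c(1L, 3L, 20L, 22L, 24L, 50L, 7L, 8L, 9L))
  ref <- find_tandem(g, og)
  for (i in 1:5) {
    shuf <- g[sample(nrow(g)), , drop = FALSE]
    expect_equal(find_tandem(shuf, og), ref)
  }
  # clusters are disjoint
  members <- unlist(strsplit(ref$members, ","))
  expect_false(anyDuplicated(members) > 0)
})

test_that("candidate windows are inclusive and distances measured to gene edges", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 1000000L, end = 1002000L,
                      stringsAsFactors = FALSE)
  sig <- function(pos, score = 0.4, trait = "PH")
    data.frame(trait = trait, chrom = "chr1", pos = pos, score = score,
               stringsAsFactors = FALSE)
  expect_equal(select_candidates(genes, sig(1050000))$distance, 48000L)
  expect_equal(select_candidates(genes, sig(1001000))$distance, 0L)
  expect_equal(select_candidates(genes, sig(1102000))$distance, 100000L)
  expect_equal(nrow(select_candidates(genes, sig(1102001))), 0)
  expect_equal(select_candidates(genes, sig(900000))$distance, 100000L)
  expect_equal(nrow(select_candidates(genes, sig(1050000, score = 0.01))), 0)
  off <- sig(5)
  off$chrom <- "chrX"
  expect_warning(out <- select_candidates(genes, off), "unknown chromosome")
  expect_equal(nrow(out), 0)
})

test_that("window selection equals a brute-force scan on random instances", {
  set.seed(62)
  genes <- data.frame(
    gene_id = paste0("g", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, TRUE),
    start = sample.int(5000000L, 40), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(5000L, 40)
  signals <- data.frame(
    trait = sample(c("PH", "DTA"), 60, TRUE),
    chrom = sample(c("chr1", "chr2"), 60, TRUE),
    pos = sample.int(5000000L, 60),
    score = round(runif(60, 0, 0.3), 3), stringsAsFactors = FALSE)
  w <- 100000L
  got <- select_candidates(genes, signals, score_min = 0.05, window = w)
  brute <- 0L
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(signals))) {
    if (signals$score[j] < 0.05) next
    if (signals$chrom[j] != genes$chrom[i]) next
    if (signals$pos[j] >= genes$start[i] - w &&
        signals$pos[j] <= genes$end[i] + w) {
      brute <- brute + 1L
      d <- max(0L, genes$start[i] - signals$pos[j],
               signals$pos[j] - genes$end[i])
      row <- got[got$gene_id == genes$gene_id[i] &
                 got$pos == signals$pos[j] &
                 got$trait == signals$trait[j], ]
      expect_true(nrow(row) >= 1)
      expect_equal(row$distance[1], d)
    }
  }
  expect_equal(nrow(got), brute)
})

test_that("trait summaries deduplicate traits and split single from multi", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    trait = c("PH", "PH", "DTA", "EW"),
    chrom = "chr1", pos = 1:4, score = 0.1, distance = 0L,
    stringsAsFactors = FALSE)
  ts <- trait_summary(hits)
  expect_equal(ts$n_traits[ts$gene_id == "g1"], 2)
  expect_equal(ts$class[ts$gene_id == "g1"], "multi")
  expect_equal(ts$class[ts$gene_id == "g2"], "single")
  expect_equal(nrow(trait_summary(hits[0, ])), 0)
})
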