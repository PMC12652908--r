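test_that("pairwise identity handles the canonical cases", {
  p <- random_protein(50)
  expect_equal(pairwise_identity(p, p), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_error(pairwise_identity("AAAA", ""), "empty")
})

test_that("the batched identity matrix equals single-pair alignment", {
  set.seed(11)
  prots <- setNames(vapply(c(40, 45, 60, 40, 52), random_protein, ""),
                    paste0("p", 1:5))
  # make two near-identical pairs
  prots["p4"] <- paste0(substring(prots["p1"], 1, 35), random_protein(5))
  m <- identity_matrix(prots)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(100, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(m[i, j], pairwise_identity(prots[[i]], prots[[j]]),
                 tolerance = 1e-12)
})

test_that("subdivision keeps cliques, chains components, isolates singletons", {
  ids <- c("a", "b", "c")
  mk <- function(ab, bc, ac) {
    m <- matrix(100, 3, 3, dimnames = list(ids, ids))
    m["a", "b"] <- m["b", "a"] <- ab
    m["b", "c"] <- m["c", "b"] <- bc
    m["a", "c"] <- m["c", "a"] <- ac
    m
  }
  clique <- subdivide_og(ids, mk(95, 95, 95), 90)
  expect_equal(clique$groups, list(c("a", "b", "c")))
  chain <- subdivide_og(ids, mk(95, 95, 60), 90)  # single linkage
  expect_equal(chain$groups, list(c("a", "b", "c")))
  none <- subdivide_og(ids, mk(50, 50, 50), 90)
  expect_equal(none$groups, list())
  expect_equal(none$singletons, ids)
})

test_that("de novo clustering obeys the partition property and limits", {
  set.seed(12)
  prots <- setNames(vapply(rep(60, 8), random_protein, ""), paste0("g", 1:8))
  og0 <- cluster_denovo(prots, threshold = 0)
  expect_equal(length(og0$ogs), 1)
  expect_equal(sort(og0$ogs[[1]]), sort(names(prots)))
  one <- cluster_denovo(prots[1], threshold = 90)
  expect_equal(length(one$ogs), 0)
  expect_equal(one$singletons, "g1")
  og <- cluster_denovo(prots, threshold = 90)
  expect_equal(sum(lengths(og$ogs)) + length(og$singletons), length(prots))
})

test_that("de novo clustering recovers two planted families", {
  set.seed(13)
  base_a <- random_protein(120)
  base_b <- random_protein(120)
  mutate <- function(p, k) {
    ch <- strsplit(p, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- sample(panfam:::.AA20, k, TRUE)
    paste(ch, collapse = "")
  }
  prots <- c(
    setNames(vapply(1:5, function(i) mutate(base_a, 4), ""),
             paste0("a", 1:5)),
    setNames(vapply(1:5, function(i) mutate(base_b, 4), ""),
             paste0("b", 1:5)))
  og <- cluster_denovo(prots, threshold = 90)
  expect_equal(length(og$ogs), 2)
  members <- lapply(og$ogs, function(g) sort(substr(g, 1, 1)))
  expect_setequal(vapply(members, function(m) paste(unique(m), collapse = ""),
                         ""), c("a", "b"))
})

test_that("subdivision is idempotent and matches union-find on random instances", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 12
    ids <- paste0("g", seq_len(n))
    m <- matrix(runif(n * n, 40, 100), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    sub <- subdivide_og(ids, m, 90)
    want <- oracle_components(ids, m, 90)
    got <- c(sub$groups, as.list(sub$singletons))
    key <- function(x) paste(vapply(x, paste, "", collapse = ","))
    expect_setequal(key(got), key(want))
    # idempotence: re-subdividing every group changes nothing
    for (g in sub$groups) {
      again <- subdivide_og(g, m, 90)
      expect_equal(again$groups, list(g))
    }
  }
})

test_that("raising the threshold never merges components", {
  set.seed(15)
  n <- 10
  ids <- paste0("g", seq_len(n))
  m <- matrix(runif(n * n, 40, 100), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 100
  for (th in c(50, 70, 90)) {
    lo <- subdivide_og(ids, m, th)
    hi <- subdivide_og(ids, m, th + 8)
    comp_lo <- c(lo$groups, as.list(lo$singletons))
    comp_hi <- c(hi$groups, as.list(hi$singletons))
    # every high-threshold component sits inside one low-threshold component
    for (ch in comp_hi) {
      inside <- vapply(comp_lo, function(cl) all(ch %in% cl), TRUE)
      expect_equal(sum(inside), 1)
    }
  }
})

test_that("refinement applies the >=2-member rule and renumbers by size", {
  set.seed(16)
  base <- random_protein(80)
  prots <- c(x1 = base, x2 = base, y1 = random_protein(80),
             z1 = random_protein(70), z2 = random_protein(90))
  raw <- list(OGa = c("x1", "x2", "y1"), OGb = c("z1", "z2"))
  og <- refine_orthogroups(raw, prots, threshold = 90)
  expect_equal(lengths(og$ogs), c(OG001 = 2L))
  expect_setequal(og$singletons, c("y1", "z1", "z2"))
  tab <- ogset_table(og)
  expect_equal(sum(tab$og_id != "singleton"), 2)
  expect_equal(ogset_from_table(tab)$singletons, og$singletons)
})
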