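# Orthogroup x genome presence/absence matrix, occupancy classification
# (core / softcore / shell / variable) and saturation (rarefaction) curves:
# bootstrap resampling of genome subsets plus the closed-form expectation.

#' Build the orthogroup-by-genome presence/absence matrix
#'
#' @param ogset an `orthogroup_set`.
#' @param gene2genome named character vector mapping gene id to genome id.
#' @param genome_ids optional full roster of genomes (columns); defaults to
#'   the sorted unique values of `gene2genome`.
#' @return object of class `pan_matrix`: binary matrix (orthogroups x
#'   genomes) with an `occupancy` attribute (row sums). Singletons are not
#'   part of the matrix.
#' @export
build_pan_matrix <- function(ogset, gene2genome, genome_ids = NULL) {
  genes <- unlist(ogset$ogs, use.names = FALSE)
  unmapped <- setdiff(genes, names(gene2genome))
  if (length(unmapped))
    stop("gene(s) not mapped to a genome: ", paste(utils::head(unmapped, 3), collapse = ", "))
  if (is.null(genome_ids)) genome_ids <- sort(unique(unname(gene2genome)))
  m <- matrix(0L, nrow = length(ogset$ogs), ncol = length(genome_ids),
              dimnames = list(names(ogset$ogs), genome_ids))
  for (og in names(ogset$ogs)) {
    gs <- unique(gene2genome[ogset$ogs[[og]]])
    bad <- setdiff(gs, genome_ids)
    if (length(bad)) stop("genome not in roster: ", bad[[1L]])
    m[og, gs] <- 1L
  }
  structure(m, class = c("pan_matrix", class(m)))
}

#' Occupancy thresholds for a pan-genome of n genomes
#'
#' At n = 26 these are the conventional absolute cut-offs (softcore from 24,
#' variable up to 5); for other n they generalize as `ceil(0.92 n)` and
#' `floor(0.20 n)`, which reproduce the absolute values exactly at n = 26.
#'
#' @param n number of genomes.
#' @return list with `soft_min` and `var_max`.
#' @export
occupancy_thresholds <- function(n) {
  list(soft_min = as.integer(ceiling(0.92 * n)),
       var_max = as.integer(floor(0.20 * n)))
}

#' Classify orthogroup occupancy
#'
#' core: present in all n genomes; softcore: `soft_min <= k < n`;
#' variable: `k <= var_max`; shell: everything between.
#'
#' @param pm a `pan_matrix` (or any binary matrix with genome columns).
#' @param soft_min,var_max override the defaults from
#'   [occupancy_thresholds()].
#' @return data frame: og_id, occupancy k, category (factor with levels
#'   core, softcore, shell, variable).
#' @export
classify_occupancy <- function(pm, soft_min = NULL, var_max = NULL) {
  n <- ncol(pm)
  k <- rowSums(pm)
  if (any(k > n)) stop("occupancy exceeds genome count")
  if (any(k < 1)) stop("orthogroup with zero occupancy")
  th <- occupancy_thresholds(n)
  if (is.null(soft_min)) soft_min <- th$soft_min
  if (is.null(var_max)) var_max <- th$var_max
  stopifnot(var_max < soft_min)
  cat_ <- ifelse(k == n, "core",
          ifelse(k >= soft_min, "softcore",
          ifelse(k <= var_max, "variable", "shell")))
  data.frame(og_id = rownames(pm), k = as.integer(k),
             category = factor(cat_, levels = c("core", "softcore",
                                                "shell", "variable")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Analytic expected discovery fraction
#'
#' For an orthogroup present in k of n genomes, the probability that a
#' uniform random subset of s genomes contains it is
#' `1 - choose(n-k, s) / choose(n, s)`; the curve averages this over
#' orthogroups.
#'
#' @param k integer vector of orthogroup occupancies.
#' @param n number of genomes.
#' @param s subset size.
#' @return expected fraction of orthogroups discovered.
#' @export
expected_discovery <- function(k, n, s) {
  stopifnot(s >= 1, s <= n, all(k >= 1), all(k <= n))
  miss <- exp(lchoose(n - k, s) - lchoose(n, s))
  miss[s > (n - k)] <- 0
  mean(1 - miss)
}

#' Bootstrap + analytic saturation curve
#'
#' For each subset size s in 1..n, draws `reps` uniform subsets of s
#' distinct genomes (without replacement within a replicate) and records the
#' fraction of orthogroups with at least one presence; the closed-form
#' expectation is computed alongside.
#'
#' @param pm a `pan_matrix`.
#' @param reps bootstrap replicates per subset size (default 1000).
#' @param seed RNG seed (mandatory, recorded in the result).
#' @return data frame of class `saturation_curve`: s, mean, q025, q975,
#'   mc_se (Monte-Carlo standard error of the mean), analytic.
#' @export
saturation_curve <- function(pm, reps = 1000L, seed) {
  if (reps < 1L) stop("reps must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  if (!nrow(pm)) stop("empty pan matrix")
  n <- ncol(pm)
  k <- rowSums(pm)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(s) {
    fr <- vapply(seq_len(reps), function(r) {
      sub <- sample.int(n, s)
      mean(rowSums(pm[, sub, drop = FALSE]) > 0L)
    }, 0)
    data.frame(s = s, mean = mean(fr),
               q025 = unname(stats::quantile(fr, 0.025)),
               q975 = unname(stats::quantile(fr, 0.975)),
               mc_se = stats::sd(fr) / sqrt(reps),
               analytic = expected_discovery(k, n, s))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Smallest genome count reaching a target discovery fraction
#'
#' Uses the analytic expectation, which is non-decreasing in s.
#'
#' @param pm a `pan_matrix`.
#' @param target discovery fraction (default 0.9).
#' @return smallest s with expected discovery >= target (NA if unreached).
#' @export
find_min_s <- function(pm, target = 0.9) {
  n <- ncol(pm)
  k <- rowSums(pm)
  for (s in seq_len(n)) if (expected_discovery(k, n, s) >= target) return(s)
  NA_integer_
}

#' Per-category orthogroup and gene counts
#'
#' @param occ classification from [classify_occupancy()].
#' @param ogset the `orthogroup_set` behind the matrix (for gene counts).
#' @return data frame: category, n_ogs, n_genes.
#' @export
occupancy_counts <- function(occ, ogset) {
  sz <- stats::setNames(lengths(ogset$ogs), names(ogset$ogs))
  agg <- lapply(levels(occ$category), function(cc) {
    ogs <- occ$og_id[occ$category == cc]
    data.frame(category = cc, n_ogs = length(ogs),
               n_genes = sum(sz[ogs]), stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}
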