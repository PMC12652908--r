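# Haplotype enumeration over gene-region variants and frequency
# distribution across breeding (heterotic) clusters, with a permutation
# skew test. Haplotype calls use the collapsed haploid genotypes of
# read_vcf_minimal(); any line with a missing call in the region is
# excluded from counting (and reported).

#' Enumerate haplotypes of a gene region
#'
#' The haplotype string concatenates allele indices over the region's
#' variant sites in position order. Haplotypes seen fewer than `min_count`
#' times are merged into a `"rare"` class. Haplotypes are named Hap1,
#' Hap2, ... by descending count (ties broken lexicographically by allele
#' string); `"rare"` sorts last.
#'
#' @param vcf result of [read_vcf_minimal()].
#' @param chrom,start,end gene region (1-based inclusive).
#' @param min_count minimum count before merging into "rare" (default 2).
#' @return list of class `haplotype_table`: `haplotypes` (data frame:
#'   haplotype, allele string, count), `line_haplotype` (named vector:
#'   counted line -> haplotype name), `positions`, `n_excluded` (lines with
#'   missing calls). Empty table (with a warning) when the region has no
#'   variant sites.
#' @export
call_haplotypes <- function(vcf, chrom, start, end, min_count = 2L) {
  sel <- which(vcf$variants$chrom == chrom &
               vcf$variants$pos >= start & vcf$variants$pos <= end)
  if (!length(sel)) {
    warning("no variant sites in ", chrom, ":", start, "-", end)
    return(structure(list(
      haplotypes = data.frame(haplotype = character(), alleles = character(),
                              count = integer(), stringsAsFactors = FALSE),
      line_haplotype = stats::setNames(character(), character()),
      positions = integer(), n_excluded = 0L), class = "haplotype_table"))
  }
  sel <- sel[order(vcf$variants$pos[sel])]
  gm <- vcf$genotypes[sel, , drop = FALSE]
  complete <- colSums(is.na(gm)) == 0L
  strings <- apply(gm[, complete, drop = FALSE], 2L, paste, collapse = "")
  tab <- sort(table(strings), decreasing = TRUE)
  alleles <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, alleles)
  alleles <- alleles[ord]; counts <- counts[ord]
  rare <- counts < min_count
  hap_name <- character(length(alleles))
  hap_name[!rare] <- paste0("Hap", seq_len(sum(!rare)))
  hap_name[rare] <- "rare"
  line_hap <- stats::setNames(hap_name[match(strings, alleles)],
                              names(strings))
  haps <- data.frame(haplotype = hap_name, alleles = alleles,
                     count = counts, stringsAsFactors = FALSE)
  if (any(rare)) {
    haps <- rbind(haps[!rare, , drop = FALSE],
                  data.frame(haplotype = "rare", alleles = "*",
                             count = sum(counts[rare]),
                             stringsAsFactors = FALSE))
  }
  rownames(haps) <- NULL
  structure(list(haplotypes = haps, line_haplotype = line_hap,
                 positions = vcf$variants$pos[sel],
                 n_excluded = sum(!complete)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype table:", nrow(x$haplotypes), "haplotypes over",
      length(x$positions), "sites;", length(x$line_haplotype),
      "lines counted,", x$n_excluded, "excluded\n")
  invisible(x)
}

.check_clusters <- function(lines, clusters) {
  miss <- setdiff(lines, names(clusters))
  if (length(miss)) stop("line missing from cluster assignment: ", miss[[1L]])
  clusters[lines]
}

#' Per-haplotype cluster proportions
#'
#' @param tab a `haplotype_table`.
#' @param clusters named character vector: line id -> cluster label.
#' @return matrix haplotypes x clusters; each row sums to 1.
#' @export
cluster_distribution <- function(tab, clusters) {
  if (!length(tab$line_haplotype)) return(matrix(0, 0, 0))
  cl <- .check_clusters(names(tab$line_haplotype), clusters)
  levels_cl <- sort(unique(unname(clusters)))
  m <- table(factor(tab$line_haplotype, levels = tab$haplotypes$haplotype),
             factor(cl, levels = levels_cl))
  m <- unclass(m)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m / rowSums(m)
}

#' Cluster-skew statistic with a permutation test
#'
#' For each haplotype the chi-square statistic of its cluster counts
#' against the cluster marginal totals is computed; the gene's score is the
#' maximum over haplotypes, normalised by the number of counted lines.
#' Significance comes from shuffling cluster labels across lines. The
#' statistic is a package convention for quantifying a qualitative pattern.
#'
#' @param tab a `haplotype_table`.
#' @param clusters named character vector: line id -> cluster label.
#' @param perms number of permutations (default 999).
#' @param seed RNG seed (mandatory).
#' @return list: `score`, `p_value` (= (1 + #perm >= observed)/(perms+1)),
#'   `perms`, `seed`.
#' @export
skew_statistic <- function(tab, clusters, perms = 999L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  lines <- names(tab$line_haplotype)
  if (length(lines) < 2L) stop("need >= 2 counted lines")
  cl <- .check_clusters(lines, clusters)
  if (length(unique(cl)) < 2L)
    stop("need counted lines in >= 2 clusters")
  hap <- tab$line_haplotype
  cl_levels <- sort(unique(unname(cl)))
  n <- length(lines)
  marg <- table(factor(cl, levels = cl_levels)) / n
  stat <- function(cluster_of_line) {
    cm <- unclass(table(factor(hap, levels = unique(hap)),
                        factor(cluster_of_line, levels = cl_levels)))
    mx <- 0
    for (i in seq_len(nrow(cm))) {
      obs <- cm[i, ]
      expd <- sum(obs) * marg
      ch <- sum((obs - expd)^2 / ifelse(expd > 0, expd, 1))
      if (ch > mx) mx <- ch
    }
    mx / n
  }
  obs <- stat(cl)
  set.seed(seed)
  ge <- 0L
  for (p in seq_len(perms)) {
    if (stat(sample(cl)) >= obs - 1e-12) ge <- ge + 1L
  }
  list(score = obs, p_value = (1L + ge) / (perms + 1L),
       perms = perms, seed = seed)
}
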