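# Genome context of family genes: tandem-duplication clusters from
# annotation ranks, and candidate-gene selection around association signals.

#' Tandem-duplication clusters within one genome
#'
#' Two genes are tandem-linked when they share an orthogroup and a
#' chromosome and at most `max_intervening` annotated genes (of any family)
#' lie between them in full-annotation rank order; clusters are the
#' transitive closure of this relation.
#'
#' @param genes data frame of the genome's family genes (gene_id, chrom,
#'   rank; e.g. `scan_family()$genes`).
#' @param ogset an `orthogroup_set`; singleton genes cannot form clusters.
#' @param max_intervening maximum intervening gene count (default 5).
#' @return data frame: genome cluster id, og_id, chrom, n_members and the
#'   comma-joined member ids in rank order.
#' @export
find_tandem <- function(genes, ogset, max_intervening = 5L) {
  stopifnot(all(c("gene_id", "chrom", "rank") %in% names(genes)))
  if (anyNA(genes$rank)) stop("missing rank for ",
                              genes$gene_id[is.na(genes$rank)][1L])
  og_of <- stats::setNames(rep(names(ogset$ogs), lengths(ogset$ogs)),
                           unlist(ogset$ogs, use.names = FALSE))
  genes <- genes[genes$gene_id %in% names(og_of), , drop = FALSE]
  if (!nrow(genes))
    return(data.frame(cluster_id = character(), og_id = character(),
                      chrom = character(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE))
  genes$og_id <- unname(og_of[genes$gene_id])
  rows <- list()
  for (key in split(seq_len(nrow(genes)),
                    paste(genes$og_id, genes$chrom, sep = "\r"))) {
    d <- genes[key, , drop = FALSE]
    d <- d[order(d$rank), , drop = FALSE]
    if (nrow(d) < 2L) next
    gap_new <- c(TRUE, diff(d$rank) - 1L > max_intervening)
    grp <- cumsum(gap_new)
    for (g in split(seq_len(nrow(d)), grp)) {
      if (length(g) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = d$og_id[[1L]], chrom = d$chrom[[1L]],
        n_members = length(g),
        members = paste(d$gene_id[g], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(og_id = character(), chrom = character(),
               n_members = integer(), members = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$og_id, out$chrom, out$members), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out <- cbind(cluster_id = sprintf("TD%03d", seq_len(nrow(out))), out)
  out
}

#' Candidate genes within a window of association signals
#'
#' Keeps signals with score >= `score_min`, then reports every
#' gene/signal pair where the signal position falls inside
#' `[start - window, end + window]` (inclusive at both edges). Distance is
#' 0 for signals inside the gene, else base pairs to the nearest gene edge.
#'
#' @param genes data frame with gene_id, chrom, start, end.
#' @param signals data frame with trait, chrom, pos, score.
#' @param score_min signal score threshold (default 0.05, a resample model
#'   inclusion probability).
#' @param window half-window in bp (default 100000).
#' @return data frame: gene_id, trait, chrom, pos, score, distance.
#' @export
select_candidates <- function(genes, signals, score_min = 0.05,
                              window = 100000L) {
  stopifnot(all(c("trait", "chrom", "pos", "score") %in% names(signals)))
  if (any(signals$pos < 1)) stop("signal position must be >= 1")
  sig <- signals[signals$score >= score_min, , drop = FALSE]
  unknown <- setdiff(unique(sig$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("skipping signals on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    sig <- sig[!sig$chrom %in% unknown, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    g <- genes[genes$chrom == sig$chrom[i] &
               genes$start - window <= sig$pos[i] &
               genes$end + window >= sig$pos[i], , drop = FALSE]
    if (!nrow(g)) next
    dist <- pmax(0L, pmax(g$start - sig$pos[i], sig$pos[i] - g$end))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, trait = sig$trait[i], chrom = sig$chrom[i],
      pos = sig$pos[i], score = sig$score[i], distance = as.integer(dist),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), trait = character(),
               chrom = character(), pos = integer(), score = numeric(),
               distance = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$trait, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct-trait counts per candidate gene
#'
#' @param hits candidate table from [select_candidates()].
#' @return data frame: gene_id, n_traits, traits (comma-joined distinct
#'   traits), class ("single" or "multi"). Genes with no hits are absent.
#' @export
trait_summary <- function(hits) {
  if (!nrow(hits))
    return(data.frame(gene_id = character(), n_traits = integer(),
                      traits = character(), class = character(),
                      stringsAsFactors = FALSE))
  agg <- lapply(split(hits$trait, hits$gene_id), function(tr) {
    tr <- sort(unique(tr))
    data.frame(n_traits = length(tr), traits = paste(tr, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(gene_id = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, agg))
  out$class <- ifelse(out$n_traits > 1L, "multi", "single")
  rownames(out) <- NULL
  out
}
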