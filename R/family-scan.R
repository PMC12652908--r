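# From raw domain hits + annotation + genome sequence to validated family
# gene records: E-value filtering, representative-CDS extraction, promoter
# extraction, physicochemical properties, and co-domain flagging.

#' Filter domain hits by E-value
#'
#' Keeps hits with per-domain independent E-value <= `e_max` (inclusive).
#' A gene may retain several hits (e.g. two consecutive family domains).
#'
#' @param hits data frame as returned by [read_domtblout()].
#' @param e_max inclusive E-value ceiling (default 1e-5).
#' @return the filtered data frame.
#' @export
filter_hits <- function(hits, e_max = 1e-5) {
  stopifnot(is.data.frame(hits), "e_value" %in% names(hits))
  hits[hits$e_value <= e_max, , drop = FALSE]
}

.longest_cds_tx <- function(ann, gene_id) {
  txs <- ann$transcripts$tx_id[ann$transcripts$gene_id == gene_id]
  if (!length(txs)) stop("gene ", gene_id, " has no mRNA")
  len <- vapply(txs, function(tx) {
    seg <- ann$cds[ann$cds$tx_id == tx, , drop = FALSE]
    sum(seg$end - seg$start + 1L)
  }, 0L)
  if (all(len == 0L)) stop("gene ", gene_id, " has no CDS")
  # deterministic tie-break: longest CDS, then lexicographic tx id
  txs[order(-len, txs)][1L]
}

#' Extract protein, CDS and 2 kb upstream sequence of a gene
#'
#' The representative transcript is the one with the longest total CDS.
#' The CDS is spliced in transcript orientation (reverse-complemented on the
#' minus strand). The upstream region is the 2,000 bp 5' of the CDS start in
#' transcript orientation, truncated (and flagged) at the contig edge.
#' A terminal stop codon is trimmed before translation.
#'
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param ann annotation from [read_gff3()].
#' @param gene_id gene to extract.
#' @param upstream_len upstream window length in bp (default 2000).
#' @return list with `protein`, `cds` (stop-trimmed), `upstream`,
#'   `upstream_truncated` (logical) and `internal_stop` (logical; when TRUE
#'   the protein is NA and the gene should be excluded).
#' @export
extract_sequences <- function(genome, ann, gene_id, upstream_len = 2000L) {
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("gene not in annotation: ", gene_id)
  if (!g$chrom %in% names(genome)) stop("contig missing from FASTA: ", g$chrom)
  contig <- genome[[g$chrom]]
  clen <- nchar(contig)
  tx <- .longest_cds_tx(ann, gene_id)
  seg <- ann$cds[ann$cds$tx_id == tx, , drop = FALSE]
  if (any(seg$end > clen)) stop("CDS beyond contig end for ", gene_id)

  pieces <- substring(contig, pmin(seg$start, seg$end), pmax(seg$start, seg$end))
  if (g$strand == "+") {
    cds <- paste(pieces[order(seg$start)], collapse = "")
    up_hi <- min(seg$start) - 1L
    up_lo <- max(1L, up_hi - upstream_len + 1L)
    upstream <- if (up_hi >= up_lo) substring(contig, up_lo, up_hi) else ""
    truncated <- (up_hi - up_lo + 1L) < upstream_len
  } else {
    cds <- revcomp(paste(pieces[order(seg$start)], collapse = ""))
    up_lo <- max(seg$end) + 1L
    up_hi <- min(clen, up_lo + upstream_len - 1L)
    upstream <- if (up_hi >= up_lo) revcomp(substring(contig, up_lo, up_hi)) else ""
    truncated <- (up_hi - up_lo + 1L) < upstream_len
  }

  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not a multiple of 3 for ", gene_id)
  aa <- translate_cds(cds)
  # trim one terminal stop
  if (nchar(aa) > 0L && substring(aa, nchar(aa)) == "*") {
    aa <- substring(aa, 1L, nchar(aa) - 1L)
    cds <- substring(cds, 1L, nchar(cds) - 3L)
  }
  internal_stop <- grepl("*", aa, fixed = TRUE)
  list(protein = if (internal_stop) NA_character_ else aa,
       cds = cds, upstream = upstream,
       upstream_truncated = truncated, internal_stop = internal_stop)
}

.charge_at_ph <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - .PKA$nterm)) +
    sum(counts[names(.PKA$positive)] / (1 + 10^(ph - .PKA$positive)))
  neg <- 1 / (1 + 10^(.PKA$cterm - ph)) +
    sum(counts[names(.PKA$negative)] / (1 + 10^(.PKA$negative - ph)))
  pos - neg
}

#' Physicochemical properties of a protein
#'
#' Molecular weight from average residue masses plus one water (reported in
#' kDa); isoelectric point by bisection on the Henderson-Hasselbalch net
#' charge (EMBOSS pKa set) to |charge| < 1e-4; instability index of
#' Guruprasad et al. (1990); GRAVY as mean Kyte-Doolittle hydropathy.
#'
#' @param protein a single amino-acid string over the standard 20 residues.
#' @return data frame row: mw_kda, pi, instability, gravy, hydrophilic
#'   (`gravy < 0`).
#' @export
physchem <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("empty protein")
  aa <- strsplit(protein, "")[[1L]]
  bad <- setdiff(unique(aa), .AA20)
  if (length(bad))
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  L <- length(aa)
  counts <- table(factor(aa, levels = .AA20))
  mw <- sum(.AA_MASS[aa]) + .WATER_MASS

  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- .charge_at_ph(counts, mid)
    if (abs(ch) < 1e-4 || (hi - lo) < 1e-12) break
    if (ch > 0) lo <- mid else hi <- mid
  }

  instability <- if (L < 2L) 0 else
    (10 / L) * sum(.DIWV[cbind(aa[-L], aa[-1L])])
  gravy <- mean(.AA_KD[aa])

  data.frame(mw_kda = mw / 1000, pi = mid, instability = instability,
             gravy = gravy, hydrophilic = gravy < 0)
}

#' Flag genes carrying a co-occurring lectin (JRL) domain
#'
#' @param gene_ids character vector of gene ids to flag.
#' @param jrl_hits data frame of JRL domain hits ([read_domtblout()]).
#' @param e_max inclusive E-value ceiling, same filter as the family domain.
#' @return named logical vector: TRUE iff >= 1 JRL hit passes the filter.
#' @export
flag_jrl <- function(gene_ids, jrl_hits, e_max = 1e-5) {
  passing <- unique(filter_hits(jrl_hits, e_max)$gene_id)
  stats::setNames(gene_ids %in% passing, gene_ids)
}

#' Scan one genome for family genes
#'
#' Applies the domain E-value filter, extracts sequences for each passing
#' gene, computes physicochemical properties, flags JRL co-domains and
#' scaffold placement. Genes whose CDS contains an internal stop are
#' excluded with a warning.
#'
#' @param genome named character vector of contig sequences.
#' @param ann annotation from [read_gff3()].
#' @param hits family-domain hits ([read_domtblout()]).
#' @param genome_id label recorded for every gene.
#' @param jrl_hits optional JRL-domain hits.
#' @param e_max inclusive E-value ceiling (default 1e-5).
#' @param chrom_regex chromosome-name pattern; non-matching contigs are
#'   flagged `on_scaffold` (matching is case-insensitive).
#' @return list of class `panfam_family`: `genes` (one row per family gene:
#'   coordinates, rank, n_domains, has_jrl, on_scaffold, upstream_truncated
#'   and physicochemical columns) plus named vectors `proteins`, `cds`,
#'   `upstream`.
#' @export
scan_family <- function(genome, ann, hits, genome_id,
                        jrl_hits = NULL, e_max = 1e-5,
                        chrom_regex = "^chr([0-9]+)$") {
  kept <- filter_hits(hits, e_max)
  ids <- sort(intersect(unique(kept$gene_id), ann$genes$gene_id))
  jrl <- if (is.null(jrl_hits)) {
    stats::setNames(rep(FALSE, length(ids)), ids)
  } else flag_jrl(ids, jrl_hits, e_max)

  rows <- list(); prot <- character(); cds <- character(); up <- character()
  for (gid in ids) {
    sq <- extract_sequences(genome, ann, gid)
    if (sq$internal_stop) {
      warning("excluding ", gid, ": internal stop codon in CDS")
      next
    }
    g <- ann$genes[ann$genes$gene_id == gid, , drop = FALSE]
    pc <- physchem(sq$protein)
    rows[[gid]] <- data.frame(
      gene_id = gid, genome_id = genome_id, chrom = g$chrom,
      start = g$start, end = g$end, strand = g$strand, rank = g$rank,
      n_domains = sum(kept$gene_id == gid),
      has_jrl = unname(jrl[gid]),
      on_scaffold = !grepl(chrom_regex, tolower(g$chrom)),
      upstream_truncated = sq$upstream_truncated,
      pc, stringsAsFactors = FALSE)
    prot[gid] <- sq$protein
    cds[gid] <- sq$cds
    up[gid] <- sq$upstream
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), genome_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), rank = integer(), n_domains = integer(),
               has_jrl = logical(), on_scaffold = logical(),
               upstream_truncated = logical(), mw_kda = numeric(),
               pi = numeric(), instability = numeric(), gravy = numeric(),
               hydrophilic = logical(), stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes, proteins = prot, cds = cds, upstream = up),
            class = "panfam_family")
}

#' @export
print.panfam_family <- function(x, ...) {
  cat("panfam family scan:", nrow(x$genes), "genes")
  if (nrow(x$genes))
    cat(" (", sum(x$genes$has_jrl), " with JRL co-domain, ",
        sum(x$genes$on_scaffold), " on scaffolds)", sep = "")
  cat("\n")
  invisible(x)
}

#' Headline arithmetic summaries of a pan-family census
#'
#' Given the census counts of a pan-genome family survey, returns the
#' derived headline figures: mean genes per line (rounded, as conventionally
#' reported), percentage of genes carrying the co-domain, mean orthogroup
#' size over grouped (non-singleton) genes, and the number of genes on
#' unplaced scaffolds.
#'
#' @param n_genes total family genes across all genomes.
#' @param n_genomes number of genomes surveyed.
#' @param n_jrl number of genes with the co-domain.
#' @param n_on_chrom number of genes placed on chromosomes.
#' @param n_ogs number of orthogroups.
#' @param n_singletons number of singleton genes.
#' @return list: mean_genes_per_line, jrl_pct, mean_og_size, scaffold_genes.
#' @export
family_census_summary <- function(n_genes, n_genomes, n_jrl, n_on_chrom,
                                  n_ogs, n_singletons) {
  stopifnot(n_genes >= n_on_chrom, n_genes >= n_jrl, n_ogs > 0)
  list(mean_genes_per_line = round(n_genes / n_genomes),
       jrl_pct = round(100 * n_jrl / n_genes, 2),
       mean_og_size = round((n_genes - n_singletons) / n_ogs),
       scaffold_genes = n_genes - n_on_chrom)
}
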