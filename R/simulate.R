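# Synthetic pan-genome study generator with planted ground truth.
#
# Emits, per simulated genome, a FASTA assembly, a GFF3 annotation
# (family genes with promoters and occasional introns, plus background
# genes), and domtblout-dialect domain-hit files; separately, a minimal
# population VCF with a line-to-cluster table, a GWAS-signal table, and a
# count matrix with planted tissue/stress effects. Every draw flows from
# the mandatory config seed, so outputs are byte-identical across reruns.
#
# Codon model: an ancestral codon sequence per orthogroup is mutated
# independently down each genome; every attempted substitution is kept if
# synonymous, kept with probability min(1, omega) if nonsynonymous, and
# redrawn if it would create a stop codon. With no transition bias this is
# the process whose divergence the NG86 estimator models, so planted omega
# (<= 1) is recoverable.

#' Default orthogroup specification
#'
#' Emulates the scale of a 26-genome maize family survey: ~47 family genes
#' per genome split over core (p = 1, incl. small tandem arrays), softcore,
#' shell and variable orthogroups on 10 chromosomes, with one variable
#' orthogroup on an unplaced scaffold.
#'
#' @param n_genomes number of genomes the probabilities are aimed at.
#' @return data frame: og_id, p (presence probability per genome), size
#'   (copies per present genome), omega, codon_length, chrom, jrl.
#' @export
default_og_spec <- function(n_genomes = 26L) {
  # mix calibrated to the surveyed family: ~70 orthogroups, ~47 genes per
  # genome, core genes just above 40% of the total, ~3% variable genes
  n_core <- 18L; n_soft <- 10L; n_shell <- 30L; n_var <- 12L
  n <- n_core + n_soft + n_shell + n_var
  og_id <- sprintf("sim%02d", seq_len(n))
  p <- c(rep(1, n_core), rep(0.945, n_soft), rep(0.55, n_shell),
         rep(0.12, n_var))
  size <- rep(1L, n)
  size[3L] <- 2L  # core tandem arrays
  size[7L] <- 3L
  omega <- rep(c(0.1, 0.2, 0.3, 0.5), length.out = n)
  omega[c(17L, 28L)] <- 1.0  # relaxed/positive-selection-like orthogroups
  codon_length <- 100L + (seq_len(n) %% 9L) * 25L
  chrom <- paste0("chr", (seq_len(n) - 1L) %% 10L + 1L)
  chrom[n] <- "scaffold_7"
  jrl <- rep(FALSE, n)
  jrl[seq(2L, n, by = 6L)] <- TRUE  # ~17% of genes carry the co-domain
  data.frame(og_id = og_id, p = p, size = size, omega = omega,
             codon_length = codon_length, chrom = chrom, jrl = jrl,
             stringsAsFactors = FALSE)
}

#' Default motif planting specification
#'
#' `rate` is the probability that a promoter receives at least one planted
#' copy of the motif (one guaranteed copy is placed when the Bernoulli
#' draw succeeds; position uniform).
#'
#' @return data frame: name, iupac, category, rate.
#' @export
default_motif_spec <- function() {
  data.frame(
    name = c("ABRE", "MBS", "CGTCA-motif", "TGACG-motif", "G-box", "CAT-box"),
    iupac = c("ACGTG", "CAACTG", "CGTCA", "TGACG", "CACGTG", "GCCACT"),
    category = c("stress", "stress", "hormone", "hormone", "light",
                 "development"),
    rate = c(0.8, 0.5, 0.7, 0.4, 0.3, 0.25),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' @param n_genomes number of genomes (default 26).
#' @param og_spec orthogroup table (see [default_og_spec()]).
#' @param motif_spec motif planting table (see [default_motif_spec()]).
#' @param og_motif_rates optional named list (og_id -> named numeric of
#'   per-motif rates) overriding `motif_spec$rate` for specific
#'   orthogroups.
#' @param subs_per_codon expected attempted substitutions per codon on the
#'   ancestor-to-genome branch (default 0.15).
#' @param n_background background (non-family) genes per chromosome per
#'   genome (default 3).
#' @param intron_frac fraction of family genes receiving one intron.
#' @param seed RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 26L, og_spec = default_og_spec(n_genomes),
                       motif_spec = default_motif_spec(),
                       og_motif_rates = NULL,
                       subs_per_codon = 0.15, n_background = 3L,
                       intron_frac = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genomes >= 1L,
            all(og_spec$p >= 0 & og_spec$p <= 1),
            all(og_spec$omega >= 0),
            all(og_spec$codon_length >= 10L),
            all(og_spec$size >= 1L),
            all(motif_spec$rate >= 0 & motif_spec$rate <= 1))
  if (anyDuplicated(og_spec$og_id)) stop("duplicate og_id in og_spec")
  structure(list(n_genomes = as.integer(n_genomes), og_spec = og_spec,
                 motif_spec = motif_spec, og_motif_rates = og_motif_rates,
                 subs_per_codon = subs_per_codon,
                 n_background = as.integer(n_background),
                 intron_frac = intron_frac, seed = as.integer(seed)),
            class = "sim_config")
}

.rand_seq <- function(n) paste(sample(.NUC, n, replace = TRUE), collapse = "")

.rand_cds_body <- function(n_codons) {
  paste(c("ATG", sample(setdiff(.SENSE_CODONS, "ATG"), n_codons - 1L,
                        replace = TRUE)), collapse = "")
}

.evolve_cds <- function(cds, omega, attempts) {
  L <- nchar(cds)
  codons <- substring(cds, seq(1L, L, 3L), seq(3L, L, 3L))
  for (t in seq_len(attempts)) {
    pos <- sample.int(L, 1L)
    ci <- (pos - 1L) %/% 3L + 1L
    off <- (pos - 1L) %% 3L + 1L
    old <- codons[ci]
    base <- substring(old, off, off)
    alt <- sample(setdiff(.NUC, base), 1L)
    new <- old
    substring(new, off, off) <- alt
    if (.GENETIC_CODE[[new]] == "*") next  # redraw; stops never fix
    if (.GENETIC_CODE[[new]] == .GENETIC_CODE[[old]] ||
        stats::runif(1) < min(1, omega))
      codons[ci] <- new
  }
  paste(codons, collapse = "")
}

.resolve_iupac <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1L]],
               function(ch) sample(.IUPAC[[ch]], 1L), ""), collapse = "")
}

.plant_motifs <- function(promoter, spec, rates) {
  counts <- stats::setNames(integer(nrow(spec)), spec$name)
  for (j in seq_len(nrow(spec))) {
    if (stats::runif(1) >= rates[[j]]) next
    inst <- .resolve_iupac(spec$iupac[j])
    at <- sample.int(nchar(promoter) - nchar(inst) + 1L, 1L)
    substring(promoter, at, at + nchar(inst) - 1L) <- inst
    counts[j] <- 1L
  }
  list(promoter = promoter, counts = counts)
}

.domtbl_line <- function(gene, domain, evalue, qlen, ali_from, ali_to) {
  sprintf(paste0("%-20s -          %5d %-12s PF00000.0  %5d  %9.2g  120.5   0.1",
                 "   1   1  %9.2g  %9.2g  118.2   0.1     1 %5d %5d %5d %5d %5d 0.95 -"),
          gene, qlen + 50L, domain, qlen, evalue, evalue / 10, evalue,
          qlen, ali_from, ali_to, ali_from, ali_to)
}

#' Simulate a pan-genome study with planted truth
#'
#' Writes per-genome FASTA, GFF3 and domtblout files under
#' `out_dir/genomes/`, truth tables under `out_dir/truth/` and a JSON
#' manifest echoing the seed and configuration scale.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `paths` (per-genome file table) and
#'   `truth`: `genes` (gene_id, genome_id, og_id, chrom, start, end,
#'   strand, has_jrl, on_scaffold), `presence` (orthogroup x genome 0/1
#'   matrix), `omega` (named per orthogroup), `ancestral_cds`, and
#'   `motif_counts` (planted per gene x motif).
#' @export
simulate_pan_genome <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(config$seed)
  spec <- config$og_spec
  genome_ids <- sprintf("G%02d", seq_len(config$n_genomes))

  # ancestral CDS per orthogroup (body only; terminal stop appended on
  # placement so it is never mutated)
  anc <- stats::setNames(
    vapply(spec$codon_length, .rand_cds_body, ""), spec$og_id)

  presence <- matrix(0L, nrow = nrow(spec), ncol = config$n_genomes,
                     dimnames = list(spec$og_id, genome_ids))
  gene_rows <- list(); motif_rows <- list(); paths <- list()

  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    here <- stats::runif(nrow(spec)) < spec$p
    presence[, gi] <- as.integer(here)
    chroms <- unique(spec$chrom)
    fa <- character(); gff <- character(); dirig <- character(); jrl <- character()
    counter <- 0L
    for (chrom in chroms) {
      seq_parts <- character(); pos <- 0L
      slots <- which(here & spec$chrom == chrom)
      # background genes interleaved among family cassettes
      n_bg <- config$n_background
      order_slots <- c(rep(list(NULL), n_bg), as.list(slots))
      order_slots <- order_slots[sample.int(length(order_slots))]
      for (slot in order_slots) {
        if (is.null(slot)) {  # background gene
          counter <- counter + 1L
          gene_id <- sprintf("%s_g%04d", gid, counter)
          spacer <- .rand_seq(sample(200:600, 1L))
          body <- .rand_cds_body(sample(60:120, 1L))
          cdsseq <- paste0(body, "TAA")
          strand <- sample(c("+", "-"), 1L)
          cass <- cdsseq
          if (strand == "-") cass <- revcomp(cass)
          g_start <- pos + nchar(spacer) + 1L
          g_end <- g_start + nchar(cass) - 1L
          seq_parts <- c(seq_parts, spacer, cass)
          pos <- g_end
          gff <- c(gff, .gff_gene_lines(gene_id, chrom, g_start, g_end,
                                        strand, list(c(g_start, g_end))))
          # decoys: some background genes carry an above-threshold hit
          if (stats::runif(1) < 0.3)
            dirig <- c(dirig, .domtbl_line(gene_id, "Dirigent",
                                           10^stats::runif(1, -4.5, -2),
                                           100L, 5L, 95L))
          next
        }
        for (copy in seq_len(spec$size[slot])) {
          counter <- counter + 1L
          gene_id <- sprintf("%s_g%04d", gid, counter)
          og <- spec$og_id[slot]
          attempts <- stats::rpois(1L, config$subs_per_codon *
                                     spec$codon_length[slot])
          body <- .evolve_cds(anc[[og]], spec$omega[slot], attempts)
          cdsseq <- paste0(body, "TAA")
          rates <- stats::setNames(config$motif_spec$rate,
                                   config$motif_spec$name)
          if (!is.null(config$og_motif_rates[[og]])) {
            ov <- config$og_motif_rates[[og]]
            rates[names(ov)] <- ov
          }
          pm <- .plant_motifs(.rand_seq(2000L), config$motif_spec, rates)
          intron <- if (stats::runif(1) < config$intron_frac)
            .rand_seq(sample(60:150, 1L)) else NULL
          strand <- sample(c("+", "-"), 1L)
          spacer <- .rand_seq(sample(300:800, 1L))

          if (is.null(intron)) {
            tx_seq <- paste0(pm$promoter, cdsseq)
            cds_off <- list(c(2001L, 2000L + nchar(cdsseq)))
          } else {
            k <- 3L * sample.int(nchar(cdsseq) %/% 3L - 1L, 1L)
            tx_seq <- paste0(pm$promoter, substring(cdsseq, 1L, k), intron,
                             substring(cdsseq, k + 1L, nchar(cdsseq)))
            cds_off <- list(c(2001L, 2000L + k),
                            c(2001L + k + nchar(intron),
                              2000L + nchar(intron) + nchar(cdsseq)))
          }
          cass_start <- pos + nchar(spacer) + 1L
          if (strand == "+") {
            cass <- tx_seq
            segs <- lapply(cds_off, function(o) cass_start + o - 1L)
          } else {
            cass <- revcomp(tx_seq)
            L <- nchar(tx_seq)
            segs <- lapply(cds_off, function(o)
              sort(cass_start + (L - o) ))
          }
          g_start <- min(vapply(segs, min, 0))
          g_end <- max(vapply(segs, max, 0))
          seq_parts <- c(seq_parts, spacer, cass)
          pos <- cass_start + nchar(cass) - 1L
          gff <- c(gff, .gff_gene_lines(gene_id, chrom, g_start, g_end,
                                        strand, segs))
          qlen <- spec$codon_length[slot]
          n_dom <- if (stats::runif(1) < 0.15) 2L else 1L
          for (dmi in seq_len(n_dom))
            dirig <- c(dirig, .domtbl_line(gene_id, "Dirigent",
                                           10^stats::runif(1, -30, -8),
                                           qlen, 10L + 30L * (dmi - 1L),
                                           60L + 30L * (dmi - 1L)))
          if (spec$jrl[slot]) {
            jrl <- c(jrl, .domtbl_line(gene_id, "Jacalin",
                                       10^stats::runif(1, -20, -8),
                                       qlen, 5L, 55L))
          } else if (stats::runif(1) < 0.05) {
            # weak, above-threshold lectin similarity: must not flag
            jrl <- c(jrl, .domtbl_line(gene_id, "Jacalin",
                                       10^stats::runif(1, -4, -2),
                                       qlen, 5L, 55L))
          }
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = gene_id, genome_id = gid, og_id = og, chrom = chrom,
            start = g_start, end = g_end, strand = strand,
            has_jrl = spec$jrl[slot],
            on_scaffold = !grepl("^chr[0-9]+$", chrom),
            stringsAsFactors = FALSE)
          motif_rows[[length(motif_rows) + 1L]] <-
            c(list(gene_id = gene_id), as.list(pm$counts))
        }
      }
      seq_parts <- c(seq_parts, .rand_seq(300L))
      fa[chrom] <- paste(seq_parts, collapse = "")
    }
    fasta_path <- file.path(out_dir, "genomes", paste0(gid, ".fa"))
    gff_path <- file.path(out_dir, "genomes", paste0(gid, ".gff3"))
    dir_path <- file.path(out_dir, "genomes", paste0(gid, ".dirigent.domtbl"))
    jrl_path <- file.path(out_dir, "genomes", paste0(gid, ".jrl.domtbl"))
    write_fasta(fa, fasta_path)
    writeLines(c("##gff-version 3", gff), gff_path)
    writeLines(c("# domtblout (simulated)", dirig), dir_path)
    writeLines(c("# domtblout (simulated)", jrl), jrl_path)
    paths[[gid]] <- data.frame(genome_id = gid, fasta = fasta_path,
                               gff = gff_path, hits = dir_path,
                               jrl_hits = jrl_path, stringsAsFactors = FALSE)
  }

  genes <- do.call(rbind, gene_rows)
  motif_counts <- do.call(rbind, lapply(motif_rows, as.data.frame))
  truth <- list(genes = genes, presence = presence,
                omega = stats::setNames(spec$omega, spec$og_id),
                ancestral_cds = anc, motif_counts = motif_counts)
  write_panfam_tsv(genes, file.path(out_dir, "truth", "membership.tsv"),
                   header = paste("seed =", config$seed))
  write_panfam_tsv(cbind(og_id = rownames(presence),
                         as.data.frame(presence)),
                   file.path(out_dir, "truth", "presence.tsv"),
                   header = paste("seed =", config$seed))
  jsonlite::write_json(
    list(seed = config$seed, n_genomes = config$n_genomes,
         n_ogs = nrow(spec), subs_per_codon = config$subs_per_codon),
    file.path(out_dir, "truth", "manifest.json"), auto_unbox = TRUE)
  invisible(list(paths = do.call(rbind, paths), truth = truth))
}

.gff_gene_lines <- function(gene_id, chrom, start, end, strand, cds_segs) {
  tx <- paste0(gene_id, ".t1")
  segs <- do.call(rbind, cds_segs)
  lines <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, start, end,
            strand, gene_id),
    sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", chrom,
            start, end, strand, tx, gene_id),
    sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", chrom,
            segs[, 1L], segs[, 2L], strand, tx))
  lines
}

#' Simulate a structured population with cluster-skewed haplotypes
#'
#' Each line belongs to one cluster; for every gene the line draws a
#' haplotype from its cluster's distribution, which mixes a cluster-owned
#' haplotype (weight = `skew`) with the uniform pool. `skew = 1` makes each
#' cluster own one haplotype exactly; `skew = 0` is the exchangeable null.
#'
#' @param genes data frame: gene_id, chrom, start, end and optionally
#'   n_sites (default 8), n_haps (default 4), skew (default 0.85).
#' @param n_lines number of inbred lines (default 150).
#' @param n_clusters number of heterotic clusters (default 7, labelled
#'   HG1..HG7).
#' @param seed RNG seed (mandatory).
#' @param out_dir optional; when given, writes `population.vcf`,
#'   `clusters.tsv` and `hap_genes.tsv` there.
#' @return list: `vcf_lines`, `clusters` (named vector line -> cluster),
#'   `genes`, `truth` (per gene: line haplotype index, owned cluster per
#'   haplotype) and written `paths` when `out_dir` is given.
#' @export
simulate_population <- function(genes, n_lines = 150L, n_clusters = 7L,
                                seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (is.null(genes$n_sites)) genes$n_sites <- 8L
  if (is.null(genes$n_haps)) genes$n_haps <- 4L
  if (is.null(genes$skew)) genes$skew <- 0.85
  stopifnot(all(genes$skew >= 0 & genes$skew <= 1))
  if (any(2^genes$n_sites < genes$n_haps))
    stop("fewer variant sites than needed to distinguish haplotypes")
  if (any(genes$end - genes$start + 1L < genes$n_sites))
    stop("gene region shorter than requested site count")
  lines <- sprintf("L%03d", seq_len(n_lines))
  cl_labels <- sprintf("HG%d", seq_len(n_clusters))
  clusters <- stats::setNames(sample(rep(cl_labels, length.out = n_lines)),
                              lines)
  vcf_rows <- character(); truth <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    # distinct binary haplotypes over the gene's sites
    hmat <- matrix(stats::rbinom(g$n_haps * g$n_sites, 1L, 0.5),
                   nrow = g$n_haps)
    tries <- 0L
    while (anyDuplicated(hmat) && tries < 100L) {
      hmat <- matrix(stats::rbinom(g$n_haps * g$n_sites, 1L, 0.5),
                     nrow = g$n_haps)
      tries <- tries + 1L
    }
    if (anyDuplicated(hmat)) stop("could not generate distinct haplotypes")
    owned <- (seq_len(n_clusters) - 1L) %% g$n_haps + 1L
    hap_of_line <- vapply(lines, function(ln) {
      c_idx <- match(clusters[[ln]], cl_labels)
      probs <- rep((1 - g$skew) / g$n_haps, g$n_haps)
      probs[owned[c_idx]] <- probs[owned[c_idx]] + g$skew
      sample.int(g$n_haps, 1L, prob = probs)
    }, 0L)
    pos <- sort(sample(seq(g$start, g$end), g$n_sites))
    refalt <- t(vapply(seq_len(g$n_sites), function(s) {
      r <- sample(.NUC, 1L)
      c(r, sample(setdiff(.NUC, r), 1L))
    }, c("", "")))
    for (s in seq_len(g$n_sites)) {
      gts <- paste0(hmat[hap_of_line, s], "/", hmat[hap_of_line, s])
      vcf_rows <- c(vcf_rows, paste(c(
        g$chrom, pos[s], sprintf("%s_s%d", g$gene_id, s),
        refalt[s, 1L], refalt[s, 2L], ".", "PASS", ".", "GT", gts),
        collapse = "\t"))
    }
    truth[[g$gene_id]] <- list(hap_of_line = hap_of_line,
                               owned_cluster = stats::setNames(
                                 cl_labels[match(seq_len(g$n_haps), owned)],
                                 paste0("hap", seq_len(g$n_haps))),
                               skew = g$skew, positions = pos)
  }
  vcf_lines <- c("##fileformat=VCFv4.2",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", lines), collapse = "\t"),
                 vcf_rows)
  out <- list(vcf_lines = vcf_lines, clusters = clusters, genes = genes,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(out_dir, "population.vcf")
    writeLines(vcf_lines, vcf_path)
    cl_path <- file.path(out_dir, "clusters.tsv")
    write_panfam_tsv(data.frame(line_id = lines,
                                cluster = unname(clusters[lines])),
                     cl_path, header = paste("seed =", seed))
    genes_path <- file.path(out_dir, "hap_genes.tsv")
    write_panfam_tsv(genes, genes_path, header = paste("seed =", seed))
    out$paths <- list(vcf = vcf_path, clusters = cl_path, genes = genes_path)
  }
  invisible(out)
}

#' Simulate an expression count matrix with planted effects
#'
#' Negative-binomial counts for a tissue panel (6 tissues x reps) and a
#' stress panel (2 organs x control/salt/mannitol x reps). Planted effects:
#' tissue-specific genes (fold `tissue_fc` in one tissue), stress-induced
#' genes (given log2 fold-change under one treatment, both organs); all
#' other genes are null.
#'
#' @param gene_ids character vector of gene ids.
#' @param lengths named numeric vector of gene lengths (bp).
#' @param n_reps replicates per condition (default 3).
#' @param dispersion NB dispersion (default 0.05).
#' @param tissue_fc fold-change of tissue-specific genes (default 8).
#' @param planted data frame with gene_id and columns `tissue` (NA or a
#'   tissue name), `salt_lfc`, `mannitol_lfc` (0 = null); by default the
#'   first quarter of genes is root-specific and the next two eighths are
#'   salt- / mannitol-induced at log2FC 2.
#' @param seed RNG seed (mandatory).
#' @return list: `counts` (genes x samples), `lengths`, `metadata` (sample,
#'   tissue, organ, treatment), `planted`.
#' @export
simulate_counts <- function(gene_ids, lengths, n_reps = 3L,
                            dispersion = 0.05, tissue_fc = 8,
                            planted = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ng <- length(gene_ids)
  stopifnot(ng >= 4L, all(lengths[gene_ids] > 0))
  tissues <- c("embryo", "leaf", "root", "tassel", "stem", "silk")
  if (is.null(planted)) {
    planted <- data.frame(gene_id = gene_ids,
                          tissue = NA_character_, salt_lfc = 0,
                          mannitol_lfc = 0, stringsAsFactors = FALSE)
    q <- ng %/% 4L
    planted$tissue[seq_len(q)] <- "root"
    planted$salt_lfc[(q + 1L):(q + ng %/% 8L)] <- 2
    planted$mannitol_lfc[(q + ng %/% 8L + 1L):(q + ng %/% 4L)] <- 2
  }
  base_mu <- stats::setNames(stats::rlnorm(ng, log(50), 1), gene_ids)
  md <- rbind(
    expand.grid(tissue = tissues, rep = seq_len(n_reps), organ = NA,
                treatment = NA, stringsAsFactors = FALSE),
    expand.grid(tissue = NA, rep = seq_len(n_reps),
                organ = c("root", "shoot"),
                treatment = c("control", "salt", "mannitol"),
                stringsAsFactors = FALSE))
  md$sample <- ifelse(is.na(md$tissue),
                      sprintf("%s_%s_r%d", md$organ, md$treatment, md$rep),
                      sprintf("%s_r%d", md$tissue, md$rep))
  counts <- matrix(0L, nrow = ng, ncol = nrow(md),
                   dimnames = list(gene_ids, md$sample))
  for (j in seq_len(nrow(md))) {
    fold <- rep(1, ng)
    if (!is.na(md$tissue[j])) {
      fold[!is.na(planted$tissue) & planted$tissue == md$tissue[j]] <- tissue_fc
    } else if (md$treatment[j] == "salt") {
      fold <- 2^planted$salt_lfc
    } else if (md$treatment[j] == "mannitol") {
      fold <- 2^planted$mannitol_lfc
    }
    mu <- base_mu * fold * (lengths[gene_ids] / 1000)
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  list(counts = counts, lengths = lengths[gene_ids],
       metadata = md[, c("sample", "tissue", "organ", "treatment")],
       planted = planted)
}

#' Simulate association signals around a gene set
#'
#' Plants significant signals (score >= 0.05) inside or within the window
#' of the first `n_hit_genes` genes, plus sub-threshold and out-of-window
#' background signals that a correct candidate selection must ignore.
#'
#' @param genes data frame with gene_id, chrom, start, end.
#' @param n_hit_genes how many genes receive a true signal.
#' @param traits trait labels to draw from.
#' @param window half-window used downstream (default 100000).
#' @param seed RNG seed (mandatory).
#' @return list: `signals` (trait, chrom, pos, score), `expected_genes`.
#' @export
simulate_signals <- function(genes, n_hit_genes = 3L,
                             traits = c("PH", "DTA", "EW", "KRN", "TKW"),
                             window = 100000L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  stopifnot(nrow(genes) >= n_hit_genes)
  rows <- list()
  hit_genes <- genes$gene_id[seq_len(n_hit_genes)]
  for (i in seq_len(n_hit_genes)) {
    g <- genes[i, ]
    n_sig <- sample(1:2, 1L)
    for (s in seq_len(n_sig)) {
      inside <- stats::runif(1) < 0.5
      pos <- if (inside) sample(seq(g$start, g$end), 1L) else
        max(1L, g$end + sample.int(window, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = sample(traits, 1L), chrom = g$chrom, pos = pos,
        score = round(stats::runif(1, 0.05, 0.6), 3),
        stringsAsFactors = FALSE)
    }
  }
  # sub-threshold signal on a hit gene and a far-away significant signal
  g <- genes[1L, ]
  rows[[length(rows) + 1L]] <- data.frame(
    trait = traits[1L], chrom = g$chrom, pos = g$start,
    score = 0.01, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    trait = traits[2L], chrom = g$chrom,
    pos = max(genes$end[genes$chrom == g$chrom]) + window + 50000L,
    score = 0.4, stringsAsFactors = FALSE)
  list(signals = do.call(rbind, rows), expected_genes = hit_genes)
}
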