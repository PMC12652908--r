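# Pipeline orchestration over a manifest of genomes: runs scan -> og ->
# pan -> kaks -> cis -> tandem -> gwas -> hap -> expr for the inputs that
# are present, writes every table with a reproducibility header, and
# returns a machine-readable run report with per-stage record counts and
# output checksums.

.manifest_from_yaml <- function(path) {
  m <- yaml::read_yaml(path)
  m$genomes <- do.call(rbind, lapply(m$genomes, function(g)
    as.data.frame(g, stringsAsFactors = FALSE)))
  m
}

.check_manifest <- function(m) {
  stopifnot(is.data.frame(m$genomes),
            all(c("genome_id", "fasta", "gff", "hits") %in% names(m$genomes)))
  for (col in c("fasta", "gff", "hits")) {
    missing <- !file.exists(m$genomes[[col]])
    if (any(missing))
      stop("manifest file missing: ", m$genomes[[col]][missing][1L])
  }
  for (key in c("orthogroups", "vcf", "clusters", "hap_genes", "signals",
                "counts", "lengths", "metadata")) {
    if (!is.null(m[[key]]) && !file.exists(m[[key]]))
      stop("manifest file missing: ", m[[key]])
  }
  if (is.null(m$seed)) stop("manifest must carry a seed")
  m
}

#' Run the full pan-family pipeline from a manifest
#'
#' The manifest is a list (or path to a YAML file) with a `genomes` table
#' (genome_id, fasta, gff, hits, optional jrl_hits), optional paths
#' `orthogroups`, `vcf` + `clusters` + `hap_genes`, `signals`, `counts` +
#' `lengths` + `metadata`, a mandatory `seed`, and optional `params`
#' overriding stage defaults (e_max, identity_threshold, reps, window,
#' score_min, max_intervening, min_count, perms). Stages with absent
#' optional inputs are reported as "skipped"; a stage failure aborts with
#' the stage name, retaining partial output under a `.partial` suffix.
#'
#' @param manifest list or YAML path (see above).
#' @param out_dir output directory.
#' @return (invisibly) the run report: per-stage status/record counts, the
#'   seed, parameters, and md5 checksums of all outputs (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- .manifest_from_yaml(manifest)
  m <- .check_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(e_max = 1e-5, identity_threshold = 90, reps = 1000L,
            window = 100000L, score_min = 0.05, max_intervening = 5L,
            min_count = 2L, perms = 999L)
  p[names(m$params)] <- m$params
  seed <- as.integer(m$seed)
  hdr <- function(...) c(paste("panfam", as.character(utils::packageVersion("panfam"))),
                         paste("seed =", seed), ...)
  stages <- list(); t0 <- Sys.time()
  outputs <- character()
  run_stage <- function(name, fun) {
    tic <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      part <- file.path(out_dir, paste0(name, ".partial"))
      writeLines(conditionMessage(res), part)
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    stages[[name]] <<- data.frame(
      stage = name, status = res$status, n_records = res$n,
      seconds = round(as.numeric(Sys.time() - tic, units = "secs"), 3),
      stringsAsFactors = FALSE)
    if (!is.null(res$files)) outputs <<- c(outputs, res$files)
  }

  env <- new.env()
  run_stage("scan", function() {
    fams <- lapply(seq_len(nrow(m$genomes)), function(i) {
      g <- m$genomes[i, ]
      jrl <- if (!is.null(g$jrl_hits) && !is.na(g$jrl_hits) &&
                 nzchar(g$jrl_hits)) read_domtblout(g$jrl_hits) else NULL
      scan_family(read_fasta(g$fasta), read_gff3(g$gff),
                  read_domtblout(g$hits), g$genome_id,
                  jrl_hits = jrl, e_max = p$e_max)
    })
    env$genes <- do.call(rbind, lapply(fams, `[[`, "genes"))
    env$proteins <- unlist(lapply(fams, `[[`, "proteins"))
    env$cds <- unlist(lapply(fams, `[[`, "cds"))
    env$upstream <- unlist(lapply(fams, `[[`, "upstream"))
    env$gene2genome <- stats::setNames(env$genes$genome_id, env$genes$gene_id)
    f <- file.path(out_dir, "genes.tsv")
    write_panfam_tsv(env$genes, f, hdr(paste("e_max =", p$e_max)))
    write_fasta(env$proteins, file.path(out_dir, "proteins.fa"))
    write_fasta(env$cds, file.path(out_dir, "cds.fa"))
    up <- env$upstream[nzchar(env$upstream)]
    write_fasta(up, file.path(out_dir, "upstream.fa"))
    list(status = "ok", n = nrow(env$genes),
         files = c(f, file.path(out_dir, c("proteins.fa", "cds.fa",
                                           "upstream.fa"))))
  })

  run_stage("og", function() {
    env$ogset <- if (!is.null(m$orthogroups)) {
      refine_orthogroups(read_orthogroups_tsv(m$orthogroups), env$proteins,
                         threshold = p$identity_threshold)
    } else {
      cluster_denovo(env$proteins, threshold = p$identity_threshold)
    }
    f <- file.path(out_dir, "ogs.tsv")
    write_panfam_tsv(ogset_table(env$ogset), f,
                     hdr(paste("identity_threshold =", p$identity_threshold)))
    list(status = "ok", n = length(env$ogset$ogs), files = f)
  })

  run_stage("pan", function() {
    env$pm <- build_pan_matrix(env$ogset, env$gene2genome,
                               genome_ids = m$genomes$genome_id)
    occ <- classify_occupancy(env$pm)
    curve <- saturation_curve(env$pm, reps = p$reps, seed = seed)
    f1 <- file.path(out_dir, "pan.tsv")
    f2 <- file.path(out_dir, "curve.tsv")
    write_panfam_tsv(occ, f1, hdr())
    write_panfam_tsv(as.data.frame(curve), f2,
                     hdr(paste("reps =", p$reps)))
    env$occ <- occ
    list(status = "ok", n = nrow(occ), files = c(f1, f2))
  })

  run_stage("kaks", function() {
    kk <- og_kaks(env$ogset, env$cds, env$gene2genome,
                  proteins = env$proteins)
    f1 <- file.path(out_dir, "kaks.tsv")
    f2 <- file.path(out_dir, "kaks_summary.tsv")
    write_panfam_tsv(kk$pairs, f1, hdr())
    write_panfam_tsv(kk$summary, f2, hdr())
    env$kaks <- kk
    list(status = "ok", n = nrow(kk$pairs), files = c(f1, f2))
  })

  run_stage("cis", function() {
    motifs <- read_motif_table(m$motifs)
    up <- env$upstream[nzchar(env$upstream)]
    hits <- scan_motifs(up, motifs)
    prof <- og_category_profile(hits, motifs,
                                .restrict_ogset(env$ogset, rownames(hits)))
    f1 <- file.path(out_dir, "cis.tsv")
    f2 <- file.path(out_dir, "cis_profile.tsv")
    write_panfam_tsv(data.frame(gene_id = rownames(hits), as.data.frame(hits),
                           check.names = FALSE), f1, hdr())
    write_panfam_tsv(data.frame(og_id = rownames(prof), as.data.frame(prof),
                           check.names = FALSE), f2, hdr())
    list(status = "ok", n = nrow(hits), files = c(f1, f2))
  })

  run_stage("tandem", function() {
    td <- do.call(rbind, lapply(split(env$genes, env$genes$genome_id),
      function(d) {
        t1 <- find_tandem(d, env$ogset, max_intervening = p$max_intervening)
        if (nrow(t1)) cbind(genome_id = d$genome_id[[1L]], t1) else NULL
      }))
    if (is.null(td))
      td <- data.frame(genome_id = character(), cluster_id = character(),
                       og_id = character(), chrom = character(),
                       n_members = integer(), members = character())
    rownames(td) <- NULL
    f <- file.path(out_dir, "tandem.tsv")
    write_panfam_tsv(td, f, hdr(paste("max_intervening =", p$max_intervening)))
    list(status = "ok", n = nrow(td), files = f)
  })

  run_stage("gwas", function() {
    if (is.null(m$signals)) return(list(status = "skipped", n = 0L))
    signals <- read_panfam_tsv(m$signals)
    cand <- select_candidates(env$genes, signals, score_min = p$score_min,
                              window = p$window)
    traits <- trait_summary(cand)
    f1 <- file.path(out_dir, "candidates.tsv")
    f2 <- file.path(out_dir, "traits.tsv")
    write_panfam_tsv(cand, f1, hdr(paste("window =", p$window),
                                   paste("score_min =", p$score_min)))
    write_panfam_tsv(traits, f2, hdr())
    list(status = "ok", n = nrow(cand), files = c(f1, f2))
  })

  run_stage("hap", function() {
    if (is.null(m$vcf) || is.null(m$clusters) || is.null(m$hap_genes))
      return(list(status = "skipped", n = 0L))
    vcf <- read_vcf_minimal(m$vcf)
    cl_tab <- read_panfam_tsv(m$clusters)
    clusters <- stats::setNames(cl_tab$cluster, cl_tab$line_id)
    hg <- read_panfam_tsv(m$hap_genes)
    rows <- list()
    for (i in seq_len(nrow(hg))) {
      tab <- call_haplotypes(vcf, hg$chrom[i], hg$start[i], hg$end[i],
                             min_count = p$min_count)
      if (!nrow(tab$haplotypes)) next
      dist <- cluster_distribution(tab, clusters)
      sk <- skew_statistic(tab, clusters, perms = p$perms, seed = seed + i)
      rows[[hg$gene_id[i]]] <- data.frame(
        gene_id = hg$gene_id[i], n_haplotypes = nrow(tab$haplotypes),
        n_counted = length(tab$line_haplotype),
        n_excluded = tab$n_excluded,
        top_haplotype_frac = max(tab$haplotypes$count) /
          sum(tab$haplotypes$count),
        skew_score = sk$score, skew_p = sk$p_value,
        stringsAsFactors = FALSE)
      write_panfam_tsv(
        cbind(haplotype = rownames(dist), as.data.frame(dist)),
        file.path(out_dir, sprintf("hap_%s.tsv", hg$gene_id[i])), hdr())
    }
    hap <- do.call(rbind, rows); rownames(hap) <- NULL
    f <- file.path(out_dir, "haplotypes.tsv")
    write_panfam_tsv(hap, f, hdr(paste("min_count =", p$min_count),
                                 paste("perms =", p$perms)))
    list(status = "ok", n = nrow(hap),
         files = c(f, file.path(out_dir, sprintf("hap_%s.tsv", hap$gene_id))))
  })

  run_stage("expr", function() {
    if (is.null(m$counts)) return(list(status = "skipped", n = 0L))
    cm <- read_panfam_tsv(m$counts)
    counts <- as.matrix(cm[, -1L, drop = FALSE])
    rownames(counts) <- cm[[1L]]
    lt <- read_panfam_tsv(m$lengths)
    lens <- stats::setNames(lt[[2L]], lt[[1L]])
    md <- read_panfam_tsv(m$metadata)
    fp <- fpkm(counts, lens)
    tp <- tissue_profile(fp, md[!is.na(md$tissue) & nzchar(md$tissue), ])
    sr <- stress_response(fp, md[!is.na(md$organ) & nzchar(md$organ), ])
    f1 <- file.path(out_dir, "fpkm.tsv")
    f2 <- file.path(out_dir, "tissue_profile.tsv")
    f3 <- file.path(out_dir, "stress.tsv")
    write_panfam_tsv(data.frame(gene_id = rownames(fp),
                           as.data.frame(round(fp, 4)), check.names = FALSE),
                     f1, hdr())
    write_panfam_tsv(data.frame(gene_id = rownames(tp$means),
                           as.data.frame(round(tp$means, 4)),
                           argmax = unname(tp$argmax), check.names = FALSE),
                     f2, hdr())
    write_panfam_tsv(sr, f3, hdr())
    list(status = "ok", n = nrow(fp), files = c(f1, f2, f3))
  })

  report <- list(
    seed = seed, params = p,
    stages = do.call(rbind, unname(stages)),
    checksums = as.list(tools::md5sum(sort(unique(outputs)))),
    elapsed = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(
    list(seed = report$seed, params = report$params,
         stages = report$stages[, c("stage", "status", "n_records")],
         checksums = report$checksums),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

.restrict_ogset <- function(ogset, keep) {
  ogs <- lapply(ogset$ogs, intersect, keep)
  ogs <- ogs[lengths(ogs) > 0L]
  structure(list(ogs = ogs,
                 singletons = intersect(ogset$singletons, keep)),
            class = "orthogroup_set")
}

#' Simulate a complete study and write its pipeline manifest
#'
#' Convenience wrapper chaining [simulate_pan_genome()],
#' [simulate_population()], [simulate_signals()] and [simulate_counts()]
#' on a common seed, writing all inputs plus a `manifest.yaml` that
#' [run_pipeline()] accepts.
#'
#' @param out_dir directory for the simulated study.
#' @param seed RNG seed (mandatory).
#' @param config a [sim_config()]; default scaled to `n_genomes`.
#' @param n_genomes genomes to simulate when `config` is missing
#'   (default 5).
#' @param n_hap_genes genes carried into the population simulation.
#' @param n_lines population size (default 150).
#' @return (invisibly) list with `manifest` (path), the manifest list, and
#'   the component truths.
#' @export
simulate_study <- function(out_dir, seed, config = NULL, n_genomes = 5L,
                           n_hap_genes = 4L, n_lines = 150L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(config))
    config <- sim_config(n_genomes = n_genomes, seed = seed)
  pan <- simulate_pan_genome(config, out_dir)
  g1 <- pan$truth$genes[pan$truth$genes$genome_id ==
                          pan$truth$genes$genome_id[[1L]], ]
  g1 <- g1[!g1$on_scaffold, ]
  hap_genes <- utils::head(g1[order(g1$gene_id),
                              c("gene_id", "chrom", "start", "end")],
                           n_hap_genes)
  hap_genes$skew <- rep(c(1, 0), length.out = nrow(hap_genes))
  pop <- simulate_population(hap_genes, n_lines = n_lines, seed = seed + 1L,
                             out_dir = out_dir)
  sig <- simulate_signals(g1, n_hit_genes = min(3L, nrow(g1)),
                          seed = seed + 2L)
  sig_path <- file.path(out_dir, "signals.tsv")
  write_panfam_tsv(sig$signals, sig_path, header = paste("seed =", seed + 2L))
  lens <- stats::setNames(g1$end - g1$start + 1L, g1$gene_id)
  ex <- simulate_counts(g1$gene_id, lens, seed = seed + 3L)
  counts_path <- file.path(out_dir, "counts.tsv")
  write_panfam_tsv(data.frame(gene_id = rownames(ex$counts),
                         as.data.frame(ex$counts), check.names = FALSE),
                   counts_path, header = paste("seed =", seed + 3L))
  lengths_path <- file.path(out_dir, "lengths.tsv")
  write_panfam_tsv(data.frame(gene_id = names(ex$lengths),
                              length = unname(ex$lengths)), lengths_path)
  meta_path <- file.path(out_dir, "metadata.tsv")
  write_panfam_tsv(ex$metadata, meta_path)
  manifest <- list(
    genomes = pan$paths, seed = seed,
    vcf = pop$paths$vcf, clusters = pop$paths$clusters,
    hap_genes = pop$paths$genes, signals = sig_path,
    counts = counts_path, lengths = lengths_path, metadata = meta_path)
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    genomes = lapply(seq_len(nrow(pan$paths)), function(i)
      as.list(pan$paths[i, ])),
    seed = seed, vcf = manifest$vcf, clusters = manifest$clusters,
    hap_genes = manifest$hap_genes, signals = manifest$signals,
    counts = manifest$counts, lengths = manifest$lengths,
    metadata = manifest$metadata), mpath)
  invisible(list(manifest_path = mpath, manifest = manifest,
                 pan = pan, pop = pop, signals = sig, expression = ex))
}
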