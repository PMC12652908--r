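# Readers and writers for the external formats the pipeline touches.
# All genomic coordinates are 1-based inclusive throughout the package;
# the two primary inputs (GFF3, VCF) are natively 1-based so no conversion
# happens after the read boundary.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and whitespace-stripped; record ids are the
#' first whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]], " in ", path)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs)))
    stop("empty record ", ids[!nzchar(seqs)][[1L]], " in ", path)
  names(seqs) <- ids
  seqs
}

#' Write a named character vector as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]*"), attr))
  out <- rep(NA_character_, length(attr))
  hit <- lengths(regmatches(attr, gregexpr(paste0("(^|;)", key, "="), attr))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read a GFF3 annotation
#'
#' Parses gene, mRNA and CDS features. Genes get a `rank`: their 1-based
#' position in ascending-start order among all genes of the same chromosome
#' (used by tandem-duplication detection). CDS segments are returned in
#' 5'-to-3' transcript orientation (descending start on the minus strand).
#'
#' @param path path to a GFF3 file.
#' @return a list of class `panfam_annotation` with data frames `genes`
#'   (gene_id, chrom, start, end, strand, rank), `transcripts` (tx_id,
#'   gene_id) and `cds` (tx_id, start, end).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no feature lines in ", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("malformed GFF3 line (", which(lengths(f) != 9L)[1L], " fields != 9) in ", path)
  f <- do.call(rbind, f)
  type <- f[, 3L]
  keep <- type %in% c("gene", "mRNA", "CDS")
  f <- f[keep, , drop = FALSE]
  type <- type[keep]
  start <- as.integer(f[, 4L])
  end <- as.integer(f[, 5L])
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinate in ", path)
  if (any(end < start))
    stop("feature with end < start at line with start=", start[end < start][1L])
  strand <- f[, 7L]
  if (any(type == "gene" & !strand %in% c("+", "-")))
    stop("gene with strand outside {+,-}")
  attr <- f[, 9L]
  id <- .parse_gff_attr(attr, "ID")
  parent <- .parse_gff_attr(attr, "Parent")

  gi <- type == "gene"
  genes <- data.frame(gene_id = id[gi], chrom = f[gi, 1L],
                      start = start[gi], end = end[gi], strand = strand[gi],
                      stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ID ", genes$gene_id[duplicated(genes$gene_id)][1L])
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chrom, FUN = seq_along)
  rownames(genes) <- NULL

  ti <- type == "mRNA"
  transcripts <- data.frame(tx_id = id[ti], gene_id = parent[ti],
                            strand = strand[ti], stringsAsFactors = FALSE)
  if (any(!transcripts$gene_id %in% genes$gene_id))
    stop("mRNA with unknown Parent: ",
         transcripts$tx_id[!transcripts$gene_id %in% genes$gene_id][1L])

  ci <- type == "CDS"
  cds <- data.frame(tx_id = parent[ci], start = start[ci], end = end[ci],
                    stringsAsFactors = FALSE)
  if (any(!cds$tx_id %in% transcripts$tx_id))
    stop("CDS with unknown Parent: ", cds$tx_id[!cds$tx_id %in% transcripts$tx_id][1L])
  # order segments 5'->3' in transcript orientation
  str_of_tx <- stats::setNames(transcripts$strand, transcripts$tx_id)
  neg <- str_of_tx[cds$tx_id] == "-"
  key <- ifelse(neg, -cds$start, cds$start)
  cds <- cds[order(cds$tx_id, key), , drop = FALSE]
  rownames(cds) <- NULL

  structure(list(genes = genes, transcripts = transcripts, cds = cds),
            class = "panfam_annotation")
}

#' @export
print.panfam_annotation <- function(x, ...) {
  cat("panfam annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

#' Read HMMER domtblout domain hits
#'
#' Space-delimited `--domtblout` dialect; `#` lines are comments. The
#' per-domain independent E-value (column 13) is used as the hit E-value,
#' because downstream filtering is a domain filter.
#'
#' @param path path to a domtblout file.
#' @return data frame with gene_id, domain_name, e_value, ali_start, ali_end.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(data.frame(gene_id = character(), domain_name = character(),
                      e_value = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE))
  f <- strsplit(trimws(lines), "\\s+")
  short <- lengths(f) < 22L
  if (any(short))
    stop("truncated domtblout line ", lineno[short][1L], " in ", path)
  get <- function(i) vapply(f, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v))
      stop("malformed numeric ", what, " at line ", lineno[is.na(v)][1L],
           " in ", path)
    v
  }
  out <- data.frame(
    gene_id = get(1L), domain_name = get(4L),
    e_value = num(13L, "i-Evalue"),
    ali_start = as.integer(num(18L, "ali_from")),
    ali_end = as.integer(num(19L, "ali_to")),
    stringsAsFactors = FALSE)
  if (any(out$e_value < 0)) stop("negative E-value in ", path)
  if (any(out$ali_end < out$ali_start)) stop("ali_end < ali_start in ", path)
  out
}

#' Read a minimal GT-only VCF
#'
#' Inbred-line convention: diploid homozygous genotypes collapse to a single
#' allele index; heterozygous or missing (`./.`) genotypes become `NA`.
#'
#' @param path path to an uncompressed VCF.
#' @return list with `variants` (data frame: chrom, pos, ref, alt — alt is a
#'   comma-joined string), `genotypes` (sites x samples integer matrix of
#'   allele indices, NA = missing) and `samples`.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr)) stop("missing #CHROM header in ", path)
  cols <- strsplit(lines[hdr[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF has no sample columns: ", path)
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != length(cols)))
    stop("VCF record with wrong column count in ", path)
  f <- do.call(rbind, f)
  if (is.null(dim(f))) f <- matrix(f, nrow = length(body))
  variants <- data.frame(
    chrom = f[, 1L], pos = as.integer(f[, 2L]),
    ref = f[, 4L], alt = f[, 5L], stringsAsFactors = FALSE)
  if (any(!nzchar(variants$ref))) stop("empty REF allele in ", path)
  fmt <- strsplit(f[, 9L], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(x) match("GT", x), 0L)
  if (anyNA(gt_idx)) stop("record without GT in FORMAT in ", path)
  gt_raw <- f[, -(1:9), drop = FALSE]
  n_alt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
  gmat <- matrix(NA_integer_, nrow = nrow(f), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (i in seq_len(nrow(f))) {
    gts <- vapply(strsplit(gt_raw[i, ], ":", fixed = TRUE), `[[`, "", gt_idx[i])
    al <- strsplit(gts, "[/|]")
    v <- vapply(al, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a) || length(unique(a)) != 1L) NA_integer_ else a[[1L]]
    }, 0L)
    if (any(v > n_alt[i], na.rm = TRUE))
      stop("allele index out of range at ", variants$chrom[i], ":",
           variants$pos[i])
    gmat[i, ] <- v
  }
  list(variants = variants, genotypes = gmat, samples = samples)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' Tab-separated: first column orthogroup id, remaining columns one per
#' genome holding comma-separated gene lists (possibly empty).
#'
#' @param path path to the table.
#' @return named list mapping orthogroup id to a character vector of gene ids.
#' @export
read_orthogroups_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("orthogroup table needs >= 2 columns: ", path)
  ogs <- lapply(seq_len(nrow(tab)), function(i) {
    cells <- unlist(tab[i, -1L], use.names = FALSE)
    genes <- unlist(strsplit(cells[nzchar(cells) & !is.na(cells)], ",\\s*"))
    trimws(genes[nzchar(trimws(genes))])
  })
  names(ogs) <- tab[[1L]]
  ogs
}

# --- generic TSV with a reproducibility comment header ------------------

#' Write a data frame as TSV with `#` comment header lines
#'
#' Every pipeline output begins with comment lines recording the tool
#' version, seed and parameters, so results are self-describing.
#'
#' @param x data frame.
#' @param path output path.
#' @param header character vector of comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_panfam_tsv <- function(x, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_panfam_tsv()]
#'
#' @param path path to the table.
#' @return data frame (comment lines skipped).
#' @export
read_panfam_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
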