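# Promoter cis-regulatory element scanning: exact IUPAC matching of a
# packaged motif table against 2 kb upstream sequences, on both strands,
# counting all (possibly overlapping) occurrences. An `N` in the scanned
# sequence matches nothing. Per-orthogroup category profiles report the
# fraction of members with at least one hit in the category.

#' Load a cis-element motif table
#'
#' Columns: name, iupac, category (hormone, stress, light, development,
#' core). The packaged default holds ~30 canonical plant promoter elements;
#' it is an editable convention, not a reproduction of any web catalogue.
#'
#' @param path optional path to a custom TSV; default = packaged table.
#' @return data frame with name, iupac, category.
#' @export
read_motif_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs.tsv", package = "panfam",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "iupac", "category")
  if (!all(need %in% names(tab)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  tab$iupac <- toupper(tab$iupac)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", tab$iupac)
  if (any(bad)) stop("invalid IUPAC motif: ", tab$name[bad][1L])
  if (anyDuplicated(tab$name)) stop("duplicate motif name")
  tab
}

#' Scan sequences for motif occurrences on both strands
#'
#' Counts every exact IUPAC match of each motif on the forward strand plus
#' its reverse complement; overlapping matches all count.
#'
#' @param seqs named character vector of promoter sequences over
#'   `{A,C,G,T,N}`.
#' @param motifs motif table from [read_motif_table()].
#' @return integer matrix, sequences x motifs.
#' @export
scan_motifs <- function(seqs, motifs) {
  stopifnot(!is.null(names(seqs)))
  bad <- grepl("[^ACGTN]", toupper(seqs))
  if (any(bad))
    stop("invalid character in sequence ", names(seqs)[bad][1L])
  out <- matrix(0L, nrow = length(seqs), ncol = nrow(motifs),
                dimnames = list(names(seqs), motifs$name))
  keep <- nzchar(seqs)
  if (!any(keep)) return(out)
  set <- Biostrings::DNAStringSet(toupper(seqs[keep]))
  rc <- vapply(motifs$iupac, revcomp, "")
  for (j in seq_len(nrow(motifs))) {
    cnt <- Biostrings::vcountPattern(motifs$iupac[j], set, fixed = "subject") +
      Biostrings::vcountPattern(rc[[j]], set, fixed = "subject")
    out[keep, j] <- cnt
  }
  out
}

#' Per-orthogroup cis-element category profile
#'
#' @param hits count matrix from [scan_motifs()].
#' @param motifs the motif table used for scanning.
#' @param ogset an `orthogroup_set`; members missing from `hits` are an
#'   error.
#' @return matrix orthogroups x categories: fraction of members with >= 1
#'   hit in any motif of the category.
#' @export
og_category_profile <- function(hits, motifs, ogset) {
  cats <- sort(unique(motifs$category))
  out <- matrix(0, nrow = length(ogset$ogs), ncol = length(cats),
                dimnames = list(names(ogset$ogs), cats))
  for (og in names(ogset$ogs)) {
    members <- ogset$ogs[[og]]
    miss <- setdiff(members, rownames(hits))
    if (length(miss)) stop("no motif scan for gene ", miss[[1L]])
    sub <- hits[members, , drop = FALSE]
    for (cc in cats) {
      cols <- motifs$name[motifs$category == cc]
      out[og, cc] <- mean(rowSums(sub[, cols, drop = FALSE]) > 0)
    }
  }
  out
}
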