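# FPKM from a count matrix, tissue expression profiles (with z-scored rows
# for heatmap export) and stress-response log2 fold-changes. The library
# size is the within-matrix column sum; mapped-read totals from upstream
# alignment are outside the package boundary.

#' FPKM normalisation
#'
#' `fpkm[g,s] = counts[g,s] * 1e9 / (colsum[s] * length[g])`.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param lengths named numeric vector of gene lengths in bp.
#' @return numeric matrix of FPKM values, same dimensions as `counts`.
#' @export
fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("negative counts")
  lens <- lengths[rownames(counts)]
  if (anyNA(lens)) stop("missing length for gene ",
                        rownames(counts)[is.na(lens)][1L])
  if (any(lens <= 0)) stop("non-positive gene length")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero column total in sample ",
                             colnames(counts)[totals == 0][1L])
  sweep(counts * 1e9, 2L, totals, "/") / lens
}

#' Per-tissue expression means and z-scored profiles
#'
#' Tissue means of FPKM per gene, plus per-gene z-scores across tissues of
#' `log2(mean FPKM + 1)` for heatmap export; constant rows get z-scores of
#' 0, all-zero genes get NA z-scores.
#'
#' @param fpkm_mat FPKM matrix (genes x samples).
#' @param metadata data frame with `sample` and `tissue` columns covering
#'   the matrix columns to profile.
#' @return list: `means` (genes x tissues), `zscores` (same shape),
#'   `argmax` (named character: tissue of maximal mean per gene; NA for
#'   all-zero genes).
#' @export
tissue_profile <- function(fpkm_mat, metadata) {
  stopifnot(all(c("sample", "tissue") %in% names(metadata)))
  md <- metadata[metadata$sample %in% colnames(fpkm_mat), , drop = FALSE]
  if (!nrow(md)) stop("no metadata samples found in matrix")
  tissues <- sort(unique(md$tissue))
  means <- vapply(tissues, function(tt) {
    cols <- md$sample[md$tissue == tt]
    rowMeans(fpkm_mat[, cols, drop = FALSE])
  }, numeric(nrow(fpkm_mat)))
  lg <- log2(means + 1)
  mu <- rowMeans(lg)
  sd_ <- apply(lg, 1L, stats::sd)
  z <- (lg - mu) / ifelse(sd_ > 0, sd_, 1)  # constant rows -> 0
  z[rowSums(means) == 0, ] <- NA_real_      # all-zero rows -> null profile
  argmax <- colnames(means)[max.col(means, ties.method = "first")]
  argmax[rowSums(means) == 0] <- NA_character_
  list(means = means, zscores = z,
       argmax = stats::setNames(argmax, rownames(fpkm_mat)))
}

#' Stress-response log2 fold-changes
#'
#' Per organ and treatment: `log2((mean treated FPKM + pseudo) /
#' (mean control FPKM + pseudo))`; a gene is flagged induced when the
#' fold-change reaches `lfc_min`. The threshold is a package convention
#' for a qualitative induction call.
#'
#' @param fpkm_mat FPKM matrix (genes x samples).
#' @param metadata data frame with `sample`, `organ`, `treatment` columns;
#'   the control group is `treatment == "control"`.
#' @param lfc_min induction threshold on log2 fold-change (default 1).
#' @param pseudo pseudocount (default 1).
#' @return data frame: gene_id, organ, treatment, log2fc, induced.
#' @export
stress_response <- function(fpkm_mat, metadata, lfc_min = 1, pseudo = 1) {
  stopifnot(all(c("sample", "organ", "treatment") %in% names(metadata)))
  md <- metadata[metadata$sample %in% colnames(fpkm_mat), , drop = FALSE]
  rows <- list()
  for (organ in sort(unique(md$organ))) {
    ctrl <- md$sample[md$organ == organ & md$treatment == "control"]
    if (!length(ctrl)) stop("missing control group for organ ", organ)
    cmean <- rowMeans(fpkm_mat[, ctrl, drop = FALSE])
    for (trt in setdiff(sort(unique(md$treatment[md$organ == organ])),
                        "control")) {
      tcols <- md$sample[md$organ == organ & md$treatment == trt]
      tmean <- rowMeans(fpkm_mat[, tcols, drop = FALSE])
      lfc <- log2((tmean + pseudo) / (cmean + pseudo))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = rownames(fpkm_mat), organ = organ, treatment = trt,
        log2fc = unname(lfc), induced = unname(lfc >= lfc_min),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
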