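# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method on
# protein-guided codon alignments.
#
# Site counting: at each codon position the three alternative nucleotides
# are examined; changes to stop codons are excluded from the denominator,
# and the synonymous fraction of the remaining changes contributes to S
# (so S + N = 3 x codons holds by construction). Differences between a
# codon pair differing at d positions are averaged over all d! substitution
# orders with equal weight; orders passing through a stop codon are
# excluded (with a fall-back to all orders if every path hits a stop).
# Proportions are Jukes-Cantor corrected: K = -3/4 ln(1 - 4/3 p).

.kaks_cache <- new.env(parent = emptyenv())

.codon_sites <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    base <- substring(codon, pos, pos)
    syn <- 0L; valid <- 0L
    for (alt in setdiff(.NUC, base)) {
      mut <- codon
      substring(mut, pos, pos) <- alt
      maa <- .GENETIC_CODE[[mut]]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.perms(v[-i]), function(p) c(v[i], p)))
  out
}

.codon_path_diffs <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  orders <- .perms(diff_pos)
  tally <- function(order, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      if (!allow_stop && nxt != c2 && .GENETIC_CODE[[nxt]] == "*")
        return(NULL)
      if (.GENETIC_CODE[[cur]] == .GENETIC_CODE[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(orders, tally, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
}

.kaks_tables <- function() {
  if (!is.null(.kaks_cache$sites)) return(invisible(NULL))
  codons <- .SENSE_CODONS
  sites <- t(vapply(codons, .codon_sites, c(s = 0, n = 0)))
  nn <- length(codons)
  sd <- matrix(0, nn, nn, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (i == j) next
    pd <- .codon_path_diffs(codons[i], codons[j])
    sd[i, j] <- pd[["sd"]]; nd[i, j] <- pd[["nd"]]
  }
  .kaks_cache$sites <- sites
  .kaks_cache$sd <- sd
  .kaks_cache$nd <- nd
  invisible(NULL)
}

.split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("codon string length not a multiple of 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Input rows may contain whole-codon gaps (`---`); gapped or ambiguous
#' codon columns, and columns where either codon is a stop, are dropped
#' pairwise before counting.
#'
#' @param codon_a,codon_b aligned codon strings of equal length (multiple
#'   of 3).
#' @return list of class `kaks_result`: S, N (site counts), Sd, Nd
#'   (difference counts), pS, pN, Ks, Ka, ratio and `status` ("ok",
#'   "ks_zero" when no synonymous divergence, "saturated" when a
#'   Jukes-Cantor correction diverges). `ratio` is NA unless status is
#'   "ok".
#' @export
ng86 <- function(codon_a, codon_b) {
  .kaks_tables()
  ca <- toupper(codon_a); cb <- toupper(codon_b)
  if (nchar(ca) != nchar(cb)) stop("aligned codon strings differ in length")
  a <- .split_codons(ca); b <- .split_codons(cb)
  ok <- a %in% .SENSE_CODONS & b %in% .SENSE_CODONS
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no comparable codon pairs")
  sites <- .kaks_cache$sites
  S <- (sum(sites[a, "s"]) + sum(sites[b, "s"])) / 2
  N <- (sum(sites[a, "n"]) + sum(sites[b, "n"])) / 2
  Sd <- sum(.kaks_cache$sd[cbind(a, b)])
  Nd <- sum(.kaks_cache$nd[cbind(a, b)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  status <- if (is.na(Ks) || is.na(Ka)) "saturated"
            else if (Ks == 0) "ks_zero" else "ok"
  ratio <- if (identical(status, "ok")) Ka / Ks else NA_real_
  structure(list(n_codons = length(a), S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
                 status = status),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s ratio=%s [%s]\n",
              x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4), x$status))
  invisible(x)
}

#' Thread coding sequences onto a protein alignment
#'
#' Replaces every aligned residue by its source codon and every residue gap
#' by `---`, giving a codon alignment whose ungapped translation equals the
#' input proteins.
#'
#' @param prot_aln_a,prot_aln_b aligned (gapped) protein strings of equal
#'   length.
#' @param cds_a,cds_b in-frame coding sequences of the two proteins
#'   (terminal stop already trimmed).
#' @return list with `codon_a` and `codon_b`.
#' @export
backthread_codons <- function(prot_aln_a, prot_aln_b, cds_a, cds_b) {
  thread <- function(paln, cds, label) {
    res <- strsplit(paln, "")[[1L]]
    aa <- res[res != "-"]
    codons <- .split_codons(toupper(cds))
    if (length(codons) != length(aa))
      stop("CDS/protein length mismatch for sequence ", label)
    tr <- .GENETIC_CODE[codons]
    tr[is.na(tr)] <- "X"
    bad <- which(tr != aa & aa != "X")
    if (length(bad))
      stop("CDS does not translate to protein for sequence ", label,
           " at residue ", bad[[1L]])
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- codons
    paste(out, collapse = "")
  }
  if (nchar(prot_aln_a) != nchar(prot_aln_b))
    stop("protein alignment rows differ in length")
  list(codon_a = thread(prot_aln_a, cds_a, "a"),
       codon_b = thread(prot_aln_b, cds_b, "b"))
}

#' Align two genes and estimate Ka/Ks
#'
#' Globally aligns the proteins (BLOSUM62, gap open 10 / extend 0.5),
#' threads the coding sequences onto the alignment and applies [ng86()].
#'
#' @param cds_a,cds_b coding sequences (terminal stop trimmed).
#' @param prot_a,prot_b optional proteins; translated from the CDS when
#'   omitted.
#' @return a `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b, prot_a = NULL, prot_b = NULL) {
  if (is.null(prot_a)) prot_a <- translate_cds(cds_a)
  if (is.null(prot_b)) prot_b <- translate_cds(cds_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  th <- backthread_codons(
    as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)),
    cds_a, cds_b)
  ng86(th$codon_a, th$codon_b)
}

#' Ka/Ks over all cross-genome pairs within each orthogroup
#'
#' @param ogset an `orthogroup_set`.
#' @param cds named character vector of coding sequences.
#' @param gene2genome named character vector mapping gene id to genome id;
#'   pairs from the same genome are skipped (paralogous pairs can be
#'   included with `within_genome = TRUE`).
#' @param proteins optional named protein vector.
#' @param within_genome include same-genome pairs (default FALSE).
#' @return list with `pairs` (one row per pair: og_id, gene_a, gene_b, Ka,
#'   Ks, ratio, status) and `summary` (per orthogroup: n_pairs, median
#'   ratio over defined ratios, fraction > 1, any_positive flag).
#' @export
og_kaks <- function(ogset, cds, gene2genome, proteins = NULL,
                    within_genome = FALSE) {
  rows <- list()
  for (og in names(ogset$ogs)) {
    members <- ogset$ogs[[og]]
    members <- members[members %in% names(cds)]
    if (length(members) < 2L) {
      message("skipping ", og, ": fewer than 2 members with CDS")
      next
    }
    cmb <- utils::combn(sort(members), 2L)
    for (p in seq_len(ncol(cmb))) {
      a <- cmb[1L, p]; b <- cmb[2L, p]
      if (!within_genome &&
          identical(unname(gene2genome[a]), unname(gene2genome[b]))) next
      kk <- kaks_pair(cds[[a]], cds[[b]],
                      if (is.null(proteins)) NULL else proteins[[a]],
                      if (is.null(proteins)) NULL else proteins[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og, gene_a = a, gene_b = b,
        S = kk$S, N = kk$N, Sd = kk$Sd, Nd = kk$Nd,
        Ka = kk$Ka, Ks = kk$Ks, ratio = kk$ratio, status = kk$status,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(og_id = character(), gene_a = character(),
               gene_b = character(), S = numeric(), N = numeric(),
               Sd = numeric(), Nd = numeric(), Ka = numeric(),
               Ks = numeric(), ratio = numeric(), status = character(),
               stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(pairs, pairs$og_id), function(d) {
    def <- d$ratio[!is.na(d$ratio)]
    data.frame(og_id = d$og_id[[1L]], n_pairs = nrow(d),
               median_ratio = if (length(def)) stats::median(def) else NA_real_,
               frac_gt1 = if (length(def)) mean(def > 1) else NA_real_,
               any_positive = any(def > 1),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}
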