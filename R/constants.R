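# Internal constant tables: genetic code, amino-acid physicochemistry,
# IUPAC nucleotide codes. All published reference values; sources noted inline.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ExPASy average residue masses (Da); protein MW = sum(residues) + one water.
.AA_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
.WATER_MASS <- 18.01528

# Kyte & Doolittle (1982) hydropathy.
.AA_KD <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3)

# EMBOSS pKa set used for isoelectric-point bisection.
.PKA <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (rows: first residue, cols: second residue).
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.AA20, .AA20))

# Standard nuclear genetic code, codon -> one-letter amino acid ("*" = stop).
.NUC <- c("T", "C", "A", "G")
.CODONS <- as.vector(outer(outer(.NUC, .NUC, paste0), .NUC,
                           function(ab, c) paste0(ab, c)))
.GENETIC_CODE <- local({
  aa <- Biostrings::GENETIC_CODE
  code <- as.character(aa[.CODONS])
  names(code) <- .CODONS
  code
})
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]

# IUPAC nucleotide ambiguity codes; N deliberately matches nothing when it
# appears in a scanned sequence (handled at scan time, see regulatory.R).
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D")

#' Reverse-complement a nucleotide string
#'
#' Handles the full IUPAC alphabet; case-insensitive, returns upper case.
#'
#' @param x a single nucleotide string.
#' @return the reverse complement of `x`.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- rev(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(unique(chars), names(.COMPLEMENT))
  if (length(bad))
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "))
  paste(.COMPLEMENT[chars], collapse = "")
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code. Length must be a multiple of 3; codons
#' containing characters outside ACGT translate to "X".
#'
#' @param cds a single nucleotide string, length divisible by 3.
#' @return a single amino-acid string; stop codons become `"*"`.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
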