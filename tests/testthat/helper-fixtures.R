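# Hand-built miniature fixtures, written to tempfiles at test time.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A two-contig genome with three genes:
#   gA: + strand, single CDS chr1:3000-3011
#   gB: - strand, two CDS segments (5'->3' = 200-298 then 100-150) on chr1
#   gC: + strand near the contig start of chr2 (upstream truncation)
tiny_genome <- function() {
  set.seed(99)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  chr2 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  # plant gA CDS: ATG AAA TGG TAA at 3000..3011 (+)
  substring(chr1, 3000, 3011) <- "ATGAAATGGTAA"
  # plant gB CDS on minus strand, segments 200..298 and 100..150 (genomic)
  # transcript = revcomp(seg 200..298) + revcomp(seg 100..150), 150 nt
  body <- paste(c("ATG", replicate(48, sample(setdiff(panfam:::.SENSE_CODONS,
                                                      "ATG"), 1))),
                collapse = "")
  tx <- paste0(body, "TAA")  # 150 nt
  substring(chr1, 200, 298) <- panfam:::revcomp(substring(tx, 1, 99))
  substring(chr1, 100, 150) <- panfam:::revcomp(substring(tx, 100, 150))
  # plant gC CDS at chr2:500-511 (+): upstream only 499 bp
  substring(chr2, 500, 511) <- "ATGCCCGGGTAA"
  fa <- write_tmp(c(">chr1", chr1, ">chr2", chr2), ".fa")
  gff <- write_tmp(c(
    "##gff-version 3",
    "chr1\tx\tgene\t3000\t3011\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t3000\t3011\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tx\tCDS\t3000\t3011\t.\t+\t0\tParent=gA.t1",
    "chr1\tx\tgene\t100\t298\t.\t-\t.\tID=gB",
    "chr1\tx\tmRNA\t100\t298\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tx\tCDS\t200\t298\t.\t-\t0\tParent=gB.t1",
    "chr1\tx\tCDS\t100\t150\t.\t-\t0\tParent=gB.t1",
    "chr2\tx\tgene\t500\t511\t.\t+\t.\tID=gC",
    "chr2\tx\tmRNA\t500\t511\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr2\tx\tCDS\t500\t511\t.\t+\t0\tParent=gC.t1"), ".gff3")
  list(fa = fa, gff = gff, tx_gB = tx)
}

# domtblout line in the 23-column dialect the reader expects
domtbl_line <- function(gene, domain = "Dirigent", evalue = 1e-10) {
  sprintf(paste0("%s - 150 %s PF00000.0 100 %g 120.5 0.1 1 1 %g %g",
                 " 118.2 0.1 1 100 10 60 10 60 0.95 -"),
          gene, domain, evalue, evalue / 10, evalue)
}

# orthogroup set from a plain list of gene-id vectors (+ singletons)
ogset_of <- function(groups, singletons = character()) {
  names(groups) <- sprintf("OG%03d", seq_along(groups))
  structure(list(ogs = groups, singletons = singletons),
            class = "orthogroup_set")
}

random_protein <- function(n) {
  paste(sample(panfam:::.AA20, n, TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  paste(sample(panfam:::.SENSE_CODONS, n_codons, TRUE), collapse = "")
}
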