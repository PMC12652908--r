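# Independent brute-force oracles. These deliberately re-derive every
# quantity with explicit loops/enumeration and share no code with the
# package implementation paths they check.

GC_ORACLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_ORACLE) <- names(Biostrings::GENETIC_CODE)

# -- NG86 oracle: explicit site fractions and exhaustive pathway
#    enumeration for one ungapped codon pair --------------------------
oracle_ng86_pair <- function(c1, c2) {
  nucs <- c("A", "C", "G", "T")
  aa <- function(codon) GC_ORACLE[[codon]]
  syn_sites <- function(codon) {
    total <- 0
    for (pos in 1:3) {
      syn <- 0; nonstop <- 0
      for (nt in nucs) {
        if (nt == substr(codon, pos, pos)) next
        alt <- codon
        substr(alt, pos, pos) <- nt
        if (aa(alt) == "*") next
        nonstop <- nonstop + 1
        if (aa(alt) == aa(codon)) syn <- syn + 1
      }
      if (nonstop > 0) total <- total + syn / nonstop
    }
    total
  }
  # exhaustive path enumeration by recursion
  paths <- function(cur, target) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dp)) return(list(list(sd = 0, nd = 0, stop = FALSE)))
    out <- list()
    for (pos in dp) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      step_syn <- aa(cur) == aa(nxt)
      hit_stop <- aa(nxt) == "*" && nxt != target
      for (rest in paths(nxt, target)) {
        out[[length(out) + 1]] <- list(
          sd = rest$sd + as.numeric(step_syn),
          nd = rest$nd + as.numeric(!step_syn),
          stop = hit_stop || rest$stop)
      }
    }
    out
  }
  pp <- paths(c1, c2)
  ok <- Filter(function(p) !p$stop, pp)
  if (!length(ok)) ok <- pp
  s1 <- syn_sites(c1); s2 <- syn_sites(c2)
  list(S = (s1 + s2) / 2, N = (3 - s1 + 3 - s2) / 2,
       Sd = mean(vapply(ok, `[[`, 0, "sd")),
       Nd = mean(vapply(ok, `[[`, 0, "nd")))
}

# -- union-find oracle for single-linkage subdivision ----------------
oracle_components <- function(members, idm, threshold) {
  parent <- seq_along(members)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(members)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && idm[members[i], members[j]] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(lapply(split(members, roots), sort))
}

# -- naive sliding-window IUPAC motif count (one strand) -------------
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_count_one_strand <- function(seq, motif) {
  L <- nchar(seq); m <- nchar(motif)
  if (m > L) return(0L)
  sc <- strsplit(seq, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  starts <- 1:(L - m + 1)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m))
    ok <- ok & sc[starts + j - 1] %in% IUPAC_ORACLE[[mc[j]]]
  sum(ok)
}

oracle_count_both <- function(seq, motif) {
  rc <- paste(rev(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                         strsplit(motif, "")[[1]])), collapse = "")
  oracle_count_one_strand(seq, motif) + oracle_count_one_strand(seq, rc)
}

# -- direct-loop protein property recomputation ----------------------
oracle_physchem <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  mass <- 0; grav <- 0
  for (a in aas) {
    mass <- mass + panfam:::.AA_MASS[[a]]
    grav <- grav + panfam:::.AA_KD[[a]]
  }
  inst <- 0
  if (length(aas) >= 2)
    for (i in 1:(length(aas) - 1))
      inst <- inst + panfam:::.DIWV[aas[i], aas[i + 1]]
  list(mw_kda = (mass + 18.01528) / 1000,
       gravy = grav / length(aas),
       instability = if (length(aas) < 2) 0 else 10 * inst / length(aas))
}
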