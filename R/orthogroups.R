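# Orthogroup refinement: pairwise global protein identity, subdivision of
# heterogeneous orthogroups at an identity threshold (single linkage), the
# >=2-member rule, and a de novo clustering fallback for when no external
# orthogroup assignment is supplied.

#' Percent identity of two proteins under global alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap open 10, gap extend
#' 0.5. Identity = 100 x identical columns / alignment length; gap columns
#' count in the denominator. The argument order is canonicalised (the
#' lexicographically smaller sequence is the alignment pattern) so that
#' tie-broken traceback gives `identity(a, b) == identity(b, a)` exactly.
#'
#' @param a,b amino-acid strings.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' All-pairs identity matrix for a set of proteins
#'
#' @param proteins named character vector of protein sequences.
#' @return symmetric matrix of percent identities; diagonal is 100.
#' @export
identity_matrix <- function(proteins) {
  n <- length(proteins)
  ids <- names(proteins)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  if (any(!nzchar(proteins))) stop("empty protein sequence")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  set <- Biostrings::AAStringSet(proteins)
  lens <- nchar(proteins)
  # one vectorised alignment call per subject keeps the DP loops in C and
  # preserves the canonical orientation of pairwise_identity() (pattern =
  # lexicographically smaller sequence); alignment length with gap columns
  # is L_a + L_b - aligned pairs. Identical sequences are trivially 100.
  for (j in seq_len(n)) {
    eq <- which(proteins == proteins[[j]])
    m[eq, j] <- m[j, eq] <- 100
    pat <- which(proteins < proteins[[j]])
    if (!length(pat)) next
    al <- Biostrings::pairwiseAlignment(
      set[pat], set[[j]],
      substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global")
    nm <- Biostrings::nmatch(al)
    alnlen <- lens[pat] + lens[j] - (nm + Biostrings::nmismatch(al))
    idy <- 100 * nm / alnlen
    m[pat, j] <- m[j, pat] <- idy
  }
  m
}

.align_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.align_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$blosum62 <- e$BLOSUM62
  }
  .align_cache$blosum62
}

.components_at <- function(members, idm, threshold) {
  if (length(members) == 1L) return(list(members))
  sub <- idm[members, members, drop = FALSE]
  adj <- sub >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic order: by smallest member id within each component
  split_members <- unname(split(members, comp))
  split_members[order(vapply(split_members, min, ""))]
}

#' Subdivide one orthogroup at an identity threshold
#'
#' Builds the graph with an edge where identity >= threshold; connected
#' components (single linkage) become sub-orthogroups; size-1 components
#' become singletons.
#'
#' @param members character vector of gene ids.
#' @param idm identity matrix covering all members ([identity_matrix()]).
#' @param threshold percent-identity threshold (default 90).
#' @return list with `groups` (list of character vectors, each >= 2 genes)
#'   and `singletons`.
#' @export
subdivide_og <- function(members, idm, threshold = 90) {
  stopifnot(all(members %in% rownames(idm)))
  comps <- .components_at(members, idm, threshold)
  keep <- lengths(comps) >= 2L
  list(groups = lapply(comps[keep], sort),
       singletons = sort(unlist(comps[!keep], use.names = FALSE)))
}

.make_ogset <- function(groups, singletons) {
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, ""))]
  names(groups) <- sprintf("OG%03d", seq_along(groups))
  structure(list(ogs = groups,
                 singletons = sort(unique(singletons))),
            class = "orthogroup_set")
}

#' Refine an external orthogroup assignment
#'
#' Applies [subdivide_og()] to every input orthogroup, then the >=2-member
#' rule; resulting groups are renumbered by descending size. Genes absent
#' from `proteins` are dropped with a warning.
#'
#' @param raw_ogs named list of gene-id vectors (e.g.
#'   [read_orthogroups_tsv()]).
#' @param proteins named character vector of protein sequences.
#' @param threshold percent-identity threshold (default 90).
#' @return an `orthogroup_set`: list with `ogs` (named list, every group
#'   >= 2 members) and `singletons`.
#' @export
refine_orthogroups <- function(raw_ogs, proteins, threshold = 90) {
  known <- names(proteins)
  groups <- list(); singles <- character()
  for (og in raw_ogs) {
    og <- unique(og)
    missing <- setdiff(og, known)
    if (length(missing)) {
      warning("dropping ", length(missing), " gene(s) without protein sequence")
      og <- intersect(og, known)
    }
    if (!length(og)) next
    if (length(og) == 1L) { singles <- c(singles, og); next }
    idm <- identity_matrix(proteins[og])
    sub <- subdivide_og(og, idm, threshold)
    groups <- c(groups, sub$groups)
    singles <- c(singles, sub$singletons)
  }
  .make_ogset(groups, singles)
}

#' De novo orthogroup clustering by identity
#'
#' Single-linkage connected components over the >= threshold identity graph
#' on all proteins, then the >=2-member rule. A fallback for when no
#' external orthogroup assignment is available; not equivalent to
#' MCL-based orthology inference.
#'
#' @param proteins named character vector of protein sequences.
#' @param threshold percent-identity threshold (default 90).
#' @param idm optional precomputed identity matrix.
#' @return an `orthogroup_set`.
#' @export
cluster_denovo <- function(proteins, threshold = 90, idm = NULL) {
  if (!length(proteins)) return(.make_ogset(list(), character()))
  if (is.null(idm)) idm <- identity_matrix(proteins)
  sub <- subdivide_og(names(proteins), idm, threshold)
  .make_ogset(sub$groups, sub$singletons)
}

#' @export
print.orthogroup_set <- function(x, ...) {
  sz <- lengths(x$ogs)
  cat("orthogroup set:", length(x$ogs), "orthogroups (",
      sum(sz), "genes ), ", length(x$singletons), "singletons\n")
  if (length(sz)) cat("  sizes:", min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' Flatten an orthogroup set to a table
#'
#' @param ogset an `orthogroup_set`.
#' @return data frame with gene_id and og_id ("singleton" for singletons).
#' @export
ogset_table <- function(ogset) {
  tab <- data.frame(
    gene_id = c(unlist(ogset$ogs, use.names = FALSE), ogset$singletons),
    og_id = c(rep(names(ogset$ogs), lengths(ogset$ogs)),
              rep("singleton", length(ogset$singletons))),
    stringsAsFactors = FALSE)
  tab[order(tab$og_id, tab$gene_id), , drop = FALSE]
}

#' Rebuild an orthogroup set from [ogset_table()] output
#'
#' @param tab data frame with gene_id and og_id columns.
#' @return an `orthogroup_set`.
#' @export
ogset_from_table <- function(tab) {
  singles <- tab$gene_id[tab$og_id == "singleton"]
  rest <- tab[tab$og_id != "singleton", , drop = FALSE]
  groups <- split(rest$gene_id, rest$og_id)
  structure(list(ogs = lapply(groups[order(names(groups))], sort),
                 singletons = sort(singles)),
            class = "orthogroup_set")
}
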