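## Origin of newly gained tRNA genes. Most recent gain events (MRGEs) are
## gain events with no further gain of the same species below them; the
## genes descending from an MRGE are compared against the database of all
## tRNA genes with a local aligner, hits are kept when they reach 80% of
## the query's self-alignment score, and each query's best vertical and
## best non-vertical hits are classified into the mechanisms that can
## explain the similarity: HGT of the same species, HGT followed by an
## anticodon mutation, an anticodon mutation of a close ortholog, or gene
## duplication followed by an anticodon mutation.

.tips_below <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  desc <- ape::extract.clade(tree, node)$tip.label
  desc
}

.descendant_nodes <- function(tree, node) {
  ## all nodes strictly below `node`
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(integer(0))
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    ch <- edge[edge[, 1] == cur, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > nTip])
  }
  out
}

#' Find most recent gain events (MRGEs)
#'
#' Gain events with no other called gain of the same species strictly below
#' them in the tree. Descendant organisms are the tips below the gain node
#' that retain the species.
#'
#' @param events event data.frame from [callEvents()].
#' @param tree rooted \code{phylo}.
#' @param x a [PresenceMatrix-class].
#' @return data.frame with \code{species}, \code{node}, \code{mrgeId} and a
#'   list-column \code{descendants} of organism ids.
#' @export
findMrges <- function(events, tree, x) {
  gains <- events[events$type == "gain", , drop = FALSE]
  m <- as.matrix(x)
  rows <- list()
  for (sp in unique(gains$species)) {
    nodes <- unique(gains$node[gains$species == sp])
    for (nd in nodes) {
      below <- .descendant_nodes(tree, nd)
      if (any(nodes %in% below)) next  # a more recent gain exists below
      tips <- .tips_below(tree, nd)
      keep <- tips[m[tips, sp] == 1]
      rows[[paste(sp, nd)]] <- data.frame(
        species = sp, node = nd, mrgeId = paste0(sp, "@", nd),
        stringsAsFactors = FALSE)
      rows[[paste(sp, nd)]]$descendants <- list(keep)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0), node = integer(0),
                      mrgeId = character(0))
  rownames(out) <- NULL
  out
}

.align_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -3, baseOnly = TRUE)
    cache
  }
})

#' Local alignment score of two tRNA gene sequences
#'
#' Smith-Waterman score under match +1, mismatch -3, gap open -5, gap
#' extend -2 (a gap of length L costs 5 + 2L). At typical tRNA gene length
#' (~76-90 nt) the 80%-of-self-score rule then tolerates 3-4 mismatches or
#' 1-2 short gaps. Sequences may be DNA or RNA; the score is symmetric.
#'
#' @param a,b nucleotide sequences (character).
#' @return alignment score (numeric).
#' @export
alignScore <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  A <- Biostrings::DNAString(chartr("Uu", "Tt", a))
  B <- Biostrings::DNAString(chartr("Uu", "Tt", b))
  Biostrings::pairwiseAlignment(A, B, type = "local",
                                substitutionMatrix = .align_submat(),
                                gapOpening = 5, gapExtension = 2,
                                scoreOnly = TRUE)
}

.align_scores_many <- function(query, subjects) {
  q <- Biostrings::DNAString(chartr("Uu", "Tt", query))
  subj <- Biostrings::DNAStringSet(chartr("Uu", "Tt", subjects))
  Biostrings::pairwiseAlignment(subj, q, type = "local",
                                substitutionMatrix = .align_submat(),
                                gapOpening = 5, gapExtension = 2,
                                scoreOnly = TRUE)
}

#' Assign each gene to the MRGE it descends from
#'
#' A gene is assigned the most recent MRGE of its species whose subtree
#' contains the gene's organism; genes of a species with no called gain
#' above their organism descend from the root stock and get the pseudo-id
#' \code{"root:<species>"}.
#'
#' @param genes gene table (\code{organism}, \code{geneId},
#'   \code{anticodon}, \code{sequence}).
#' @param mrges output of [findMrges()].
#' @param tree rooted \code{phylo}.
#' @return character vector of MRGE ids, named by gene id.
#' @export
geneMrgeAssignment <- function(genes, mrges, tree) {
  depth <- ape::node.depth.edgelength(tree)
  out <- stats::setNames(paste0("root:", genes$anticodon), genes$geneId)
  if (!nrow(mrges)) return(out)
  for (i in seq_len(nrow(mrges))) {
    tips <- .tips_below(tree, mrges$node[i])
    hit <- genes$anticodon == mrges$species[i] & genes$organism %in% tips
    if (!any(hit)) next
    ## keep the deepest (most recent) assignment per gene
    cur <- out[genes$geneId[hit]]
    curDepth <- ifelse(grepl("^root:", cur), -Inf,
                       depth[as.integer(sub(".*@", "", cur))])
    newDepth <- depth[mrges$node[i]]
    upd <- newDepth > curDepth
    out[genes$geneId[hit][upd]] <- mrges$mrgeId[i]
  }
  out
}

#' Classify a similarity hit
#'
#' Vertical inheritance when query and subject share the anticodon and
#' descend from the same MRGE; otherwise non-vertical with a scenario:
#' same anticodon, different MRGE: HGT of the species
#' (\code{hgt_same_anticodon}); different anticodon in the same organism:
#' duplication followed by anticodon mutation (\code{duplication_mutation});
#' different anticodon in distant organisms (patristic distance above the
#' 90th percentile of all pairwise tip distances): HGT followed by
#' anticodon mutation (\code{hgt_plus_mutation}); different anticodon in
#' close organisms: anticodon mutation of an ortholog
#' (\code{ortholog_mutation}).
#'
#' @param queryAnticodon,subjectAnticodon anticodons.
#' @param queryOrganism,subjectOrganism organism ids.
#' @param queryMrge,subjectMrge MRGE ids from [geneMrgeAssignment()].
#' @param tipDistance patristic distance between the organisms.
#' @param distantCutoff distance above which organisms count as distant.
#' @return list with \code{category} ("vertical"/"non_vertical") and
#'   \code{scenario}.
#' @export
classifyHit <- function(queryAnticodon, subjectAnticodon, queryOrganism,
                        subjectOrganism, queryMrge, subjectMrge,
                        tipDistance, distantCutoff) {
  sameAc <- queryAnticodon == subjectAnticodon
  if (sameAc && queryMrge == subjectMrge)
    return(list(category = "vertical", scenario = "vertical"))
  if (sameAc)
    return(list(category = "non_vertical", scenario = "hgt_same_anticodon"))
  if (queryOrganism == subjectOrganism)
    return(list(category = "non_vertical",
                scenario = "duplication_mutation"))
  if (is.na(tipDistance))
    return(list(category = "non_vertical", scenario = "unclassified"))
  if (tipDistance >= distantCutoff)
    return(list(category = "non_vertical", scenario = "hgt_plus_mutation"))
  list(category = "non_vertical", scenario = "ortholog_mutation")
}

#' Search similar tRNA genes for MRGE descendants
#'
#' Every gene descending from each MRGE is queried against the full gene
#' database (both strands). Hits scoring below \code{threshold} times the
#' query self-score are dropped; the best-scoring hit is retained per query
#' within the vertical and the non-vertical category (ties broken by
#' lexicographic subject gene id), and classified with [classifyHit()].
#'
#' @param mrges output of [findMrges()].
#' @param genes gene table (\code{organism}, \code{geneId},
#'   \code{anticodon}, \code{sequence}); rows with missing sequences are
#'   skipped with a warning when queried.
#' @param tree rooted \code{phylo}.
#' @param threshold fraction of the self-score (inclusive).
#' @param distantQuantile quantile of pairwise tip distances defining
#'   "distant" organisms.
#' @return data.frame of best hits per query and category: query/subject
#'   gene ids and organisms, anticodons, score, selfScore, category,
#'   scenario.
#' @export
searchSimilar <- function(mrges, genes, tree, threshold = 0.8,
                          distantQuantile = 0.9) {
  stopifnot(nrow(genes) > 0)
  assign <- geneMrgeAssignment(genes, mrges, tree)
  D <- ape::cophenetic.phylo(tree)
  cutoff <- stats::quantile(D[upper.tri(D)], distantQuantile)
  revc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("Uu", "Tt", s))))
  rows <- list()
  for (i in seq_len(nrow(mrges))) {
    descOrgs <- mrges$descendants[[i]]
    qIdx <- which(genes$organism %in% descOrgs &
                    genes$anticodon == mrges$species[i])
    for (qi in qIdx) {
      qseq <- genes$sequence[qi]
      if (is.na(qseq) || !nzchar(qseq)) {
        warning("descendant gene ", genes$geneId[qi],
                " has no sequence; skipped")
        next
      }
      self <- alignScore(qseq, qseq)
      subj <- genes[-qi, , drop = FALSE]
      sc <- pmax(.align_scores_many(qseq, subj$sequence),
                 .align_scores_many(revc(qseq), subj$sequence))
      keep <- sc >= threshold * self
      if (!any(keep)) next
      hits <- subj[keep, , drop = FALSE]
      hits$score <- sc[keep]
      hits$vertical <- hits$anticodon == genes$anticodon[qi] &
        assign[hits$geneId] == assign[genes$geneId[qi]]
      for (cat in c(TRUE, FALSE)) {
        hc <- hits[hits$vertical == cat, , drop = FALSE]
        if (!nrow(hc)) next
        hc <- hc[order(-hc$score, hc$geneId), , drop = FALSE]
        best <- hc[1, ]
        cl <- classifyHit(genes$anticodon[qi], best$anticodon,
                          genes$organism[qi], best$organism,
                          assign[genes$geneId[qi]], assign[best$geneId],
                          D[genes$organism[qi], best$organism], cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          mrgeId = mrges$mrgeId[i],
          queryGene = genes$geneId[qi], queryOrganism = genes$organism[qi],
          queryAnticodon = genes$anticodon[qi],
          subjectGene = best$geneId, subjectOrganism = best$organism,
          subjectAnticodon = best$anticodon,
          score = best$score, selfScore = self,
          category = cl$category, scenario = cl$scenario,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mrgeId = character(0), queryGene = character(0),
                      queryOrganism = character(0),
                      queryAnticodon = character(0),
                      subjectGene = character(0),
                      subjectOrganism = character(0),
                      subjectAnticodon = character(0),
                      score = numeric(0), selfScore = numeric(0),
                      category = character(0), scenario = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flanking-sequence support for duplication calls
#'
#' Position-wise identity fraction of the upstream and downstream flanks of
#' two genes; high upstream/downstream identity supports a duplication
#' origin. Flanks are compared over their common length.
#'
#' @param upA,upB upstream flanks (character; NA allowed).
#' @param downA,downB downstream flanks.
#' @return list with \code{upstream} and \code{downstream} identity
#'   fractions (NA when a flank is unavailable).
#' @export
flankingSupport <- function(upA, upB, downA, downB) {
  ident <- function(x, y) {
    if (is.na(x) || is.na(y) || !nzchar(x) || !nzchar(y))
      return(NA_real_)
    n <- min(nchar(x), nchar(y))
    a <- strsplit(toupper(substr(x, nchar(x) - n + 1, nchar(x))), "")[[1]]
    b <- strsplit(toupper(substr(y, nchar(y) - n + 1, nchar(y))), "")[[1]]
    mean(a == b)
  }
  identDown <- function(x, y) {
    if (is.na(x) || is.na(y) || !nzchar(x) || !nzchar(y))
      return(NA_real_)
    n <- min(nchar(x), nchar(y))
    a <- strsplit(toupper(substr(x, 1, n)), "")[[1]]
    b <- strsplit(toupper(substr(y, 1, n)), "")[[1]]
    mean(a == b)
  }
  list(upstream = ident(upA, upB), downstream = identDown(downA, downB))
}
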