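## Operon co-occurrence analysis: do co-gained (co-lost) tRNA pairs sit in
## shared operons in the organisms descending from (neighbouring) the
## event, compared to the background of all other organisms?

#' Read an operon map
#'
#' TSV with columns \code{organism}, \code{operon_id}, \code{gene_id}.
#' @param path file path.
#' @return data.frame with \code{organism}, \code{operonId}, \code{geneId}.
#' @export
readOperonMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("organism", "operon_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("operon TSV needs columns: ", paste(need, collapse = ", "))
  data.frame(organism = df$organism, operonId = df$operon_id,
             geneId = df$gene_id, stringsAsFactors = FALSE)
}

## organism-level counts used by both co-gain and co-loss tables: for a set
## of organisms, how many carry both species, how many of those have operon
## data for both, and how many have >= 1 operon containing >= 1 gene of each
.operon_triple <- function(orgs, pair, m, operons, genes) {
  if (!length(orgs)) return(c(both = 0L, withData = 0L, shared = 0L))
  both <- orgs[m[orgs, pair[1]] == 1 & m[orgs, pair[2]] == 1]
  withData <- 0L; shared <- 0L
  for (o in both) {
    gA <- genes$geneId[genes$organism == o & genes$anticodon == pair[1]]
    gB <- genes$geneId[genes$organism == o & genes$anticodon == pair[2]]
    opA <- operons$operonId[operons$organism == o & operons$geneId %in% gA]
    opB <- operons$operonId[operons$organism == o & operons$geneId %in% gB]
    if (length(opA) && length(opB)) {
      withData <- withData + 1L
      if (length(intersect(opA, opB))) shared <- shared + 1L
    }
  }
  c(both = length(both), withData = withData, shared = shared)
}

#' Operon co-occurrence in descendants of co-gain events
#'
#' Among the organisms descending from the pair's co-gain nodes: the number
#' carrying both species, the number of those with operon data for both,
#' and the number with at least one operon containing at least one gene of
#' each species; the same three counts over all other organisms give the
#' background.
#'
#' @param pair character vector of two species.
#' @param coGainNodes node ids where both species have called gains.
#' @param tree rooted \code{phylo}.
#' @param x a [PresenceMatrix-class].
#' @param operons operon map data.frame (see [readOperonMap()]).
#' @param genes tRNA gene table.
#' @return one-row data.frame: pair, nNodes, descendants (n), descBoth,
#'   descWithData, descShared, bgBoth, bgWithData, bgShared.
#' @export
cogainOperonCounts <- function(pair, coGainNodes, tree, x, operons,
                               genes) {
  m <- as.matrix(x)
  desc <- unique(unlist(lapply(coGainNodes, function(nd)
    .tips_below(tree, nd))))
  bg <- setdiff(rownames(m), desc)
  d <- .operon_triple(desc, pair, m, operons, genes)
  b <- .operon_triple(bg, pair, m, operons, genes)
  data.frame(speciesA = pair[1], speciesB = pair[2],
             nNodes = length(coGainNodes), nDescendants = length(desc),
             descBoth = d[["both"]], descWithData = d[["withData"]],
             descShared = d[["shared"]],
             bgBoth = b[["both"]], bgWithData = b[["withData"]],
             bgShared = b[["shared"]], stringsAsFactors = FALSE)
}

#' Operon co-occurrence in nearest neighbours of co-loss events
#'
#' Nearest neighbours of a co-loss event are the tips descending from the
#' parent of the co-loss branch but not from the co-loss branch itself
#' (they still carry the genes unless independently lost). Events at the
#' root have no parent and are skipped with a warning.
#'
#' @param pair character vector of two species.
#' @param coLossNodes node ids where both species have called losses.
#' @inheritParams cogainOperonCounts
#' @return one-row data.frame mirroring [cogainOperonCounts()].
#' @export
colossNeighborCounts <- function(pair, coLossNodes, tree, x, operons,
                                 genes) {
  m <- as.matrix(x)
  root <- length(tree$tip.label) + 1L
  edge <- tree$edge
  neigh <- character(0)
  used <- 0L
  for (nd in coLossNodes) {
    if (nd == root) {
      warning("co-loss at the root has no neighbours; skipped")
      next
    }
    parent <- edge[edge[, 2] == nd, 1]
    below <- .tips_below(tree, parent)
    neigh <- union(neigh, setdiff(below, .tips_below(tree, nd)))
    used <- used + 1L
  }
  bg <- setdiff(rownames(m), neigh)
  d <- .operon_triple(neigh, pair, m, operons, genes)
  b <- .operon_triple(bg, pair, m, operons, genes)
  data.frame(speciesA = pair[1], speciesB = pair[2],
             nNodes = used, nNeighbors = length(neigh),
             neighBoth = d[["both"]], neighWithData = d[["withData"]],
             neighShared = d[["shared"]],
             bgBoth = b[["both"]], bgWithData = b[["withData"]],
             bgShared = b[["shared"]], stringsAsFactors = FALSE)
}

#' Operon coverage of the tRNA gene complement
#'
#' Per organism: the fraction of tRNA genes with an operon annotation, and
#' the fraction of annotated tRNA genes sharing an operon with another
#' tRNA gene.
#'
#' @param operons operon map data.frame.
#' @param genes tRNA gene table.
#' @return data.frame with \code{organism}, \code{nGenes},
#'   \code{coverage}, \code{coOperonic}.
#' @export
operonCoverage <- function(operons, genes) {
  rows <- lapply(split(genes, genes$organism), function(g) {
    ann <- operons[operons$organism == g$organism[1] &
                     operons$geneId %in% g$geneId, , drop = FALSE]
    nGenes <- nrow(g)
    cov <- nrow(ann) / nGenes
    coop <- if (nrow(ann)) {
      shared <- table(ann$operonId)
      mean(shared[ann$operonId] >= 2)
    } else NA_real_
    data.frame(organism = g$organism[1], nGenes = nGenes,
               coverage = cov, coOperonic = coop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
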