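## Co-gain / co-loss analysis: distribution of events per node, permutation
## nulls that reassign each species' events to random branches, pairwise
## co-event tests, and sequential (ancestor-ordered) gain relationships.

.branch_ids <- function(tree) {
  stats::reorder(tree, "postorder")$edge[, 2]
}

#' Histogram of events per node
#'
#' For each node (branch) and event type, the number of distinct species
#' gaining (losing) there; summarized as a histogram of nodes by event
#' multiplicity.
#'
#' @param events event data.frame from [callEvents()].
#' @return list with \code{perNode} (data.frame node/type/count over nodes
#'   with >= 1 event) and \code{histogram} (list gain/loss: table of node
#'   counts by multiplicity).
#' @export
countMultiEventNodes <- function(events) {
  if (!nrow(events))
    return(list(perNode = data.frame(node = integer(0),
                                     type = character(0),
                                     count = integer(0)),
                histogram = list(gain = table(integer(0)),
                                 loss = table(integer(0)))))
  agg <- stats::aggregate(species ~ node + type, data = events,
                          FUN = function(s) length(unique(s)))
  names(agg)[3] <- "count"
  hist <- lapply(c(gain = "gain", loss = "loss"), function(ty)
    table(agg$count[agg$type == ty]))
  list(perNode = agg[order(agg$type, agg$node), ], histogram = hist)
}

.permute_once <- function(counts, branches, weights) {
  lapply(counts, function(k)
    sample(branches, k, replace = FALSE, prob = weights))
}

#' Randomize called events across branches
#'
#' Null scheme: per permutation, each species' gain (loss) events are
#' reassigned to branches uniformly at random without replacement,
#' preserving per-species event counts; gains and losses are permuted
#' independently. An optional branch-length-weighted variant draws branches
#' with probability proportional to length.
#'
#' @param events event data.frame from [callEvents()].
#' @param tree rooted \code{phylo}.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param weighted use branch-length-proportional sampling.
#' @return list with \code{scheme}, \code{nPerm}, \code{branchHitFreq}
#'   (per species x type: named frequency vector over branches),
#'   \code{multiNodeNull} (per type: nPerm-length counts of nodes carrying
#'   >= 2 events), and \code{observedMultiNodes} (same statistic observed).
#' @export
randomizeEvents <- function(events, tree, nPerm = 1000L, seed = 17L,
                            weighted = FALSE) {
  branches <- .branch_ids(tree)
  tr <- stats::reorder(tree, "postorder")
  weights <- if (weighted) tr$edge.length else NULL
  set.seed(seed)
  out <- list(scheme = if (weighted) "length-weighted" else "uniform",
              nPerm = as.integer(nPerm))
  for (ty in c("gain", "loss")) {
    ev <- events[events$type == ty, , drop = FALSE]
    counts <- vapply(split(ev$node, ev$species), length, integer(1))
    counts <- counts[counts > 0]
    if (any(counts > length(branches)))
      stop("species with more ", ty, " events than branches")
    obs <- sum(table(ev$node) >= 2)
    hits <- matrix(0, length(counts), length(branches),
                   dimnames = list(names(counts), as.character(branches)))
    multi <- integer(nPerm)
    for (p in seq_len(nPerm)) {
      placed <- .permute_once(counts, branches, weights)
      allNodes <- unlist(placed, use.names = FALSE)
      multi[p] <- sum(table(allNodes) >= 2)
      for (s in seq_along(placed))
        hits[s, as.character(placed[[s]])] <-
          hits[s, as.character(placed[[s]])] + 1
    }
    out$branchHitFreq[[ty]] <- hits / nPerm
    out$multiNodeNull[[ty]] <- multi
    out$observedMultiNodes[[ty]] <- obs
  }
  out
}

#' Permutation test of co-gain (or co-loss) for one species pair
#'
#' Observed statistic: the number of nodes where both species have a called
#' event of the given type. The null reassigns each species' events to
#' branches uniformly at random (independently, preserving counts); the
#' p-value uses the add-one estimator p = (1 + #{null >= observed}) /
#' (1 + nPerm), so an overlap never reproduced in 1e4 permutations reports
#' p < 1e-4.
#'
#' @param events event data.frame from [callEvents()].
#' @param tree rooted \code{phylo}.
#' @param pair character vector of two species.
#' @param type "gain" or "loss".
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param weighted branch-length-weighted null variant.
#' @return list (CoEventStats): \code{speciesA}, \code{speciesB},
#'   \code{type}, \code{observed}, \code{nullMean}, \code{nullQ95},
#'   \code{p}, \code{nGreater} and \code{nEqual} (tail counts of the null,
#'   from which a randomized p-value -- exactly uniform under the null for
#'   this discrete statistic -- can be formed), \code{nPerm},
#'   \code{scheme}; p = NA when either species has no event of the type.
#' @export
pairCoeventTest <- function(events, tree, pair, type = "gain",
                            nPerm = 10000L, seed = 17L, weighted = FALSE) {
  stopifnot(length(pair) == 2, type %in% c("gain", "loss"))
  branches <- .branch_ids(tree)
  tr <- stats::reorder(tree, "postorder")
  weights <- if (weighted) tr$edge.length else NULL
  evA <- unique(events$node[events$species == pair[1] &
                              events$type == type])
  evB <- unique(events$node[events$species == pair[2] &
                              events$type == type])
  if (!length(evA) || !length(evB))
    return(list(speciesA = pair[1], speciesB = pair[2], type = type,
                observed = NA_integer_, nullMean = NA_real_,
                nullQ95 = NA_real_, p = NA_real_,
                nPerm = as.integer(nPerm),
                scheme = if (weighted) "length-weighted" else "uniform"))
  obs <- length(intersect(evA, evB))
  kA <- length(evA); kB <- length(evB)
  set.seed(seed)
  nullCounts <- vapply(seq_len(nPerm), function(p) {
    a <- sample(branches, kA, prob = weights)
    b <- sample(branches, kB, prob = weights)
    length(intersect(a, b))
  }, integer(1))
  list(speciesA = pair[1], speciesB = pair[2], type = type,
       observed = obs, nullMean = mean(nullCounts),
       nullQ95 = unname(stats::quantile(nullCounts, 0.95, type = 1)),
       p = (1 + sum(nullCounts >= obs)) / (1 + nPerm),
       nGreater = sum(nullCounts > obs),
       nEqual = sum(nullCounts == obs),
       nPerm = as.integer(nPerm),
       scheme = if (weighted) "length-weighted" else "uniform")
}

#' Co-event tests for all species pairs
#'
#' @inheritParams pairCoeventTest
#' @return data.frame with one row per unordered pair and type.
#' @export
allPairCoeventTests <- function(events, tree, type = "gain",
                                nPerm = 10000L, seed = 17L,
                                weighted = FALSE) {
  sp <- sort(unique(events$species[events$type == type]))
  if (length(sp) < 2)
    return(data.frame())
  rows <- list()
  idx <- 0L
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) {
      idx <- idx + 1L
      r <- pairCoeventTest(events, tree, c(sp[i], sp[j]), type,
                           nPerm = nPerm, seed = seed + idx,
                           weighted = weighted)
      rows[[idx]] <- as.data.frame(r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## node -> set of ancestor nodes (excluding the node itself)
.ancestor_sets <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  nN <- length(tr$tip.label) + tr$Nnode
  parent <- integer(nN)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- length(tr$tip.label) + 1L
  anc <- vector("list", nN)
  ## preorder: parents before children
  for (k in rev(seq_len(nrow(tr$edge)))) {
    ch <- tr$edge[k, 2]; pa <- tr$edge[k, 1]
    anc[[ch]] <- c(anc[[pa]], pa)
  }
  anc[[root]] <- integer(0)
  anc
}

#' Sequential gain-order counts
#'
#' For each ordered species pair (X, Y), the number of event pairs where a
#' gain of X lies strictly ancestral to a gain of Y on one root-to-tip
#' path. Reported descriptively.
#'
#' @param events event data.frame from [callEvents()].
#' @param tree rooted \code{phylo}.
#' @return data.frame with \code{speciesFirst}, \code{speciesSecond},
#'   \code{count} for pairs with count > 0 (plus all-zero pairs omitted).
#' @export
sequentialOrder <- function(events, tree) {
  gains <- events[events$type == "gain", , drop = FALSE]
  sp <- sort(unique(gains$species))
  anc <- .ancestor_sets(tree)
  rows <- list()
  for (X in sp) for (Y in sp) {
    if (X == Y) next
    nX <- unique(gains$node[gains$species == X])
    nY <- unique(gains$node[gains$species == Y])
    cnt <- sum(vapply(nY, function(y)
      sum(nX %in% anc[[y]]), integer(1)))
    rows[[paste(X, Y)]] <- data.frame(speciesFirst = X, speciesSecond = Y,
                                      count = cnt,
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(speciesFirst = character(0),
                      speciesSecond = character(0), count = integer(0)))
  rownames(out) <- NULL
  out
}
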