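## Shared fixtures and independent oracles used across test files. The
## oracles re-derive expected values by brute force or direct formula
## evaluation, independently of the package's implementation paths.

## exhaustive two-state likelihood: sum over every internal-state
## assignment of the product of root prior and per-branch transition
## probabilities
enum_loglik <- function(tree, tipStates, gain, loss, prior) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nT <- length(tree$tip.label)
  nN <- nT + tree$Nnode
  P <- lapply(tree$edge.length, function(t) {
    s <- gain + loss
    e <- exp(-s * t)
    matrix(c(1 - gain / s * (1 - e), loss / s * (1 - e),
             gain / s * (1 - e), 1 - loss / s * (1 - e)), 2, 2)
  })
  internals <- (nT + 1):nN
  total <- 0
  for (cfg in 0:(2^length(internals) - 1)) {
    st <- integer(nN)
    st[seq_len(nT)] <- tipStates
    st[internals] <- as.integer(intToBits(cfg)[seq_along(internals)])
    pr <- prior[st[nT + 1] + 1]
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * P[[k]][st[tree$edge[k, 1]] + 1, st[tree$edge[k, 2]] + 1]
    total <- total + pr
  }
  log(total)
}

## exhaustive marginal posteriors P(state = 1) for every node
enum_posteriors <- function(tree, tipStates, gain, loss, prior) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nT <- length(tree$tip.label)
  nN <- nT + tree$Nnode
  P <- lapply(tree$edge.length, function(t) {
    s <- gain + loss
    e <- exp(-s * t)
    matrix(c(1 - gain / s * (1 - e), loss / s * (1 - e),
             gain / s * (1 - e), 1 - loss / s * (1 - e)), 2, 2)
  })
  internals <- (nT + 1):nN
  marg <- numeric(nN)
  total <- 0
  for (cfg in 0:(2^length(internals) - 1)) {
    st <- integer(nN)
    st[seq_len(nT)] <- tipStates
    st[internals] <- as.integer(intToBits(cfg)[seq_along(internals)])
    pr <- prior[st[nT + 1] + 1]
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * P[[k]][st[tree$edge[k, 1]] + 1, st[tree$edge[k, 2]] + 1]
    total <- total + pr
    marg <- marg + pr * st
  }
  marg / total
}

## root-to-tip shared path length by explicit path enumeration
pathsum_vcv <- function(tree) {
  nT <- length(tree$tip.label)
  root <- nT + 1L
  parent <- integer(nT + tree$Nnode)
  elen <- numeric(nT + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  pathOf <- function(tip) {
    nodes <- integer(0)
    cur <- tip
    while (cur != root) {
      nodes <- c(nodes, cur)
      cur <- parent[cur]
    }
    nodes
  }
  V <- matrix(0, nT, nT, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(nT), pathOf)
  for (i in seq_len(nT)) for (j in seq_len(nT)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(elen[shared])
  }
  V
}

## straight-from-formula Wright ENC on a codon count vector, coded
## independently of the package (classic 2/9-1-5-3 layout)
oracle_enc <- function(counts) {
  sc <- senseCodons()
  fams <- split(sc$codon, sc$aminoAcid)
  F <- sapply(fams, function(cod) {
    x <- counts[cod]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  m <- sapply(fams, length)
  fbar <- sapply(c(2, 3, 4, 6), function(k) mean(F[m == k], na.rm = TRUE))
  min(61, 2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4])
}

## gene whose codon usage equals the expectation from a given base
## composition (expected counts, rounded)
expectation_gene <- function(freqs, nCodons = 10000) {
  sc <- senseCodons()
  pr <- freqs[substr(sc$codon, 1, 1)] * freqs[substr(sc$codon, 2, 2)] *
    freqs[substr(sc$codon, 3, 3)]
  pr <- pr / sum(pr)
  paste(rep(sc$codon, round(pr * nCodons)), collapse = "")
}

## small deterministic gene table for repertoire tests
toy_gene_table <- function() {
  data.frame(
    organism = c("O1", "O1", "O2", "O2", "O2"),
    geneId = paste0("g", 1:5),
    anticodon = c("GAA", "GAA", "GAA", "CAU", "UUC"),
    sequence = NA_character_,
    stringsAsFactors = FALSE
  )
}

## random n-substitution mutant. The sequence ends are protected by
## default: a terminal mismatch would be trimmed by local alignment,
## breaking the exact score arithmetic the tests assert.
mutate_n <- function(seq, n, protect = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(protect))
    protect <- c(1:3, (length(ch) - 2):length(ch))
  pos <- sample(setdiff(seq_along(ch), protect), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
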