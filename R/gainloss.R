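## Two-state (absence/presence) continuous-time Markov model on the species
## phylogeny: likelihood by Felsenstein pruning, ML gain/loss rates,
## marginal ancestral posteriors, stochastic mapping by uniformization, and
## branch-event calling. States are coded 0 (absent) and 1 (present);
## branches are identified by their child node id (ape numbering: tips
## 1..n, root n+1).

#' TwoStateModel: gain/loss rates of one tRNA species
#'
#' @slot gainRate 0 -> 1 rate per unit branch length.
#' @slot lossRate 1 -> 0 rate per unit branch length.
#' @slot rootPrior probability vector over states (0, 1).
#' @slot gammaShape shape of an optional discrete-gamma distribution of
#'   branch-rate multipliers (length 0 disables rate variation).
#' @slot nCat number of discrete-gamma categories.
#' @export
setClass("TwoStateModel",
         representation(gainRate = "numeric", lossRate = "numeric",
                        rootPrior = "numeric", gammaShape = "numeric",
                        nCat = "integer"))

setValidity("TwoStateModel", function(object) {
  msg <- character(0)
  if (object@gainRate <= 0 || object@lossRate <= 0)
    msg <- c(msg, "rates must be positive")
  if (abs(sum(object@rootPrior) - 1) > 1e-9 || any(object@rootPrior < 0))
    msg <- c(msg, "rootPrior must be a probability vector over {0,1}")
  if (length(object@gammaShape) == 1 && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a two-state gain/loss model
#'
#' @param gainRate,lossRate positive rates per unit branch length.
#' @param rootPrior prior over states (0, 1) at the root; default is the
#'   stationary distribution \code{c(loss, gain) / (gain + loss)}.
#' @param gammaShape optional shape of discrete-gamma branch-rate
#'   multipliers (mean 1); \code{numeric(0)} disables rate variation.
#' @param nCat number of gamma categories.
#' @return a \code{TwoStateModel}.
#' @export
twoStateModel <- function(gainRate, lossRate, rootPrior = NULL,
                          gammaShape = numeric(0), nCat = 4L) {
  if (is.null(rootPrior))
    rootPrior <- c(lossRate, gainRate) / (gainRate + lossRate)
  methods::new("TwoStateModel", gainRate = gainRate, lossRate = lossRate,
               rootPrior = unname(rootPrior), gammaShape = gammaShape,
               nCat = as.integer(nCat))
}

setMethod("show", "TwoStateModel", function(object) {
  cat("TwoStateModel: gain =", signif(object@gainRate, 4),
      " loss =", signif(object@lossRate, 4),
      " root prior P(present) =", signif(object@rootPrior[2], 4), "\n")
  if (length(object@gammaShape))
    cat("  discrete-gamma rate variation: shape =",
        signif(object@gammaShape, 4), ",", object@nCat, "categories\n")
})

#' @export
setGeneric("gainRate", function(x) standardGeneric("gainRate"))
#' @describeIn twoStateModel gain rate accessor
#' @param x a TwoStateModel.
#' @export
setMethod("gainRate", "TwoStateModel", function(x) x@gainRate)

#' @export
setGeneric("lossRate", function(x) standardGeneric("lossRate"))
#' @describeIn twoStateModel loss rate accessor
#' @export
setMethod("lossRate", "TwoStateModel", function(x) x@lossRate)

#' @export
setGeneric("rootPrior", function(x) standardGeneric("rootPrior"))
#' @describeIn twoStateModel root prior accessor
#' @export
setMethod("rootPrior", "TwoStateModel", function(x) x@rootPrior)

.rate_multipliers <- function(model) {
  if (!length(model@gammaShape)) return(1)
  k <- model@nCat
  a <- model@gammaShape
  ## category means of the discrete gamma (equal-probability bins):
  ## E[X; X in bin] for X ~ Gamma(a, rate a) is the shape-(a+1) CDF
  ## increment, so the bin mean is k times that increment (exact)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = a, rate = a)
  mids <- k * diff(stats::pgamma(q, shape = a + 1, rate = a))
  mids / mean(mids)
}

#' Transition probability matrix of the two-state chain
#'
#' P01(t) = g/(g+l) (1 - exp(-(g+l) t)) and symmetrically for P10.
#'
#' @param model a \code{TwoStateModel} (or NULL if rates given).
#' @param t branch length >= 0.
#' @param gain,loss rates, overriding the model.
#' @return 2x2 stochastic matrix with dimnames over states ("0", "1").
#' @export
transitionMatrix <- function(model = NULL, t, gain = NULL, loss = NULL) {
  if (t < 0) stop("negative branch length")
  g <- if (is.null(gain)) model@gainRate else gain
  l <- if (is.null(loss)) model@lossRate else loss
  s <- g + l
  e <- exp(-s * t)
  P01 <- g / s * (1 - e)
  P10 <- l / s * (1 - e)
  matrix(c(1 - P01, P10, P01, 1 - P10), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

## Postorder tree bookkeeping shared by the pruning routines.
.tree_index <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(tree = tree, edge = tree$edge, len = tree$edge.length,
       nTip = length(tree$tip.label), root = length(tree$tip.label) + 1L,
       nNode = length(tree$tip.label) + tree$Nnode)
}

.check_tip_states <- function(tipStates, tree) {
  if (!is.null(names(tipStates))) {
    missing <- setdiff(tree$tip.label, names(tipStates))
    if (length(missing))
      stop("missing tip state for: ", paste(missing, collapse = ", "))
    tipStates <- tipStates[tree$tip.label]
  }
  stopifnot(length(tipStates) == length(tree$tip.label),
            all(tipStates %in% c(0, 1)))
  as.integer(tipStates)
}

## Per-branch transition probabilities, averaged over the (independent)
## discrete-gamma branch-rate multipliers: P-bar(t) = sum_k w_k P(m_k t).
.branch_probs <- function(model, len) {
  mult <- .rate_multipliers(model)
  g <- model@gainRate; l <- model@lossRate
  s <- g + l
  P01 <- rep(0, length(len)); P10 <- rep(0, length(len))
  for (m in mult) {
    e <- exp(-s * m * len)
    P01 <- P01 + g / s * (1 - e)
    P10 <- P10 + l / s * (1 - e)
  }
  list(P01 = P01 / length(mult), P10 = P10 / length(mult))
}

## Conditional (subtree) likelihoods given per-branch transition
## probabilities; returns the nNode x 2 matrix of scaled likelihoods and
## the log scaling factor per node (cumulative over the subtree).
.pruning_partials <- function(ti, tipStates, P01, P10) {
  L <- matrix(0, ti$nNode, 2)
  logScale <- numeric(ti$nNode)
  visited <- logical(ti$nNode)
  L[cbind(seq_len(ti$nTip), tipStates + 1L)] <- 1
  for (k in seq_len(nrow(ti$edge))) {
    par <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    m0 <- (1 - P01[k]) * L[ch, 1] + P01[k] * L[ch, 2]
    m1 <- P10[k] * L[ch, 1] + (1 - P10[k]) * L[ch, 2]
    if (!visited[par]) {
      L[par, ] <- c(m0, m1)
      visited[par] <- TRUE
    } else {
      L[par, ] <- L[par, ] * c(m0, m1)
    }
    logScale[par] <- logScale[par] + logScale[ch]
    tot <- L[par, 1] + L[par, 2]
    if (tot > 0 && (tot < 1e-12 || tot > 1e12)) {
      L[par, ] <- L[par, ] / tot
      logScale[par] <- logScale[par] + log(tot)
    }
  }
  list(L = L, logScale = logScale)
}

#' Log-likelihood of one species' tip states by Felsenstein pruning
#'
#' With discrete-gamma rate variation, each branch carries an independent
#' rate multiplier, which integrates out exactly to branch-averaged
#' transition probabilities.
#'
#' @param model a \code{TwoStateModel}.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param tipStates 0/1 vector named by tip label (or in tip order).
#' @return log-likelihood.
#' @export
pruningLoglik <- function(model, tree, tipStates) {
  ti <- .tree_index(tree)
  ts <- .check_tip_states(tipStates, ti$tree)
  bp <- .branch_probs(model, ti$len)
  pp <- .pruning_partials(ti, ts, bp$P01, bp$P10)
  lr <- sum(pp$L[ti$root, ] * model@rootPrior)
  log(lr) + pp$logScale[ti$root]
}

#' Fit ML gain/loss rates per species
#'
#' Bounded 2-D maximum-likelihood optimization (L-BFGS-B on log rates) of
#' the two-state model for each species column; constant columns are
#' unidentifiable and skipped with a flag.
#'
#' @param tree rooted \code{phylo}.
#' @param x a [PresenceMatrix-class] (or a named list of tip-state
#'   vectors).
#' @param gammaShape fixed discrete-gamma shape shared by all species
#'   (\code{numeric(0)} for rate homogeneity), or \code{"joint"} to
#'   estimate one shared shape by ML over all species jointly.
#' @param lower,upper rate bounds.
#' @return named list; each element is a \code{TwoStateModel}, or NA for a
#'   skipped (constant) species. When the shape is estimated jointly it is
#'   attached as attribute \code{"gammaShape"}.
#' @export
fitRates <- function(tree, x, gammaShape = numeric(0),
                     lower = 1e-6, upper = 1e3) {
  cols <- if (methods::is(x, "PresenceMatrix")) {
    m <- as.matrix(x)
    stats::setNames(lapply(seq_len(ncol(m)), function(j)
      stats::setNames(m[, j], rownames(m))), colnames(m))
  } else x
  if (length(tree$tip.label) < 20)
    warning("fewer than 20 tips: rate estimates will be imprecise")
  ti <- .tree_index(tree)
  fitOne <- function(ts, shape) {
    nll <- function(par) {
      mdl <- twoStateModel(exp(par[1]), exp(par[2]), gammaShape = shape)
      ll <- pruningLoglik(mdl, ti$tree, ts)
      if (!is.finite(ll)) 1e10 else -ll
    }
    p0 <- log(c(mean(ts == 1) + 0.1, mean(ts == 0) + 0.1))
    opt <- stats::optim(p0, nll, method = "L-BFGS-B",
                        lower = log(lower), upper = log(upper))
    list(model = twoStateModel(exp(opt$par[1]), exp(opt$par[2]),
                               gammaShape = shape),
         nll = opt$value)
  }
  states <- lapply(cols, function(y) .check_tip_states(y, ti$tree))
  variable <- vapply(states, function(ts) length(unique(ts)) > 1L,
                     logical(1))
  fitAll <- function(shape) {
    lapply(states[variable], fitOne, shape = shape)
  }
  sharedShape <- gammaShape
  if (identical(gammaShape, "joint")) {
    tot <- function(logShape) {
      sum(vapply(fitAll(exp(logShape)), `[[`, numeric(1), "nll"))
    }
    opt <- stats::optimize(tot, interval = log(c(0.05, 20)), tol = 0.05)
    sharedShape <- exp(opt$minimum)
    ## keep the shape only if rate variation improves the joint fit
    if (opt$objective >= sum(vapply(fitAll(numeric(0)), `[[`,
                                    numeric(1), "nll")))
      sharedShape <- numeric(0)
  }
  fits <- fitAll(sharedShape)
  out <- stats::setNames(rep(list(NA), length(cols)), names(cols))
  out[names(fits)] <- lapply(fits, `[[`, "model")
  attr(out, "gammaShape") <- sharedShape
  out
}

#' Marginal ancestral-state posteriors
#'
#' Up-down (outside) algorithm: posteriors P(state = 1) for every node,
#' consistent with the pruning likelihood; tip posteriors equal the
#' observed states.
#'
#' @inheritParams pruningLoglik
#' @return numeric vector of P(present) indexed by node id (1..nTip tips,
#'   then internal nodes).
#' @export
marginalPosteriors <- function(model, tree, tipStates) {
  ti <- .tree_index(tree)
  ts <- .check_tip_states(tipStates, ti$tree)
  bp <- .branch_probs(model, ti$len)
  P01 <- bp$P01; P10 <- bp$P10
  pp <- .pruning_partials(ti, ts, P01, P10)
  ## outside pass (preorder = reversed postorder edges)
  U <- matrix(0, ti$nNode, 2)
  U[ti$root, ] <- model@rootPrior
  children <- split(seq_len(nrow(ti$edge)), ti$edge[, 1])
  for (k in rev(seq_len(nrow(ti$edge)))) {
    par <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    sibs <- setdiff(children[[as.character(par)]], k)
    out <- U[par, ]
    for (sk in sibs) {
      sc <- ti$edge[sk, 2]
      m0 <- (1 - P01[sk]) * pp$L[sc, 1] + P01[sk] * pp$L[sc, 2]
      m1 <- P10[sk] * pp$L[sc, 1] + (1 - P10[sk]) * pp$L[sc, 2]
      out <- out * c(m0, m1)
    }
    U[ch, 1] <- out[1] * (1 - P01[k]) + out[2] * P10[k]
    U[ch, 2] <- out[1] * P01[k] + out[2] * (1 - P10[k])
    tot <- sum(U[ch, ])
    if (tot > 0) U[ch, ] <- U[ch, ] / tot
  }
  num <- U[, 2] * pp$L[, 2]
  den <- num + U[, 1] * pp$L[, 1]
  ifelse(den > 0, num / den, 0)
}

## Sample joint node states conditional on the tips, for nMaps maps at
## once, given per-branch transition probabilities. Returns an
## nNode x nMaps integer matrix.
.sample_node_states <- function(ti, pp, model, P01, P10, nMaps) {
  S <- matrix(NA_integer_, ti$nNode, nMaps)
  rootP <- model@rootPrior * pp$L[ti$root, ]
  rootP <- rootP / sum(rootP)
  S[ti$root, ] <- stats::rbinom(nMaps, 1, rootP[2])
  for (k in rev(seq_len(nrow(ti$edge)))) {
    par <- ti$edge[k, 1]; ch <- ti$edge[k, 2]
    sp <- S[par, ]
    ## P(child = 1 | parent, data below child)
    p1given0 <- P01[k] * pp$L[ch, 2] /
      ((1 - P01[k]) * pp$L[ch, 1] + P01[k] * pp$L[ch, 2])
    p1given1 <- (1 - P10[k]) * pp$L[ch, 2] /
      (P10[k] * pp$L[ch, 1] + (1 - P10[k]) * pp$L[ch, 2])
    p <- ifelse(sp == 1L, p1given1, p1given0)
    S[ch, ] <- stats::rbinom(nMaps, 1, p)
  }
  S
}

## Given endpoint states a, b (vectors over maps) on a branch of length t,
## sample whether >= 1 gain and >= 1 loss occurred, by uniformization at
## rate Lambda = g + l. With this Lambda the virtual-jump chain is rank one:
## each jump lands in state 1 with probability g / (g + l) independently,
## so conditioning on the endpoints only truncates the jump count.
.sample_branch_events <- function(a, b, t, g, l) {
  n <- length(a)
  lam <- (g + l) * t
  pi1 <- g / (g + l)
  gains <- logical(n); losses <- logical(n)
  if (lam == 0) return(list(gain = gains, loss = losses))
  ## number of virtual jumps k
  k <- integer(n)
  same <- a == b
  if (any(!same)) {
    ## k >= 1, truncated Poisson
    u <- stats::runif(sum(!same), stats::ppois(0, lam), 1)
    k[!same] <- stats::qpois(pmin(u, 1 - 1e-16), lam)
  }
  if (any(same)) {
    pb <- ifelse(b[same] == 1L, pi1, 1 - pi1)
    p0 <- exp(-lam)
    pk <- (1 - exp(-lam)) * pb
    isZero <- stats::runif(sum(same)) < p0 / (p0 + pk)
    idx <- which(same)
    nz <- idx[!isZero]
    if (length(nz)) {
      u <- stats::runif(length(nz), stats::ppois(0, lam), 1)
      k[nz] <- stats::qpois(pmin(u, 1 - 1e-16), lam)
    }
  }
  ## realized transitions along the jump sequence a, s1..s_{k-1}, b
  active <- which(k >= 1L)
  for (i in active) {
    ki <- k[i]
    states <- c(a[i],
                if (ki >= 2) stats::rbinom(ki - 1L, 1, pi1) else integer(0),
                b[i])
    d <- diff(states)
    gains[i] <- any(d == 1L)
    losses[i] <- any(d == -1L)
  }
  list(gain = gains, loss = losses)
}

#' Stochastic mapping of gain/loss events
#'
#' Samples joint character histories conditional on the tip states and
#' estimates, for every branch, the probability of at least one gain and
#' of at least one loss as the fraction of maps containing such an event.
#' Node states are sampled from their joint conditional distribution;
#' within a branch, the number and order of events is sampled by
#' uniformization. With discrete-gamma rate variation, each branch's rate
#' category is sampled conditional on its endpoint states.
#'
#' @inheritParams pruningLoglik
#' @param nMaps number of sampled histories (>= 100).
#' @param seed RNG seed for reproducibility.
#' @return list with \code{branchGain} and \code{branchLoss} (numeric,
#'   named by child node id) and \code{nMaps}.
#' @export
stochasticMap <- function(model, tree, tipStates, nMaps = 1000L,
                          seed = 17L) {
  stopifnot(nMaps >= 100)
  ti <- .tree_index(tree)
  ts <- .check_tip_states(tipStates, ti$tree)
  set.seed(seed)
  mult <- .rate_multipliers(model)
  bp <- .branch_probs(model, ti$len)
  pp <- .pruning_partials(ti, ts, bp$P01, bp$P10)
  S <- .sample_node_states(ti, pp, model, bp$P01, bp$P10, nMaps)
  nb <- nrow(ti$edge)
  gainHits <- matrix(FALSE, nb, nMaps)
  lossHits <- matrix(FALSE, nb, nMaps)
  g <- model@gainRate; l <- model@lossRate
  for (k in seq_len(nb)) {
    a <- S[ti$edge[k, 1], ]; b <- S[ti$edge[k, 2], ]
    if (length(mult) > 1) {
      ## per-branch category, conditional on the sampled endpoints:
      ## P(cat = c | a, b) proportional to P_c[a, b]
      Pk <- vapply(mult, function(m) {
        P <- transitionMatrix(t = ti$len[k] * m, gain = g, loss = l)
        c(P[1, 1], P[1, 2], P[2, 1], P[2, 2])
      }, numeric(4))
      combo <- 1L + 2L * a + b  # 00 -> 1, 01 -> 2, 10 -> 3, 11 -> 4
      catOf <- integer(nMaps)
      for (cb in unique(combo)) {
        idx <- which(combo == cb)
        w <- Pk[cb, ]
        catOf[idx] <- sample.int(length(mult), length(idx),
                                 replace = TRUE, prob = w)
      }
      for (ci in unique(catOf)) {
        idx <- which(catOf == ci)
        ev <- .sample_branch_events(a[idx], b[idx], ti$len[k] * mult[ci],
                                    g, l)
        gainHits[k, idx] <- ev$gain
        lossHits[k, idx] <- ev$loss
      }
    } else {
      ev <- .sample_branch_events(a, b, ti$len[k], g, l)
      gainHits[k, ] <- ev$gain
      lossHits[k, ] <- ev$loss
    }
  }
  childIds <- as.character(ti$edge[, 2])
  list(branchGain = stats::setNames(rowMeans(gainHits), childIds),
       branchLoss = stats::setNames(rowMeans(lossHits), childIds),
       nMaps = nMaps)
}

#' Reconstruction: ancestral posteriors and branch event probabilities
#'
#' @slot species tRNA species (anticodon).
#' @slot model the fitted \code{TwoStateModel}.
#' @slot nodePosterior P(present) per node id (tips hold observed states).
#' @slot branchGain,branchLoss P(>= 1 event) per branch, named by child
#'   node id.
#' @slot nMaps number of stochastic maps used.
#' @export
setClass("Reconstruction",
         representation(species = "character", model = "TwoStateModel",
                        nodePosterior = "numeric", branchGain = "numeric",
                        branchLoss = "numeric", nMaps = "integer"))

setValidity("Reconstruction", function(object) {
  p <- c(object@nodePosterior, object@branchGain, object@branchLoss)
  if (any(p < -1e-9 | p > 1 + 1e-9)) "probabilities must lie in [0,1]"
  else TRUE
})

setMethod("show", "Reconstruction", function(object) {
  cat("Reconstruction of", object@species, "\n")
  cat("  model: gain =", signif(object@model@gainRate, 4),
      " loss =", signif(object@model@lossRate, 4), "\n")
  cat("  branches with P(gain) >= 0.8:", sum(object@branchGain >= 0.8),
      "; P(loss) >= 0.8:", sum(object@branchLoss >= 0.8), "\n")
})

#' @export
setGeneric("nodePosterior", function(x) standardGeneric("nodePosterior"))
#' @describeIn Reconstruction node posteriors accessor
#' @param x a Reconstruction.
#' @export
setMethod("nodePosterior", "Reconstruction", function(x) x@nodePosterior)

#' @export
setGeneric("branchEvents", function(x) standardGeneric("branchEvents"))
#' @describeIn Reconstruction per-branch event probabilities as a
#'   data.frame (node = child node id)
#' @export
setMethod("branchEvents", "Reconstruction", function(x) {
  data.frame(node = as.integer(names(x@branchGain)),
             pGain = unname(x@branchGain), pLoss = unname(x@branchLoss),
             stringsAsFactors = FALSE)
})

#' Reconstruct the history of one species
#'
#' Convenience wrapper: fits rates (unless a model is supplied), computes
#' marginal posteriors and runs stochastic mapping.
#'
#' @param tree rooted \code{phylo}.
#' @param tipStates 0/1 tip states named by tip label.
#' @param species species label to store.
#' @param model optional prefitted \code{TwoStateModel}.
#' @param nMaps,seed passed to [stochasticMap()].
#' @return a [Reconstruction-class], or NA for a constant column.
#' @export
reconstructSpecies <- function(tree, tipStates, species = "species",
                               model = NULL, nMaps = 1000L, seed = 17L) {
  if (is.null(model)) {
    model <- fitRates(tree, stats::setNames(list(tipStates), species))[[1]]
    if (!methods::is(model, "TwoStateModel")) return(NA)
  }
  post <- marginalPosteriors(model, tree, tipStates)
  sm <- stochasticMap(model, tree, tipStates, nMaps = nMaps, seed = seed)
  methods::new("Reconstruction", species = species, model = model,
               nodePosterior = post, branchGain = sm$branchGain,
               branchLoss = sm$branchLoss, nMaps = as.integer(nMaps))
}

#' Reconstruct all species of a presence matrix
#'
#' @param tree rooted \code{phylo}.
#' @param x a [PresenceMatrix-class].
#' @param nMaps,seed passed to [stochasticMap()].
#' @param gammaShape shared gamma shape for [fitRates()] (a value,
#'   \code{numeric(0)}, or \code{"joint"}).
#' @return named list of [Reconstruction-class] (constant species are NA).
#' @export
reconstructAll <- function(tree, x, nMaps = 1000L, seed = 17L,
                           gammaShape = numeric(0)) {
  models <- fitRates(tree, x, gammaShape = gammaShape)
  m <- as.matrix(x)
  out <- lapply(colnames(m), function(sp) {
    if (!methods::is(models[[sp]], "TwoStateModel")) return(NA)
    reconstructSpecies(tree, stats::setNames(m[, sp], rownames(m)),
                       species = sp, model = models[[sp]], nMaps = nMaps,
                       seed = seed + match(sp, colnames(m)))
  })
  names(out) <- colnames(m)
  out
}

#' Call gain/loss events from branch probabilities
#'
#' Retains branches whose event probability reaches \code{threshold};
#' events are attributed to the branch's child node. A branch on which both
#' a gain and a loss are called triggers a warning.
#'
#' @param recons a [Reconstruction-class] or a (possibly named) list of
#'   them (NA elements skipped).
#' @param threshold calling threshold (inclusive).
#' @return data.frame with columns \code{species}, \code{node},
#'   \code{type} ("gain"/"loss"), \code{probability}.
#' @export
callEvents <- function(recons, threshold = 0.8) {
  if (methods::is(recons, "Reconstruction")) recons <- list(recons)
  rows <- lapply(recons, function(r) {
    if (!methods::is(r, "Reconstruction")) return(NULL)
    be <- branchEvents(r)
    g <- be[be$pGain >= threshold, c("node", "pGain")]
    l <- be[be$pLoss >= threshold, c("node", "pLoss")]
    both <- intersect(g$node, l$node)
    if (length(both))
      warning("species ", r@species, ": both gain and loss called on ",
              "branch(es) ", paste(both, collapse = ", "))
    rbind(
      if (nrow(g)) data.frame(species = r@species, node = g$node,
                              type = "gain", probability = g$pGain,
                              stringsAsFactors = FALSE),
      if (nrow(l)) data.frame(species = r@species, node = l$node,
                              type = "loss", probability = l$pLoss,
                              stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0), node = integer(0),
                      type = character(0), probability = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genome-wide gain/loss rate sums
#'
#' Per species, the sums of the per-branch gain and loss probabilities over
#' the whole tree: comparable measures of how dynamic each species is.
#'
#' @param recons list of [Reconstruction-class] (NA elements skipped).
#' @return data.frame with \code{species}, \code{gainSum}, \code{lossSum}.
#' @export
totalRates <- function(recons) {
  if (methods::is(recons, "Reconstruction")) recons <- list(recons)
  rows <- lapply(recons, function(r) {
    if (!methods::is(r, "Reconstruction")) return(NULL)
    data.frame(species = r@species, gainSum = sum(r@branchGain),
               lossSum = sum(r@branchLoss), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Root presence posteriors
#'
#' @param recons list of [Reconstruction-class] over species.
#' @param tree the tree used for the reconstructions.
#' @return data.frame with \code{species} and \code{rootPosterior}.
#' @export
rootReport <- function(recons, tree) {
  root <- length(tree$tip.label) + 1L
  if (methods::is(recons, "Reconstruction")) recons <- list(recons)
  rows <- lapply(recons, function(r) {
    if (!methods::is(r, "Reconstruction")) return(NULL)
    data.frame(species = r@species,
               rootPosterior = unname(r@nodePosterior[root]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
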