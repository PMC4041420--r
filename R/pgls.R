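## Phylogenetically controlled maximum-likelihood regression with Pagel's
## lambda: the presence/absence profile of each tRNA species (treated as a
## continuous response, as the reference tool does for binary traits) is
## regressed on z-normalized genomic traits under a multivariate-normal
## model whose covariance is the lambda-scaled shared-path-length matrix of
## the species tree.

#' Phylogenetic covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @return symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
treeVcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries by lambda, leaving the diagonal
#' unchanged; lambda = 0 removes the phylogenetic signal, lambda = 1 leaves
#' the Brownian covariance intact.
#'
#' @param V covariance matrix.
#' @param lambda value in [0, 1].
#' @return transformed matrix.
#' @export
lambdaTransform <- function(V, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## GLS profile likelihood at a fixed lambda: beta and sigma2 have closed
## forms; returns the profiled log-likelihood and estimates.
.gls_at_lambda <- function(y, X, V, lambda) {
  W <- lambdaTransform(V, lambda)
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  n <- length(y)
  Ly <- backsolve(R, y, transpose = TRUE)
  LX <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(LX)
  beta <- tryCatch(solve(XtX, crossprod(LX, Ly)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  resid <- Ly - LX %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  fitted <- drop(X %*% beta)
  se <- sqrt(diag(solve(XtX)) * rss / max(1, n - ncol(X)))
  list(lambda = lambda, beta = drop(beta), sigma2 = sigma2,
       logLik = ll, fitted = fitted, se = se)
}

#' Maximum-likelihood phylogenetic regression with Pagel's lambda
#'
#' Jointly maximizes the multivariate-normal log-likelihood over the
#' regression coefficients, the Brownian scale and lambda: lambda is
#' profiled on [0, 1] by bounded scalar search with multi-start (0, 0.5, 1),
#' and beta and sigma2 take their GLS closed forms at each lambda. A binary
#' response is treated as continuous.
#'
#' @param y response vector, named by organism or in tip order.
#' @param X predictor matrix (no intercept column; one is added), or NULL
#'   for an intercept-only model.
#' @param tree rooted \code{phylo}; tips must match the observations.
#' @param V optional precomputed [treeVcv()] matrix (saves repeated work in
#'   screens).
#' @return object of class \code{pglsFit}: list with \code{coefficients}
#'   (intercept first), \code{se}, \code{lambda}, \code{sigma2},
#'   \code{logLik}, \code{r.squared} (squared Pearson correlation between
#'   GLS-fitted and observed response), \code{fitted}, \code{nobs},
#'   \code{nFree} (free parameters: coefficients + sigma2 + lambda).
#' @export
fitPgls <- function(y, X = NULL, tree = NULL, V = NULL) {
  if (is.null(V)) V <- treeVcv(tree)
  tips <- rownames(V)
  if (!is.null(names(y))) {
    stopifnot(setequal(names(y), tips))
    y <- y[tips]
    if (!is.null(X)) {
      X <- as.matrix(X)
      stopifnot(!is.null(rownames(X)))
      X <- X[tips, , drop = FALSE]
    }
  }
  n <- length(y)
  stopifnot(n == nrow(V))
  Xd <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X)) Xd <- cbind(Xd, as.matrix(X))
  if (n < ncol(Xd) + 3) stop("too few observations for the design")
  if (qr(Xd)$rank < ncol(Xd)) stop("singular design matrix")
  if (stats::var(y) == 0) stop("response has zero variance")

  obj <- function(l) {
    fit <- .gls_at_lambda(y, Xd, V, l)
    if (is.null(fit) || !is.finite(fit$logLik)) return(1e10)
    -fit$logLik
  }
  ## multi-start bounded search: the profile can be bimodal near the bounds
  opts <- lapply(list(c(0, 0.5), c(0.5, 1)), function(b)
    stats::optimize(obj, interval = b, tol = 1e-6))
  cand <- c(0, 0.5, 1, vapply(opts, `[[`, numeric(1), "minimum"))
  vals <- vapply(cand, obj, numeric(1))
  lam <- cand[which.min(vals)]
  fit <- .gls_at_lambda(y, Xd, V, lam)
  if (is.null(fit) || !is.finite(fit$logLik))
    stop("non-finite likelihood at the optimum; check the tree and data")
  r2 <- if (ncol(Xd) > 1) stats::cor(fit$fitted, y)^2 else 0
  structure(list(coefficients = stats::setNames(fit$beta, colnames(Xd)),
                 se = stats::setNames(fit$se, colnames(Xd)),
                 lambda = lam, sigma2 = fit$sigma2, logLik = fit$logLik,
                 r.squared = r2, fitted = fit$fitted, nobs = n,
                 nFree = ncol(Xd) + 2L),
            class = "pglsFit")
}

#' @export
print.pglsFit <- function(x, ...) {
  cat("Phylogenetic ML regression (Pagel's lambda)\n")
  cat("  lambda =", signif(x$lambda, 4), " sigma2 =", signif(x$sigma2, 4),
      " logLik =", signif(x$logLik, 6), "\n")
  print(signif(rbind(coef = x$coefficients, se = x$se), 4))
  cat("  R-squared =", signif(x$r.squared, 4), "\n")
  invisible(x)
}

#' Likelihood-ratio test of nested phylogenetic regressions
#'
#' Statistic = 2 (lnL_full - lnL_restricted), compared to a chi-square with
#' df equal to the difference in free parameters (1 when a single
#' coefficient is fixed at zero).
#'
#' @param full,restricted \code{pglsFit} objects, restricted nested in full.
#' @param df degrees of freedom; default from the fits' free parameters.
#' @param tol tolerance for a negative statistic before an optimization
#'   failure is declared.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
lrt <- function(full, restricted, df = NULL, tol = 1e-6) {
  stat <- 2 * (full$logLik - restricted$logLik)
  if (stat < -tol)
    stop("negative likelihood-ratio statistic (", signif(stat, 4),
         "): optimization failure, refit the models")
  stat <- max(stat, 0)
  if (is.null(df)) df <- full$nFree - restricted$nFree
  stopifnot(df >= 1)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param q target false discovery rate.
#' @return list with \code{reject} (logical, in input order),
#'   \code{threshold} (largest rejected p-value, NA when none).
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  reject <- adj <= q
  list(reject = reject,
       threshold = if (any(reject)) max(pvalues[reject]) else NA_real_)
}

#' Phylogenetic correlation of two continuous traits
#'
#' ML bivariate Brownian fit with a shared Pagel's lambda; the reported R is
#' the GLS correlation, and the p-value comes from a likelihood-ratio test
#' against the zero-correlation model (chi-square, 1 df).
#'
#' @param x,y numeric traits named by organism (or in tip order).
#' @param tree rooted \code{phylo}.
#' @return list with \code{R}, \code{lambda}, \code{statistic},
#'   \code{p.value}, \code{logLik}.
#' @export
traitCorrelation <- function(x, y, tree) {
  V <- treeVcv(tree)
  tips <- rownames(V)
  if (!is.null(names(x))) { x <- x[tips]; y <- y[tips] }
  n <- length(x)
  stopifnot(n == nrow(V), length(y) == n)
  one <- rep(1, n)

  biv <- function(l, constrainDiag = FALSE) {
    W <- lambdaTransform(V, l)
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Lx <- backsolve(R, cbind(x, y, one), transpose = TRUE)
    l1 <- Lx[, 3]
    mu <- c(crossprod(l1, Lx[, 1]), crossprod(l1, Lx[, 2])) / sum(l1^2)
    E <- cbind(Lx[, 1] - mu[1] * l1, Lx[, 2] - mu[2] * l1)
    S <- crossprod(E) / n
    logdetC <- 2 * sum(log(diag(R)))
    if (constrainDiag) S[1, 2] <- S[2, 1] <- 0
    detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (detS <= 0) return(list(ll = Inf, S = S))
    trTerm <- if (constrainDiag) 2 * n else
      sum(diag(solve(S, crossprod(E))))
    ll <- -0.5 * (2 * n * log(2 * pi) + n * log(detS) + 2 * logdetC +
                    trTerm)
    list(ll = ll, S = S)
  }
  prof <- function(constrain) {
    f <- function(l) {
      b <- biv(l, constrain)
      if (is.null(b)) return(1e10)
      if (!is.finite(b$ll)) return(-1e10)  # degenerate perfect fit
      -b$ll
    }
    o <- stats::optimize(f, c(0, 1), tol = 1e-6)
    cand <- c(0, 1, o$minimum)
    vals <- vapply(cand, f, numeric(1))
    lam <- cand[which.min(vals)]
    list(lambda = lam, fit = biv(lam, constrain))
  }
  full <- prof(FALSE)
  S <- full$fit$S
  Rcor <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (abs(Rcor) >= 1 - 1e-12) {
    return(list(R = sign(Rcor) * 1, lambda = full$lambda, statistic = Inf,
                p.value = 0, logLik = full$fit$ll))
  }
  restr <- prof(TRUE)
  stat <- max(0, 2 * (full$fit$ll - restr$fit$ll))
  list(R = Rcor, lambda = full$lambda, statistic = stat,
       p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
       logLik = full$fit$ll)
}

#' Screen tRNA species for trait associations
#'
#' For each tRNA species with more than \code{minDiscordant} discordant
#' organisms, fits phylogenetic regressions of the presence column on each
#' single trait and each pair of traits plus the intercept-only model, and
#' performs the nested likelihood-ratio tests: each trait against the
#' tree-only model, and each trait added to each other single trait. All
#' p-values are pooled into one Benjamini-Hochberg correction at level
#' \code{q}. A trait is called statistically significant and independent
#' for a species when adding it to the regression on each other single
#' trait survives the correction.
#'
#' @param x a [PresenceMatrix-class].
#' @param traits data.frame from [traitTable()] (the z-normalized columns
#'   are used), or any data.frame with an \code{organism} column and
#'   numeric trait columns ending in \code{.z}.
#' @param tree rooted \code{phylo} over the organisms.
#' @param q FDR level.
#' @param minDiscordant species whose minority state has at most this many
#'   organisms are skipped.
#' @return list with \code{calls} (data.frame: species, trait, beta,
#'   lambda, r.squared, pVsNull, pOverOthers (max of the two addition
#'   tests), called, direction), \code{threshold} (BH threshold),
#'   \code{skipped} (species skipped for low variability), \code{pooledP}.
#' @export
associationScreen <- function(x, traits, tree, q = 0.05,
                              minDiscordant = 3L) {
  m <- as.matrix(x)
  zCols <- grep("\\.z$", names(traits), value = TRUE)
  stopifnot(length(zCols) >= 2, "organism" %in% names(traits))
  Tm <- as.matrix(traits[, zCols, drop = FALSE])
  rownames(Tm) <- traits$organism
  stopifnot(setequal(rownames(m), rownames(Tm)))
  tree <- ape::keep.tip(tree, rownames(m))
  V <- treeVcv(tree)
  Tm <- Tm[rownames(V), , drop = FALSE]
  m <- m[rownames(V), , drop = FALSE]

  skipped <- character(0)
  rows <- list()
  pvals <- numeric(0)
  pid <- character(0)
  for (sp in colnames(m)) {
    yv <- m[, sp]
    disc <- min(sum(yv == 1), sum(yv == 0))
    if (disc <= minDiscordant) { skipped <- c(skipped, sp); next }
    fit0 <- fitPgls(yv, NULL, V = V)
    single <- lapply(zCols, function(tr)
      fitPgls(yv, Tm[, tr, drop = FALSE], V = V))
    names(single) <- zCols
    pairFit <- list()
    for (i in seq_along(zCols)) for (j in seq_along(zCols)) {
      if (i < j) {
        key <- paste(sort(c(zCols[i], zCols[j])), collapse = "+")
        pairFit[[key]] <- fitPgls(yv, Tm[, c(zCols[i], zCols[j])], V = V)
      }
    }
    for (tr in zCols) {
      pNull <- lrt(single[[tr]], fit0, df = 1)$p.value
      others <- setdiff(zCols, tr)
      pAdd <- vapply(others, function(ot) {
        key <- paste(sort(c(tr, ot)), collapse = "+")
        lrt(pairFit[[key]], single[[ot]], df = 1)$p.value
      }, numeric(1))
      pvals <- c(pvals, pNull, pAdd)
      pid <- c(pid, paste(sp, tr, "null", sep = "|"),
               paste(sp, tr, "over", others, sep = "|"))
      rows[[paste(sp, tr)]] <- data.frame(
        species = sp, trait = tr,
        beta = unname(single[[tr]]$coefficients[tr]),
        lambda = single[[tr]]$lambda,
        r.squared = single[[tr]]$r.squared,
        pVsNull = pNull, pOverOthers = max(pAdd),
        stringsAsFactors = FALSE)
      attr(rows[[paste(sp, tr)]], "pAdd") <- pAdd
    }
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    return(list(calls = NULL, threshold = NA_real_, skipped = skipped,
                pooledP = numeric(0)))
  }
  fdr <- bhFdr(pvals, q)
  rejected <- stats::setNames(fdr$reject, pid)
  calls$called <- vapply(seq_len(nrow(calls)), function(k) {
    sp <- calls$species[k]; tr <- calls$trait[k]
    others <- setdiff(zCols, tr)
    all(rejected[paste(sp, tr, "over", others, sep = "|")])
  }, logical(1))
  calls$direction <- ifelse(calls$beta > 0, "positive", "negative")
  rownames(calls) <- NULL
  list(calls = calls, threshold = fdr$threshold, skipped = skipped,
       pooledP = stats::setNames(pvals, pid))
}

#' Compare variability between associated and non-associated species
#'
#' Two-sided Mann-Whitney test of the variability measure between species
#' called trait-associated and the remaining species.
#'
#' @param variability named numeric vector of [variabilityMeasure()] values.
#' @param called logical vector (same order) marking associated species.
#' @return p-value, or NA when either group is empty.
#' @export
variabilityVsAssociation <- function(variability, called) {
  stopifnot(length(variability) == length(called))
  a <- variability[called]
  b <- variability[!called]
  if (!length(a) || !length(b)) return(NA_real_)
  exact <- min(length(a), length(b)) <= 8
  suppressWarnings(stats::wilcox.test(a, b, exact = exact)$p.value)
}
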