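test_that("the tree covariance matrix equals the path-sum oracle", {
  ## two tips, unit branches from the root
  tr <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(treeVcv(tr)), diag(2))
  ## shared stem
  tr2 <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  V <- treeVcv(tr2)
  expect_equal(V["a", "b"], 0.5)
  expect_equal(V["a", "a"], 1.0)
  expect_equal(V["a", "c"], 0)
  ## random trees vs explicit path enumeration
  set.seed(5)
  for (i in 1:10) {
    tr3 <- ape::rtree(6)
    expect_equal(treeVcv(tr3)[tr3$tip.label, tr3$tip.label],
                 pathsum_vcv(tr3), tolerance = 1e-12)
  }
  trNeg <- tr
  trNeg$edge.length[1] <- -0.1
  expect_error(treeVcv(trNeeg <- trNeg), "negative")
})

test_that("the lambda transform scales only off-diagonal entries", {
  V <- matrix(c(1, .6, .3, .6, 1, .2, .3, .2, 1.5), 3, 3)
  expect_equal(lambdaTransform(V, 0), diag(diag(V)))
  expect_equal(lambdaTransform(V, 1), V)
  W <- lambdaTransform(V, 0.5)
  expect_equal(W[1, 2], 0.3)
  expect_equal(diag(W), diag(V))
  expect_error(lambdaTransform(V, 1.2), "lambda")
})

test_that("on a star tree the ML fit equals ordinary least squares", {
  n <- 40
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  set.seed(3)
  x <- rnorm(n)
  y <- 1.5 * x + rnorm(n)
  names(x) <- names(y) <- tr$tip.label
  fit <- fitPgls(y, matrix(x, dimnames = list(names(x), "x")), tr)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
  ## y identical to x: perfect fit
  fit2 <- fitPgls(x + 0, matrix(x, dimnames = list(names(x), "x")), tr)
  expect_equal(fit2$r.squared, 1, tolerance = 1e-9)
})

test_that("closed-form GLS beta matches brute-force likelihood
           maximization on small trees", {
  set.seed(8)
  for (i in 1:5) {
    tr <- ape::rtree(6)
    V <- treeVcv(tr)
    x <- rnorm(6)
    y <- drop(t(chol(V)) %*% rnorm(6)) + 0.8 * x
    names(x) <- names(y) <- tr$tip.label
    fit <- fitPgls(y, matrix(x, dimnames = list(names(x), "x")), V = V)
    nll <- function(par) {
      W <- lambdaTransform(V, plogis(par[4]))
      mu <- par[1] + par[2] * x[rownames(V)]
      s2 <- exp(par[3])
      -mvtnorm_ll(y[rownames(V)], mu, s2 * W)
    }
    mvtnorm_ll <- function(yy, mu, S) {
      R <- chol(S)
      z <- backsolve(R, yy - mu, transpose = TRUE)
      -0.5 * (length(yy) * log(2 * pi) + 2 * sum(log(diag(R))) +
                sum(z^2))
    }
    opt <- optim(c(0, 0, 0, 0), nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(unname(fit$coefficients[2]), opt$par[2],
                 tolerance = 1e-3)
    expect_lte(-opt$value, fit$logLik + 1e-4)  # ML at least as good
  }
})

test_that("nesting monotonicity and the likelihood-ratio test", {
  set.seed(12)
  tr <- ape::rcoal(50)
  V <- treeVcv(tr)
  x <- drop(t(chol(V)) %*% rnorm(50))
  y <- drop(t(chol(V)) %*% rnorm(50))
  names(x) <- names(y) <- rownames(V)
  f1 <- fitPgls(y, matrix(x, dimnames = list(names(x), "x")), V = V)
  f0 <- fitPgls(y, NULL, V = V)
  expect_gte(f1$logLik, f0$logLik - 1e-8)
  l <- lrt(f1, f0)
  expect_equal(l$df, 1)
  ## arithmetic and the chi-square oracle
  stat4 <- lrt(list(logLik = -100, nFree = 4),
               list(logLik = -102, nFree = 3))
  expect_equal(stat4$statistic, 4)
  expect_equal(stat4$p.value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(stat4$p.value, 0.0455, tolerance = 1e-3)
  same <- lrt(f1, f1, df = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(lrt(list(logLik = -102, nFree = 4),
                   list(logLik = -100, nFree = 3)), "negative")
})

test_that("lambda is recovered across its range", {
  set.seed(21)
  tr <- simulateTree(200, seed = 77)
  V <- treeVcv(tr)
  for (lam in c(0, 0.5, 1)) {
    est <- replicate(7, {
      W <- lambdaTransform(V, lam)
      y <- drop(t(chol(W)) %*% rnorm(200))
      names(y) <- rownames(V)
      fitPgls(y, NULL, V = V)$lambda
    })
    expect_lt(abs(median(est) - lam), 0.15)
  }
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  r <- bhFdr(c(0.001, 0.01, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$threshold, 0.04)
  expect_false(any(bhFdr(rep(1, 6), 0.05)$reject))
  expect_true(bhFdr(0.04, 0.05)$reject)
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")
  ## agreement with the step-up definition on a random vector
  set.seed(6)
  p <- runif(50)^2
  r2 <- bhFdr(p, 0.1)
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= 0.1 * seq_len(m) / m)))
  manual <- rep(FALSE, m)
  if (k > 0) manual[ord[seq_len(k)]] <- TRUE
  expect_equal(r2$reject, manual)
})

test_that("phylogenetic trait correlation hits the exact extremes", {
  tr <- ape::rcoal(30)
  set.seed(14)
  x <- drop(t(chol(treeVcv(tr))) %*% rnorm(30))
  names(x) <- tr$tip.label
  expect_equal(traitCorrelation(x, x + 0, tr)$R, 1)
  neg <- traitCorrelation(x, -x, tr)
  expect_equal(neg$R, -1)
  expect_equal(neg$p.value, 0)
})

test_that("trait correlation p-values are calibrated under the null", {
  set.seed(19)
  tr <- simulateTree(60, seed = 5)
  V <- treeVcv(tr)
  ps <- replicate(60, {
    x <- drop(t(chol(V)) %*% rnorm(60)); names(x) <- rownames(V)
    y <- drop(t(chol(V)) %*% rnorm(60)); names(y) <- rownames(V)
    traitCorrelation(x, y, tr)$p.value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("variability comparison uses the exact Mann-Whitney
           distribution for separated small groups", {
  v <- c(51, 52, 53, 54, 55, 96, 97, 98, 99, 100)
  called <- rep(c(FALSE, TRUE), each = 5)
  expect_equal(variabilityVsAssociation(v, called), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_true(is.na(variabilityVsAssociation(v, rep(TRUE, 10))))
})

test_that("the association screen skips low-variability species and
           controls false calls", {
  set.seed(33)
  tr <- simulateTree(80, seed = 44)
  V <- treeVcv(tr)
  orgs <- tr$tip.label
  mk <- function() drop(t(chol(V)) %*% rnorm(80))
  traits <- traitTable(setNames(10^(6 + 0.2 * mk()), orgs),
                       setNames(0.5 + 0.05 * mk(), orgs),
                       setNames(0.05 + 0.01 * mk(), orgs))
  m <- cbind(const = rep(1L, 80),
             nearconst = c(rep(1L, 78), 0L, 0L),
             rand1 = rbinom(80, 1, 0.5),
             rand2 = rbinom(80, 1, 0.5))
  rownames(m) <- orgs
  scr <- associationScreen(PresenceMatrix(m), traits, tr, q = 0.05)
  expect_true(all(c("const", "nearconst") %in% scr$skipped))
  ## independent binary noise: nothing should be called
  expect_false(any(scr$calls$called))
})
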