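## Gaussian closed-form estimators of MI, CMI and CMI2 -- the causal-strength
## kernel of the pipeline. All values are in nats (natural logarithm).

.RIDGE <- 1e-8

.degenerate <- function(what) {
    stop(errorCondition(paste0("degenerate input: ", what),
                        class = c("dbncsDegenerateInput", "error")))
}

.checkSeries <- function(x, name = deparse(substitute(x))) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
        stop(sprintf("'%s' must be finite numeric", name))
    if (stats::sd(x) == 0) .degenerate(sprintf("'%s' is constant", name))
    invisible(x)
}

## Regularised sample correlation matrix of the columns of M.
## The ridge keeps near-singular matrices invertible and caps MI when |r| -> 1.
.corRidge <- function(M) {
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) .degenerate("constant conditioning variable")
    R <- stats::cor(M)
    R + diag(.RIDGE, ncol(M))
}

## log-determinant via Cholesky; failure means a non-PD matrix, which the
## ridge should prevent on real data -- report it as degenerate input.
.logdet <- function(S) {
    ch <- tryCatch(chol(S), error = function(e)
        .degenerate("singular covariance block"))
    2 * sum(log(diag(ch)))
}

#' Gaussian mutual information between two samples
#'
#' Mutual information of two jointly Gaussian variables computed from the
#' sample Pearson correlation r as -1/2 * log(1 - r^2) nats. A small ridge
#' (1e-8) on the correlation diagonal keeps the value finite as |r| -> 1.
#'
#' @param x,y numeric sample vectors of equal length (>= 3), neither
#'   constant.
#' @return non-negative mutual information in nats.
#' @examples
#' x <- rnorm(200); y <- 0.6 * x + rnorm(200)
#' gaussianMI(x, y)
#' @seealso [gaussianCMI()], [gaussianCMI2()]
#' @export
gaussianMI <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    .checkSeries(x, "x"); .checkSeries(y, "y")
    R <- .corRidge(cbind(x, y))
    mi <- 0.5 * (log(R[1L, 1L]) + log(R[2L, 2L]) - .logdet(R))
    max(mi, 0)
}

#' Gaussian conditional mutual information
#'
#' CMI(X; Y | Z) under a joint Gaussian model, computed from determinants of
#' the regularised correlation blocks:
#' 1/2 * log(|C(X,Z)| |C(Y,Z)| / (|C(Z)| |C(X,Y,Z)|)).
#' With an empty conditioning set this reduces to [gaussianMI()].
#'
#' @param x,y numeric sample vectors of equal length.
#' @param z numeric matrix of conditioning samples (rows aligned with `x`),
#'   possibly with zero columns, or `NULL`.
#' @return non-negative conditional mutual information in nats (clamped at 0
#'   against determinant round-off).
#' @examples
#' z <- rnorm(500); x <- z + rnorm(500); y <- z + rnorm(500)
#' gaussianCMI(x, y, cbind(z))   # near 0: x and y independent given z
#' @export
gaussianCMI <- function(x, y, z = NULL) {
    if (is.null(z) || NCOL(z) == 0L || length(z) == 0L)
        return(gaussianMI(x, y))
    z <- as.matrix(z)
    stopifnot(length(x) == length(y), nrow(z) == length(x))
    .checkSeries(x, "x"); .checkSeries(y, "y")
    R <- .corRidge(cbind(x, y, z))
    p <- ncol(R)
    zi <- seq.int(3L, p)
    cmi <- 0.5 * (.logdet(R[c(1L, zi), c(1L, zi), drop = FALSE]) +
                  .logdet(R[c(2L, zi), c(2L, zi), drop = FALSE]) -
                  .logdet(R[zi, zi, drop = FALSE]) - .logdet(R))
    max(cmi, 0)
}

## Covariance of the interventional distribution obtained by deleting the
## edge `from` -> `to` in a Gaussian system with covariance S: the (x, z)
## marginal is kept and the target's conditional is replaced by
## Ptilde(to | z) = Int P(to | from', z) P(from') dfrom', i.e. the influence
## of `from` is routed through an independent copy.
.interventionalCov <- function(S, from, to) {
    p <- ncol(S)
    zi <- setdiff(seq_len(p), c(from, to))
    pred <- c(from, zi)
    b <- tryCatch(solve(S[pred, pred, drop = FALSE], S[pred, to]),
                  error = function(e)
                      .degenerate("singular covariance block"))
    a <- b[1L]
    bz <- b[-1L]
    s2 <- S[to, to] - sum(S[to, pred] * b)
    Q <- S
    crossCov <- drop(bz %*% S[zi, -to, drop = FALSE])
    Q[to, -to] <- crossCov
    Q[-to, to] <- crossCov
    Q[to, to] <- drop(bz %*% S[zi, zi, drop = FALSE] %*% bz) + s2 +
        a^2 * S[from, from]
    Q
}

## KL(N(0, S) || N(0, Q)) for equal dimension p.
.gaussKL <- function(S, Q, p) {
    0.5 * (sum(diag(solve(Q, S))) - p + .logdet(Q) - .logdet(S))
}

#' Gaussian conditional mutual inclusive information (CMI2)
#'
#' CMI2(X; Y | Z) augments the conditional mutual information with two
#' Kullback-Leibler terms measuring how much the observed joint distribution
#' departs from the interventional distributions in which the direct edge
#' X -> Y (respectively Y -> X) is deleted:
#' CMI2 = 1/2 KL(P || P_{X->Y}) + 1/2 KL(P || P_{Y->X})
#'      = CMI(X;Y|Z) + two non-negative conditional KL terms.
#' Under a joint Gaussian model both interventional distributions are
#' Gaussian with explicitly constructed covariances, so the score has a
#' closed form in traces and log-determinants of the regularised correlation
#' blocks. CMI2 is symmetric in (x, y) and bounded below by CMI.
#'
#' @param x,y numeric sample vectors of equal length.
#' @param z numeric conditioning matrix with at least one column (for an
#'   empty conditioning set the pipeline uses [gaussianMI()]).
#' @return non-negative CMI2 in nats.
#' @examples
#' z <- rnorm(500); x <- z + rnorm(500); y <- x + z + rnorm(500)
#' gaussianCMI2(x, y, cbind(z))
#' @seealso [cmi2MonteCarlo()] for a sampling-based reference evaluation.
#' @export
gaussianCMI2 <- function(x, y, z) {
    z <- as.matrix(z)
    if (ncol(z) < 1L)
        stop("gaussianCMI2 needs at least one conditioning variable; use gaussianMI for the unconditional case")
    stopifnot(length(x) == length(y), nrow(z) == length(x))
    .checkSeries(x, "x"); .checkSeries(y, "y")
    R <- .corRidge(cbind(x, y, z))
    p <- ncol(R)
    klxy <- .gaussKL(R, .interventionalCov(R, 1L, 2L), p)
    klyx <- .gaussKL(R, .interventionalCov(R, 2L, 1L), p)
    max(0.5 * (klxy + klyx), 0)
}

#' Monte-Carlo reference evaluation of CMI2
#'
#' Evaluates CMI2(X; Y | Z) for a given correlation matrix by its
#' definition rather than the closed form: the CMI term is computed from
#' determinants, and each interventional KL term is estimated by sampling
#' from N(0, R) and integrating the interventional conditional
#' Ptilde(y | z) = Int P(y | x', z) P(x') dx' by inner Monte-Carlo over an
#' independent copy x'. Intended as an independent validator for
#' [gaussianCMI2()]; it shares no code with the closed form.
#'
#' @param R correlation (or covariance) matrix over (x, y, z1..znz),
#'   `x` first, `y` second.
#' @param nSample outer Monte-Carlo sample size.
#' @param nInner inner sample size for the interventional integral.
#' @param seed integer seed for the sampler.
#' @return list with elements `value` (the MC estimate of CMI2) and `se`
#'   (the Monte-Carlo standard error of the KL part).
#' @examples
#' R <- diag(3); R[1, 2] <- R[2, 1] <- 0.4
#' cmi2MonteCarlo(R, nSample = 1000, nInner = 200, seed = 1)
#' @export
cmi2MonteCarlo <- function(R, nSample = 4000L, nInner = 500L, seed = 1L) {
    stopifnot(is.matrix(R), nrow(R) == ncol(R), nrow(R) >= 3L)
    p <- ncol(R)
    set.seed(seed)
    L <- chol(R)
    X <- matrix(stats::rnorm(nSample * p), nSample, p) %*% L

    ## log N(y; mean, sd) for the conditional of variable `to` given the rest
    condMoments <- function(to, given) {
        b <- solve(R[given, given, drop = FALSE], R[given, to])
        s2 <- R[to, to] - sum(R[to, given] * b)
        list(b = b, sd = sqrt(s2))
    }

    klTerm <- function(from, to) {
        zi <- setdiff(seq_len(p), c(from, to))
        ## log P(to | z): plain Gaussian conditional
        mz <- condMoments(to, zi)
        muZ <- X[, zi, drop = FALSE] %*% mz$b
        logPz <- stats::dnorm(X[, to], mean = muZ, sd = mz$sd, log = TRUE)
        ## log Ptilde(to | z) by inner MC over an independent copy of `from`
        mf <- condMoments(to, c(from, zi))
        a <- mf$b[1L]; bz <- mf$b[-1L]
        base <- X[, zi, drop = FALSE] %*% bz                 # nSample x 1
        xprime <- stats::rnorm(nInner, 0, sqrt(R[from, from]))
        ## density matrix: rows = outer samples, cols = inner draws
        mu <- outer(drop(base), a * xprime, "+")
        dens <- stats::dnorm(X[, to], mean = mu, sd = mf$sd)
        logPtilde <- log(rowMeans(dens))
        logPz - logPtilde
    }

    t1 <- klTerm(1L, 2L)
    t2 <- klTerm(2L, 1L)
    klHalf <- 0.5 * t1 + 0.5 * t2
    ## CMI term from determinants (exact for the given R)
    zi <- seq.int(3L, p)
    cmi <- 0.5 * (determinant(R[c(1L, zi), c(1L, zi), drop = FALSE])$modulus +
                  determinant(R[c(2L, zi), c(2L, zi), drop = FALSE])$modulus -
                  determinant(R[zi, zi, drop = FALSE])$modulus -
                  determinant(R)$modulus)
    list(value = as.numeric(cmi + mean(klHalf)),
         se = stats::sd(klHalf) / sqrt(nSample))
}
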