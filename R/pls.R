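#' @include classes-dataset.R
NULL

#' NIPALS PLS1 regression model
#'
#' Centered (unscaled) partial least-squares regression with one response,
#' fitted by the NIPALS algorithm with deflation of X per component. The
#' per-component weights, loadings and y-loadings are stored so that
#' prediction coefficients can be assembled for any number of latent
#' variables up to `A`.
#'
#' @slot xCenter mean training spectrum.
#' @slot yCenter mean training moisture value.
#' @slot weights p x A matrix of unit-norm weight vectors `w_a`.
#' @slot xLoadings p x A matrix of x-loadings `p_a`.
#' @slot yLoadings length-A vector of y-loadings `q_a`.
#' @slot scores n x A matrix of training scores (mutually orthogonal).
#' @slot coefficients p x A matrix; column `a` holds the regression vector
#'   using the first `a` latent variables.
#' @slot A number of latent variables.
#'
#' @seealso [fitPLS()], [predict,PLSModel-method]
#' @export
setClass("PLSModel",
         representation(xCenter = "numeric",
                        yCenter = "numeric",
                        weights = "matrix",
                        xLoadings = "matrix",
                        yLoadings = "numeric",
                        scores = "matrix",
                        coefficients = "matrix",
                        A = "integer"))

setValidity("PLSModel", function(object) {
    msg <- character()
    if (object@A < 1L)
        msg <- c(msg, "A must be >= 1")
    if (nrow(object@coefficients) != length(object@xCenter))
        msg <- c(msg, "coefficient length differs from wavelength count")
    TT <- crossprod(object@scores)
    if (max(abs(TT - diag(diag(TT), nrow = nrow(TT)))) >
        1e-8 * max(diag(TT)))
        msg <- c(msg, "score vectors are not mutually orthogonal")
    if (length(msg)) msg else TRUE
})

#' Fit a PLS1 regression of moisture on spectra
#'
#' NIPALS PLS1: X and y are mean-centered internally (no variance
#' scaling). For each latent variable the weight vector is
#' `w = X'y / ||X'y||`, scores `t = Xw`, x-loading `p = X't / t't`,
#' y-loading `q = y't / t't`, followed by deflation of X (and y). The
#' regression vector for `a` components is `W_a (P_a' W_a)^{-1} q_a`.
#'
#' @param X numeric matrix (samples x wavelengths) or a
#'   [PairedData-class].
#' @param y numeric response (moisture %, ignored when `X` is
#'   [PairedData-class]).
#' @param A number of latent variables, `nrow(X) >= A + 1`.
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(X, y = NULL, A = 7L) {
    if (is(X, "PairedData")) {
        y <- lodValues(X)
        X <- intensities(X)
    }
    X <- as.matrix(X)
    y <- as.numeric(y)
    if (nrow(X) != length(y))
        stop("X rows and y length differ")
    A <- as.integer(A)
    if (A < 1L)
        stop("A must be >= 1")
    if (nrow(X) < A + 1L)
        stop("need at least A + 1 = ", A + 1L, " samples, got ", nrow(X))
    if (stats::sd(y) < 1e-24)
        stop("response y has zero variance")
    xc <- colMeans(X)
    yc <- mean(y)
    E <- sweep(X, 2L, xc)
    f <- y - yc
    p <- ncol(X)
    W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, nrow(X), A)
    q <- numeric(A)
    totE0 <- sum(E^2)
    if (totE0 / length(E) < 1e-24)
        stop("spectra have (numerically) zero variance")
    for (a in seq_len(A)) {
        curF <- sum(f^2)
        if (curF < 1e-300)
            stop("A = ", A, " exceeds the effective rank of the data ",
                 "(response fully explained before component ", a, ")")
        w <- crossprod(E, f)
        nw <- sqrt(sum(w^2))
        if (nw^2 < 1e-24 * totE0 * curF)
            stop("A = ", A, " exceeds the effective rank of the data ",
                 "(component ", a, " degenerate)")
        w <- w / nw
        tt <- as.vector(E %*% w)
        t2 <- sum(tt^2)
        if (t2 < 1e-24 * totE0)
            stop("A = ", A, " exceeds the effective rank of the data ",
                 "(component ", a, " degenerate)")
        pa <- as.vector(crossprod(E, tt)) / t2
        qa <- sum(f * tt) / t2
        E <- E - tcrossprod(tt, pa)
        f <- f - qa * tt
        W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- tt
    }
    B <- matrix(0, p, A)
    for (a in seq_len(A)) {
        Wa <- W[, seq_len(a), drop = FALSE]
        Pa <- P[, seq_len(a), drop = FALSE]
        B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
    }
    new("PLSModel", xCenter = xc, yCenter = yc, weights = W, xLoadings = P,
        yLoadings = q, scores = Tm, coefficients = B, A = A)
}

#' Predict moisture from spectra with a fitted PLS model
#'
#' `y_hat = yCenter + (X - xCenter) %*% b_a`.
#'
#' @param object a [PLSModel-class].
#' @param newdata numeric matrix on the training wavelength grid, or a
#'   [PairedData-class].
#' @param a number of latent variables to use (default: all fitted).
#' @param ... ignored.
#' @return numeric vector of predicted moisture values (%).
#' @export
setMethod("predict", "PLSModel", function(object, newdata, a = object@A,
                                          ...) {
    if (is(newdata, "PairedData"))
        newdata <- intensities(newdata)
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@xCenter))
        stop("wavelength grid of newdata (", ncol(newdata),
             " channels) does not match the model (",
             length(object@xCenter), ")")
    a <- as.integer(a)
    if (a < 1L || a > object@A)
        stop("a must be between 1 and ", object@A)
    object@yCenter +
        as.vector(sweep(newdata, 2L, object@xCenter) %*%
                  object@coefficients[, a])
})

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel: %d latent variables over %d channels (n = %d)\n",
                object@A, length(object@xCenter), nrow(object@scores)))
})

#' Root-mean-square error and coefficient of determination
#'
#' `rmse()` returns `sqrt(mean((y - yHat)^2))` (moisture %); `rsq()`
#' returns `1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the
#' evaluated set's own `y`.
#'
#' @param y observed values.
#' @param yHat predicted values, same length (>= 2).
#' @return a single number.
#' @export
rmse <- function(y, yHat) {
    if (length(y) != length(yHat))
        stop("y and yHat lengths differ")
    if (length(y) < 2L)
        stop("need at least 2 values")
    sqrt(mean((y - yHat)^2))
}

#' @rdname rmse
#' @export
rsq <- function(y, yHat) {
    if (length(y) != length(yHat))
        stop("y and yHat lengths differ")
    if (length(y) < 2L)
        stop("need at least 2 values")
    1 - sum((y - yHat)^2) / sum((y - mean(y))^2)
}
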