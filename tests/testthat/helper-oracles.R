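# Independent brute-force oracles. Each reimplements an operation in the
# most literal way possible so the packaged (vectorised) code can be checked
# against it; none of them call package internals.

# Literal moving-average smoother: loop over rows and columns, interior rows
# use a k-point centered window, a row at ordinal l from the nearer end uses
# a reduced symmetric window of (l - 1) * 2 + 1 points.
oracleTimeSmooth <- function(X, k) {
    n <- nrow(X)
    h <- (k - 1) / 2
    out <- X
    for (j in seq_len(ncol(X))) {
        for (i in seq_len(n)) {
            l <- min(i, n - i + 1)
            half <- if (l <= h) l - 1 else h
            out[i, j] <- mean(X[(i - half):(i + half), j])
        }
    }
    out
}

# Row-wise least-squares MSC via lm().
oracleMSC <- function(X, ref) {
    out <- X
    for (i in seq_len(nrow(X))) {
        fit <- stats::lm(X[i, ] ~ ref)
        out[i, ] <- (X[i, ] - stats::coef(fit)[1]) / stats::coef(fit)[2]
    }
    out
}

# Step-by-step NIPALS PLS1 reference with explicit y-deflation, returning
# predictions for new data. Written independently of the package (vector
# loops, coefficient assembly by accumulating rank-one updates).
oraclePLSPredict <- function(X, y, A, Xnew) {
    xm <- colMeans(X)
    ym <- mean(y)
    E <- sweep(X, 2, xm)
    f <- y - ym
    Enew <- sweep(Xnew, 2, xm)
    yhat <- rep(ym, nrow(Xnew))
    for (a in seq_len(A)) {
        w <- as.numeric(t(E) %*% f)
        w <- w / sqrt(sum(w * w))
        tt <- as.numeric(E %*% w)
        p <- as.numeric(t(E) %*% tt) / sum(tt * tt)
        q <- sum(f * tt) / sum(tt * tt)
        tnew <- as.numeric(Enew %*% w)
        yhat <- yhat + q * tnew
        E <- E - outer(tt, p)
        Enew <- Enew - outer(tnew, p)
        f <- f - q * tt
    }
    yhat
}

# Explicit leave-one-out loop with a plain fit/predict cycle.
oracleLOO <- function(X, y, A) {
    vapply(seq_along(y), function(i)
        oraclePLSPredict(X[-i, , drop = FALSE], y[-i], A,
                         X[i, , drop = FALSE]),
        numeric(1))
}

# Explicit leave-a-batch-out loop.
oracleLBO <- function(X, y, batches, A) {
    yhat <- numeric(length(y))
    for (b in unique(batches)) {
        out <- batches == b
        yhat[out] <- oraclePLSPredict(X[!out, , drop = FALSE], y[!out], A,
                                      X[out, , drop = FALSE])
    }
    yhat
}
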