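#' @include classes-dataset.R
NULL

checkOddK <- function(k) {
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
        k != floor(k))
        stop("window width k must be a positive integer")
    if (k %% 2 == 0)
        stop("window width k must be odd, got ", k)
    as.integer(k)
}

#' Moving-window smoothing of spectral variables along the time domain
#'
#' Replaces each element of the time x wavelength matrix by the mean of the
#' `k` surrounding points of the same spectral variable (column), i.e. a
#' centered moving average along the time axis. The `(k-1)/2` end points on
#' each side are smoothed with a reduced symmetric window of
#' `(l - 1) * 2 + 1` points, where `l` is the point ordinal from the nearer
#' end (so the very first and last rows pass through unchanged). Unlike
#' scatter-corrective preprocessing, this transformation never mixes
#' wavelengths, so moisture-correlated baseline information is preserved.
#'
#' @param X numeric matrix, rows = time-ordered spectra, columns =
#'   wavelengths. Rows must belong to a single batch: never smooth across
#'   batch boundaries.
#' @param k odd window width in points; `k = 1` is the identity.
#' @return matrix of the same dimensions.
#' @seealso [smoothingDelay()] for the in-line availability delay.
#' @examples
#' timeSmooth(cbind(c(1, 2, 4)), k = 3)  # c(1, 7/3, 4)
#' @export
timeSmooth <- function(X, k) {
    k <- checkOddK(k)
    X <- as.matrix(X)
    if (!nrow(X) || !ncol(X))
        stop("cannot smooth an empty matrix")
    if (k == 1L)
        return(X)
    n <- nrow(X)
    h <- (k - 1L) %/% 2L
    i <- seq_len(n)
    # effective half-window: full h in the interior, l-1 near either end
    half <- pmin(i - 1L, n - i, h)
    cs <- apply(X, 2L, cumsum)
    cs <- rbind(0, cs)                  # cs[r + 1, ] = sum of rows 1..r
    out <- (cs[i + half + 1L, , drop = FALSE] -
            cs[i - half, , drop = FALSE]) / (2 * half + 1)
    dimnames(out) <- dimnames(X)
    out
}

#' In-line availability delay of the centered time smoother
#'
#' A centered `k`-point moving average can only emit a smoothed value once
#' the trailing `(k-1)/2` points have been acquired, delaying the analysis
#' by `(k-1)/2 * dt` seconds; the full window spans `(k-1) * dt` seconds of
#' process time (e.g. 35 s delay and a 70 s span for `k = 15` at 5-s
#' acquisition steps).
#'
#' @param k odd window width in points.
#' @param dt acquisition interval, seconds per spectrum (> 0).
#' @return named numeric vector with elements `delay` and `fullSpan`
#'   (seconds).
#' @export
smoothingDelay <- function(k, dt) {
    k <- checkOddK(k)
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
        stop("dt must be a single positive number")
    c(delay = (k - 1) / 2 * dt, fullSpan = (k - 1) * dt)
}

#' Multiplicative scatter correction
#'
#' Each spectrum (row) is regressed on a reference spectrum by ordinary
#' least squares over wavelengths, `x ~ a + b * ref`, and corrected as
#' `(x - a) / b`. In fit mode (`ref = NULL`) the reference is the
#' column-wise mean of `X`; the reference actually used is returned so a
#' calibration-fit reference can be applied to new data.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param ref reference spectrum (length `ncol(X)`) or `NULL` to use the
#'   mean spectrum of `X`.
#' @return list with elements `x` (corrected matrix) and `reference`.
#' @export
msc <- function(X, ref = NULL) {
    X <- as.matrix(X)
    if (is.null(ref))
        ref <- colMeans(X)
    if (length(ref) != ncol(X))
        stop("reference length differs from the wavelength axis")
    rc <- ref - mean(ref)
    ss <- sum(rc^2)
    if (ss < 1e-24)
        stop("MSC reference spectrum is constant")
    b <- as.vector(X %*% rc) / ss   # sum(rc) = 0, so row means drop out
    bad <- which(abs(b) < 1e-12)
    if (length(bad))
        stop("MSC slope numerically zero for row ", bad[1])
    a <- rowMeans(X) - b * mean(ref)
    out <- (X - a) / b
    dimnames(out) <- dimnames(X)
    list(x = out, reference = as.numeric(ref))
}

#' Standard normal variate transformation
#'
#' Standardizes each spectrum (row) to mean 0 and sample standard
#' deviation 1 (`n - 1` denominator).
#'
#' @param X numeric matrix, one spectrum per row.
#' @return matrix of the same dimensions.
#' @export
snv <- function(X) {
    X <- as.matrix(X)
    m <- rowMeans(X)
    s <- apply(X, 1L, stats::sd)
    bad <- which(s < 1e-24)
    if (length(bad))
        stop("SNV undefined for constant row ", bad[1])
    (X - m) / s
}

#' Savitzky-Golay derivative along the wavelength axis
#'
#' Row-wise Savitzky-Golay polynomial filtering; the default configuration
#' (first derivative, second-order polynomial, 15-point window) matches the
#' common "1D2.15" labelling. The derivative is expressed per channel
#' index, not per nm. Edge points are handled by the polynomial fit within
#' the end windows.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param window odd filter window in points.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order, `<= polyorder`; 0 gives plain smoothing.
#' @return matrix of the same dimensions.
#' @export
sgDerivative <- function(X, window = 15L, polyorder = 2L, deriv = 1L) {
    window <- checkOddK(window)
    if (polyorder >= window)
        stop("polyorder must be smaller than the window")
    if (deriv > polyorder)
        stop("derivative order cannot exceed polyorder")
    X <- as.matrix(X)
    if (ncol(X) < window)
        stop("spectrum has fewer channels than the filter window")
    out <- t(apply(X, 1L, signal::sgolayfilt, p = polyorder, n = window,
                   m = deriv, ts = 1))
    dimnames(out) <- dimnames(X)
    out
}

#' Parse a preprocessing method label
#'
#' Accepts the labels used throughout the package and its command-line
#' interface: `"none"`, `"s15"`, `"s47"` (time smoothing with a 15- or
#' 47-point window), `"smooth:k"`, `"msc"`, `"snv"`, and `"sg:d:p:w"`
#' (Savitzky-Golay derivative `d`, polyorder `p`, window `w`; `"sg"` alone
#' is `1D2.15`).
#'
#' @param label character method label.
#' @return a list with elements `smooth` (odd integer, 1 = none) and
#'   `rowMethod` (`"none"`, `"msc"`, `"snv"` or `"sg"`) plus Savitzky-Golay
#'   parameters where relevant.
#' @export
parseMethod <- function(label) {
    label <- tolower(label)
    out <- list(smooth = 1L, rowMethod = "none",
                sgDeriv = 1L, sgOrder = 2L, sgWindow = 15L)
    if (label %in% c("none", "raw"))
        return(out)
    if (label == "s15") { out$smooth <- 15L; return(out) }
    if (label == "s47") { out$smooth <- 47L; return(out) }
    if (grepl("^smooth:[0-9]+$", label)) {
        out$smooth <- checkOddK(as.integer(sub("^smooth:", "", label)))
        return(out)
    }
    if (label %in% c("msc", "snv")) { out$rowMethod <- label; return(out) }
    if (label == "sg") { out$rowMethod <- "sg"; return(out) }
    if (grepl("^sg:[0-9]+:[0-9]+:[0-9]+$", label)) {
        p <- as.integer(strsplit(label, ":", fixed = TRUE)[[1]][-1])
        out$rowMethod <- "sg"
        out$sgDeriv <- p[1]; out$sgOrder <- p[2]; out$sgWindow <- p[3]
        return(out)
    }
    stop("unknown preprocessing method '", label, "'")
}
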