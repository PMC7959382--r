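## Kinetics: hue -> pH calibration and Vmax extraction from curves.

.polyEval <- function(coefs, x) {
    ## Horner evaluation, coefs = c0..c4
    y <- rep(coefs[length(coefs)], length(x))
    for (i in (length(coefs) - 1):1) y <- y * x + coefs[i]
    y
}

#' Fit the degree-4 hue-to-pH calibration
#'
#' Fits \code{pH ~ c0 + c1*hue + ... + c4*hue^4} by ordinary least squares to
#' calibration pairs measured on wells of known pH (typically spanning pH
#' 6.5 down to 4.0). Monotonicity of the fitted polynomial over the hue range
#' of the pairs is checked on a fine grid; a non-monotone fit yields a
#' warning and a \code{FALSE} monotone flag, not an error.
#'
#' @param pairs a data.frame (or 2-column matrix) with columns \code{hue}
#'   and \code{ph} (case-insensitive; the first two columns are used when
#'   names are absent).
#' @return A \linkS4class{CalibrationModel}.
#' @examples
#' h <- seq(30, 110, length.out = 20)
#' cal <- fitHueCalibration(data.frame(hue = h, ph = 6.5 - 0.03 * (h - 30)))
#' @export
fitHueCalibration <- function(pairs) {
    pairs <- as.data.frame(pairs)
    nm <- tolower(names(pairs))
    hi <- match("hue", nm); pi <- match("ph", nm)
    if (is.na(hi) || is.na(pi)) { hi <- 1L; pi <- 2L }
    hue <- as.numeric(pairs[[hi]]); ph <- as.numeric(pairs[[pi]])
    ok <- is.finite(hue) & is.finite(ph)
    hue <- hue[ok]; ph <- ph[ok]
    if (length(unique(hue)) < 5L)
        stop("need at least 5 distinct hue values for a degree-4 fit")
    fit <- lm(ph ~ poly(hue, 4, raw = TRUE))
    coefs <- unname(coef(fit))
    coefs[is.na(coefs)] <- 0
    hr <- range(hue)
    grid <- seq(hr[1], hr[2], length.out = 512L)
    vals <- .polyEval(coefs, grid)
    dgrid <- diff(vals)
    ## a flat (constant) fit counts as trivially monotone
    tol <- 1e-9 * max(1, abs(diff(range(vals))))
    monotone <- all(dgrid >= -tol) || all(dgrid <= tol)
    if (!monotone)
        warning("fitted calibration polynomial is not monotone over the hue range")
    new("CalibrationModel", coefficients = coefs, hueRange = hr,
        phRange = range(ph),
        rmse = sqrt(mean(fit$residuals^2)), monotone = monotone)
}

#' Convert a hue curve to a pH curve
#'
#' Applies the calibration polynomial element-wise. Hue values outside the
#' calibration's fitted hue range are converted anyway (polynomial
#' extrapolation) but flagged in the returned curve's
#' \code{attr(, "extrapolated")} logical vector.
#'
#' @param calib a \linkS4class{CalibrationModel}.
#' @param curve a \linkS4class{PhCurve} with \code{valueKind == "hue"}.
#' @return A \linkS4class{PhCurve} with \code{valueKind == "pH"}.
#' @export
hueToPh <- function(calib, curve) {
    stopifnot(is(calib, "CalibrationModel"), is(curve, "PhCurve"))
    if (curve@valueKind != "hue")
        stop("hueToPh expects a curve with valueKind 'hue'")
    ph <- .polyEval(calib@coefficients, curve@values)
    out <- phCurve(curve@strain, curve@condition, curve@times, ph, "pH")
    attr(out, "extrapolated") <-
        curve@values < calib@hueRange[1] | curve@values > calib@hueRange[2]
    out
}

#' Numerically invert a calibration over its monotone hue range
#'
#' Maps pH values back to hue by root finding on the calibration polynomial.
#' Only valid where the fit is monotone.
#'
#' @param calib a \linkS4class{CalibrationModel}.
#' @param ph numeric pH values inside the calibrated pH range.
#' @return numeric hue values.
#' @export
phToHue <- function(calib, ph) {
    if (!calib@monotone)
        stop("calibration is not monotone; inverse is not defined")
    grid <- seq(calib@hueRange[1], calib@hueRange[2], length.out = 4096L)
    phg <- .polyEval(calib@coefficients, grid)
    if (phg[1] > phg[length(phg)]) { grid <- rev(grid); phg <- rev(phg) }
    vapply(ph, function(p) {
        if (p < phg[1] || p > phg[length(phg)])
            stop(sprintf("pH %.3f outside calibrated range [%.3f, %.3f]",
                         p, phg[1], phg[length(phg)]))
        i <- findInterval(p, phg, all.inside = TRUE)
        ## refine with uniroot on the bracketing grid cell
        f <- function(h) .polyEval(calib@coefficients, h) - p
        lo <- min(grid[i], grid[i + 1]); hi <- max(grid[i], grid[i + 1])
        if (f(lo) == 0) return(lo)
        if (f(hi) == 0) return(hi)
        uniroot(f, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
}

#' Sliding-window slopes of a uniformly sampled series
#'
#' Least-squares slope of each contiguous window of \code{windowPoints}
#' measurements, in value units per hour. Internal workhorse of
#' \code{\link{computeVmax}}, exposed for inspection.
#'
#' @param times numeric, hours, uniform spacing.
#' @param values numeric.
#' @param windowPoints window length in measurements.
#' @param method \code{"ols"}: least-squares slope over the window (default);
#'   \code{"endpoint"}: (last - first) / elapsed time.
#' @return numeric vector of window slopes (length
#'   \code{length(times) - windowPoints + 1}).
#' @export
windowSlopes <- function(times, values, windowPoints = 10L,
                         method = c("ols", "endpoint")) {
    method <- match.arg(method)
    n <- length(times)
    w <- as.integer(windowPoints)
    if (w < 2L) stop("windowPoints must be >= 2")
    if (n < w) stop("curve has fewer points than the window")
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6 * max(dt))
        stop("non-uniform time spacing")
    nw <- n - w + 1L
    if (method == "endpoint")
        return((values[w:n] - values[1:nw]) / (times[w:n] - times[1:nw]))
    ## OLS slope per window: centered time weights are fixed across windows
    ## and sum to zero, so slope_i = sum(tc * y_window) / sum(tc^2)
    tc <- times[1:w] - mean(times[1:w])
    denom <- sum(tc * tc)
    wins <- embed(values, w)       # row i = values[i+w-1], ..., values[i]
    drop(wins %*% rev(tc)) / denom
}

#' Maximum hourly acidification rate of a pH curve
#'
#' Vmax is the maximum negative slope of the pH curve over a sliding window
#' of \code{windowPoints} consecutive measurements (10 measurements at
#' 6-minute spacing). The slope of each window is its ordinary least-squares
#' regression slope in pH per hour; the returned Vmax is the most negative
#' window slope, or 0 when no window has a negative slope.
#'
#' @param curve a \linkS4class{PhCurve} with \code{valueKind == "pH"}.
#' @param windowPoints number of measurements per window (default 10).
#' @param method window slope estimator, see \code{\link{windowSlopes}}.
#' @return numeric(1), Vmax in pH h^-1 (<= 0).
#' @examples
#' cv <- phCurve("s1", "DW_YE_30", seq(0, 5, by = 0.1), 6.5 - 0.5 * seq(0, 5, by = 0.1))
#' computeVmax(cv)  # -0.5
#' @export
computeVmax <- function(curve, windowPoints = 10L,
                        method = c("ols", "endpoint")) {
    stopifnot(is(curve, "PhCurve"))
    if (curve@valueKind != "pH")
        stop("computeVmax expects a pH curve; convert hue first (hueToPh)")
    s <- windowSlopes(curve@times, curve@values, windowPoints,
                      match.arg(method))
    m <- min(s)
    if (m >= 0) 0 else m
}

#' Build a PhenotypeTable from a set of pH curves
#'
#' Applies \code{\link{computeVmax}} to every curve and arranges the results
#' as strains x 12 conditions; strain x condition combinations without a
#' curve are marked missing. At most one curve per strain x condition is
#' allowed.
#'
#' @param curves list of \linkS4class{PhCurve} objects (all pH).
#' @param windowPoints,method passed to \code{\link{computeVmax}}.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
buildPhenotypeTable <- function(curves, windowPoints = 10L,
                                method = c("ols", "endpoint")) {
    method <- match.arg(method)
    stopifnot(length(curves) > 0)
    strains <- vapply(curves, function(cv) cv@strain, character(1))
    conds <- vapply(curves, function(cv) cv@condition, character(1))
    key <- paste(strains, conds, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate strain x condition curves: ",
             paste(unique(gsub("\r", " / ", key[duplicated(key)])),
                   collapse = ", "))
    ids <- sort(unique(strains))
    mat <- matrix(NA_real_, length(ids), 12L,
                  dimnames = list(ids, conditionIds()))
    for (i in seq_along(curves))
        mat[strains[i], conds[i]] <-
            computeVmax(curves[[i]], windowPoints, method)
    phenotypeTable(mat)
}

#' Read kinetic curves from a long-form delimited table
#'
#' Expects columns \code{strain_id}, \code{temperature_C}, \code{volume}
#' (\code{LW}/\code{DW}), \code{yeast} (\code{yes}/\code{no} or
#' \code{YE}/\code{NY}), \code{time_h}, \code{value}, \code{value_kind}
#' (\code{pH}/\code{hue}).
#'
#' @param path file path (tab- or semicolon-delimited, with header).
#' @param sep field separator (default tab).
#' @return list of \linkS4class{PhCurve} objects.
#' @export
readKineticCurves <- function(path, sep = "\t") {
    d <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
    need <- c("strain_id", "temperature_C", "volume", "yeast", "time_h",
              "value", "value_kind")
    if (!all(need %in% names(d)))
        stop("kinetics table must have columns: ",
             paste(need, collapse = ", "))
    ye <- ifelse(toupper(d$yeast) %in% c("YES", "YE", "1", "TRUE"),
                 "YE", "NY")
    cond <- paste(toupper(d$volume), ye, d$temperature_C, sep = "_")
    key <- paste(d$strain_id, cond, d$value_kind, sep = "\r")
    lapply(split(seq_len(nrow(d)), key), function(ix) {
        ix <- ix[order(d$time_h[ix])]
        phCurve(d$strain_id[ix[1]], cond[ix[1]], d$time_h[ix],
                d$value[ix], d$value_kind[ix[1]])
    })
}
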