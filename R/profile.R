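#' Geometric newborn-size grid
#'
#' Strictly increasing, geometrically spaced sizes; the default sweep
#' grid for [computeProfile()].
#'
#' @param lo,hi positive range endpoints, `lo < hi`.
#' @param n number of points (>= 2), default 200.
#' @return numeric vector of length `n`.
#' @export
sizeGrid <- function(lo, hi, n = 200L) {
    stopifnot(lo > 0, hi > lo, n >= 2)
    exp(seq(log(lo), log(hi), length.out = n))
}

#' Classify the qualitative shape of a capacity profile
#'
#' Thresholds neighbor differences into rise (`+`), flat (`0`) and fall
#' (`-`) at a relative tolerance, collapses runs, and maps the resulting
#' sign pattern to a label: all `+`/`0` (with at least one `+`) is
#' `increasing`; all `-`/`0` is `decreasing`; all `0` is `constant`;
#' `+` then `-` is `unimodal` (a bell shape with an interior maximum);
#' `+`, `-`, `+` is `unimodal_then_increasing`; anything else is
#' `other`.
#'
#' @param capacities numeric vector, at least 5 points.
#' @param tol relative tolerance separating flat from monotone neighbor
#'   steps (default 1e-9).
#' @return a single shape label.
#' @examples
#' classifyShape(c(1, 3, 5, 4, 2))  # "unimodal"
#' @export
classifyShape <- function(capacities, tol = 1e-9) {
    if (length(capacities) < 5L)
        stop("usage error: shape classification needs at least 5 points",
             call. = FALSE)
    d <- diff(capacities)
    scale <- pmax(abs(capacities[-1]), abs(capacities[-length(capacities)]))
    signs <- ifelse(d > tol * scale, "+", ifelse(d < -tol * scale, "-", "0"))
    pat <- rle(signs)$values
    pat <- pat[pat != "0"]
    pat <- rle(pat)$values          # collapse runs again after dropping 0s
    if (length(pat) == 0L) "constant"
    else if (identical(pat, "+")) "increasing"
    else if (identical(pat, "-")) "decreasing"
    else if (identical(pat, c("+", "-"))) "unimodal"
    else if (identical(pat, c("+", "-", "+"))) "unimodal_then_increasing"
    else "other"
}

#' Sweep initial newborn size and build a capacity profile
#'
#' Computes the proliferation capacity at each grid size, optionally
#' normalizes (size by \eqn{\bar V}; capacity by its value at
#' `referenceSize`, interpolated linearly when the reference is not a
#' grid point), and classifies the profile shape. The default grid is
#' 200 geometrically spaced sizes over \eqn{[\bar V/10, 3\bar V]}.
#'
#' @param rule a [DivisionRule-class].
#' @param law a [GrowthLaw-class].
#' @param Tf culture horizon in hours, > 0.
#' @param v0Grid explicit strictly increasing grid of positive sizes, or
#'   `NULL` to build one from `gridRange`/`gridPoints`.
#' @param gridRange length-2 range for the default geometric grid;
#'   default `c(Vbar/10, 3 * Vbar)`.
#' @param gridPoints number of grid points (default 200).
#' @param normalize logical; normalize axes (default `TRUE`).
#' @param referenceSize size at which the capacity axis is normalized;
#'   default \eqn{\bar V}. Must lie inside the grid range.
#' @param tol relative tolerance for [classifyShape()].
#' @return a [Profile-class].
#' @examples
#' pr <- computeProfile(divisionRule(1, 30, 20),
#'                      growthLaw("exponential", alpha = 1/48), Tf = 72)
#' shapeLabel(pr)  # "increasing"
#' @export
computeProfile <- function(rule, law, Tf, v0Grid = NULL, gridRange = NULL,
                           gridPoints = 200L, normalize = TRUE,
                           referenceSize = NULL, tol = 1e-9) {
    if (is.null(v0Grid)) {
        if (is.null(gridRange))
            gridRange <- c(rule@Vbar / 10, 3 * rule@Vbar)
        v0Grid <- sizeGrid(gridRange[1], gridRange[2], gridPoints)
    }
    .checkPositiveSize(v0Grid, "v0Grid")
    if (any(diff(v0Grid) <= 0))
        stop("configuration error: 'v0Grid' must be strictly increasing",
             call. = FALSE)
    if (is.null(referenceSize)) referenceSize <- rule@Vbar
    cap <- 2^vapply(v0Grid, function(v) .log2Capacity(rule, law, v, Tf),
                    numeric(1))
    if (normalize) {
        if (referenceSize < v0Grid[1] || referenceSize > v0Grid[length(v0Grid)])
            stop("configuration error: 'referenceSize' must lie inside the grid range",
                 call. = FALSE)
        capRef <- stats::approx(v0Grid, cap, xout = referenceSize)$y
        capNorm <- cap / capRef
    } else {
        capNorm <- cap
    }
    methods::new("Profile",
                 v0 = v0Grid, capacity = cap,
                 v0Normalized = v0Grid / rule@Vbar,
                 capacityNormalized = capNorm,
                 shape = classifyShape(cap, tol),
                 referenceSize = as.numeric(referenceSize),
                 normalized = isTRUE(normalize))
}

#' @rdname Profile-class
#' @export
setMethod("shapeLabel", "Profile", function(x) x@shape)

#' Tabulate a profile
#'
#' @param profile a [Profile-class].
#' @return a data.frame with columns `v0`, `capacity`, `v0_normalized`,
#'   `capacity_normalized`.
#' @export
profileTable <- function(profile) {
    stopifnot(methods::is(profile, "Profile"))
    data.frame(v0 = profile@v0,
               capacity = profile@capacity,
               v0_normalized = profile@v0Normalized,
               capacity_normalized = profile@capacityNormalized)
}

setMethod("as.data.frame", "Profile",
          function(x, row.names = NULL, optional = FALSE, ...)
              profileTable(x))

setMethod("show", "Profile", function(object) {
    n <- length(object@v0)
    cat(sprintf(paste0("Profile: %d newborn sizes in [%.4g, %.4g], ",
                       "shape '%s'\n  capacity range [%.4g, %.4g]"),
                n, object@v0[1], object@v0[n], object@shape,
                min(object@capacity), max(object@capacity)))
    if (object@normalized)
        cat(sprintf(", normalized at size %.4g", object@referenceSize))
    cat("\n")
    invisible(object)
})
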