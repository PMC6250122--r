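#' SVD-based rank analysis of a TA matrix
#'
#' Decides how many exponential components a global fit should use. The
#' matrix is decomposed by singular value decomposition; a component counts
#' as signal when (i) its singular value exceeds a noise floor and (ii) both
#' its left (spectral) and right (temporal) singular vectors are smooth, as
#' measured by a first-lag autocorrelation above \code{autocorrThreshold}.
#' The recommended rank is the number of leading consecutive components
#' passing both criteria; ties resolve to the smaller rank (parsimony).
#'
#' Masked cells are replaced by the matrix row mean before decomposition
#' (SVD needs a complete matrix); heavy masking therefore softens the
#' criterion rather than biasing it.
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param autocorrThreshold smoothness threshold for singular vectors.
#' @param svRatioFloorFactor noise floor = this factor times the median of
#'   the trailing 50\% of singular values.
#' @return a \linkS4class{RankReport}.
#' @examples
#' ## a rank-1 outer product of smooth vectors
#' wl <- seq(400, 700, 10); t <- seq(0, 1e-9, length.out = 40)
#' m <- taMatrix(wl, t, exp(-((wl - 550) / 50)^2) %o% exp(-t / 3e-10))
#' recommendedRank(svdRank(m))
#' @export
svdRank <- function(m, autocorrThreshold = 0.8, svRatioFloorFactor = 3) {
    vals <- m@values
    vals[m@mask] <- NA
    keepRow <- rowSums(!is.na(vals)) >= 2
    keepCol <- colSums(!is.na(vals)) >= 2
    vals <- vals[keepRow, keepCol, drop = FALSE]
    if (nrow(vals) < 2L || ncol(vals) < 2L)
        stop("unmasked submatrix must have at least 2 rows and 2 columns")
    if (anyNA(vals)) {
        rm <- rowMeans(vals, na.rm = TRUE)
        rm[!is.finite(rm)] <- 0
        idx <- which(is.na(vals), arr.ind = TRUE)
        vals[idx] <- rm[idx[, 1]]
    }
    if (max(abs(vals - mean(vals))) == 0) {
        warning("degenerate (constant) matrix: rank 0")
        n <- min(dim(vals))
        return(new("RankReport", singularValues = rep(0, n),
                   autocorrLeft = rep(0, n), autocorrRight = rep(0, n),
                   rank = 0L, noiseFloor = 0,
                   autocorrThreshold = autocorrThreshold))
    }
    sv <- svd(vals)
    n <- length(sv$d)
    acL <- apply(sv$u, 2, .lag1Autocorr)
    acR <- apply(sv$v, 2, .lag1Autocorr)
    trailing <- sv$d[seq.int(ceiling(n / 2) + 1L, n)]
    if (!length(trailing)) trailing <- sv$d[n]
    floorVal <- svRatioFloorFactor * stats::median(trailing)
    pass <- sv$d > floorVal & acL >= autocorrThreshold & acR >= autocorrThreshold
    rank <- if (pass[1]) {
        runs <- rle(pass)
        as.integer(runs$lengths[1])
    } else 0L
    new("RankReport", singularValues = sv$d, autocorrLeft = acL,
        autocorrRight = acR, rank = rank, noiseFloor = floorVal,
        autocorrThreshold = autocorrThreshold)
}
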