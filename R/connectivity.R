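#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlations between all parcel time series of one
#' subject.
#'
#' @param ts a [parcel_timeseries()].
#' @return P x P symmetric correlation matrix with unit diagonal and
#'   attributes `stage = "raw_r"` and `subject_id`.
#' @export
pearson_fc <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  m <- ts$matrix
  if (ncol(m) < 3) stop("need at least 3 timepoints")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("constant parcel series (parcel ",
         paste(which(sds == 0), collapse = ", "),
         ") for subject ", ts$subject_id)
  r <- stats::cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, stage = "raw_r", subject_id = ts$subject_id)
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Applies `atanh` to the off-diagonal correlations and zeroes the diagonal
#' (the self-correlation would map to infinity and must never be selected by
#' downstream sparsification).
#'
#' @param fc raw-correlation matrix from [pearson_fc()].
#' @return Fisher-z matrix with `stage = "fisher_z"` and zero diagonal.
#' @export
fisher_z <- function(fc) {
  if (!identical(attr(fc, "stage"), "raw_r"))
    stop("fisher_z expects a raw_r-stage connectivity matrix")
  off <- fc; diag(off) <- 0
  if (any(abs(off) >= 1))
    stop("off-diagonal |r| = 1 found (duplicate parcels?)")
  z <- atanh(off)
  diag(z) <- 0
  structure(z, stage = "fisher_z", subject_id = attr(fc, "subject_id"))
}

#' Group-mean connectivity matrix
#'
#' Element-wise arithmetic mean of a set of Fisher-z connectivity matrices
#' (the template for gradient estimation is built from the mean in z-space,
#' since the z-transform precedes gradient estimation).
#'
#' @param fcs list of `fisher_z`-stage matrices of identical dimension.
#' @return Mean Fisher-z matrix tagged `subject_id = "group-mean"`.
#' @export
group_mean_fc <- function(fcs) {
  if (length(fcs) < 2) stop("need at least 2 matrices")
  stages <- vapply(fcs, function(x) attr(x, "stage") %||% "", "")
  if (!all(stages == "fisher_z"))
    stop("all matrices must be fisher_z stage (got: ",
         paste(unique(stages), collapse = ", "), ")")
  dims <- vapply(fcs, nrow, 1L)
  if (length(unique(dims)) != 1) stop("matrices differ in parcel count")
  m <- Reduce(`+`, lapply(fcs, unclass)) / length(fcs)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, stage = "fisher_z", subject_id = "group-mean")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
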