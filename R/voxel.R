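#' Construct a voxel phantom
#'
#' A minimal 3-D phantom for exercising the SUV-threshold mask rules: a
#' binary whole-body bone mask and a nonnegative PSMA-PET SUV array on the
#' same grid. Array order is (z, y, x); no world coordinates are tracked.
#'
#' @param bone_mask 3-D array of 0/1 (or logical).
#' @param suv 3-D numeric array, same shape, finite and >= 0.
#' @param voxel_volume_ml Positive scalar voxel volume.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(bone_mask, suv, voxel_volume_ml = 1) {
  bone_mask <- (bone_mask != 0) * 1L
  if (length(dim(bone_mask)) != 3L || length(dim(suv)) != 3L)
    stop("bone_mask and suv must be 3-D arrays", call. = FALSE)
  if (!identical(dim(bone_mask), dim(suv)))
    stop("bone_mask and suv must share a shape", call. = FALSE)
  if (any(!is.finite(suv)) || any(suv < 0))
    stop("suv must be finite and nonnegative", call. = FALSE)
  stopifnot(voxel_volume_ml > 0)
  structure(list(bone_mask = bone_mask, suv = suv,
                 voxel_volume_ml = voxel_volume_ml),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %s, %d bone voxels, SUVmax = %.3g\n",
              paste(dim(x$suv), collapse = "x"), sum(x$bone_mask), max(x$suv)))
  invisible(x)
}

#' Non-tumor-infiltrated bone-marrow mask
#'
#' The whole-body bone mask minus voxels whose PSMA uptake exceeds half the
#' whole-body SUV maximum: marrow = bone AND (SUV <= 0.5 * max(SUV)).
#' Voxels exactly at the threshold are retained in marrow (the exclusion
#' rule is "above 50%").
#'
#' @param phantom A [voxel_phantom()].
#' @return Binary 3-D array, same shape; always a subset of the bone mask.
#' @export
marrow_mask <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  mx <- max(phantom$suv)
  if (mx <= 0) stop("undefined threshold", call. = FALSE)
  (phantom$bone_mask == 1L & phantom$suv <= 0.5 * mx) * 1L
}

#' Tumor iso-contour mask by global SUV thresholding
#'
#' Voxels whose SUV strictly exceeds `threshold_fraction` times the global
#' SUV maximum — the patient-specific global-threshold iso-contour used for
#' whole-body tumor delineation.
#'
#' @param suv 3-D nonnegative array (or a [voxel_phantom()], whose `suv`
#'   is used).
#' @param threshold_fraction Fraction of the global maximum, in (0, 1).
#' @return Binary 3-D array of the same shape.
#' @export
tumor_mask <- function(suv, threshold_fraction = 0.5) {
  if (inherits(suv, "voxel_phantom")) suv <- suv$suv
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      !is.finite(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("invalid threshold", call. = FALSE)
  mx <- max(suv)
  if (mx <= 0) stop("undefined threshold", call. = FALSE)
  (suv > threshold_fraction * mx) * 1L
}
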