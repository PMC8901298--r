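#' Read a DWI acquisition (NIfTI + FSL bval/bvec)
#'
#' Reads a NIfTI image (.nii or .nii.gz) together with its FSL-dialect
#' gradient table (bvals: one whitespace-separated row; bvecs: 3 rows x Q
#' columns). A 3-D image is returned as one [dwi_stack()]; a 4-D image
#' (H x W x Z x Q) is returned as a `dwi_volume`, a list of per-slice stacks
#' along the third (slice) axis. Gradient directions are interpreted in the
#' image frame. Voxel coordinates are 0-based in any reported output.
#'
#' @param image_path path to a NIfTI file.
#' @param bval_path,bvec_path paths to the gradient-table text files.
#' @return a [dwi_stack()] (3-D input) or a `dwi_volume` (4-D input).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  img <- as.array(RNifti::readNifti(image_path))
  img <- array(as.numeric(img), dim(img))  # drop NIfTI header attributes
  bvals <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L)
    stop("bvec file must have exactly 3 rows (FSL dialect)", call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite voxels", call. = FALSE)
  d <- dim(img)
  q <- d[length(d)]
  if (length(bvals) != q || ncol(bvec) != q)
    stop("gradient table length (", length(bvals),
         ") does not match volume count (", q, ")", call. = FALSE)
  if (length(d) == 3L) return(dwi_stack(img, bvals, bvec))
  if (length(d) == 4L) {
    slices <- lapply(seq_len(d[3L]), function(z)
      dwi_stack(img[, , z, ], bvals, bvec))
    return(structure(list(slices = slices, dim = d, bvals = bvals,
                          bvecs = bvec), class = "dwi_volume"))
  }
  stop("expected a 3-D or 4-D NIfTI image, got ", length(d), "-D",
       call. = FALSE)
}

#' Write a DWI stack as NIfTI + FSL bval/bvec
#'
#' Inverse of [read_dwi()] for 3-D stacks: the image is stored as
#' double-precision NIfTI so read/write round-trips are exact, and the
#' gradient table is written in the FSL dialect. Output directories are
#' created as needed.
#'
#' @param stack a [dwi_stack()] or `dwi_volume`.
#' @param image_path output NIfTI path (.nii or .nii.gz).
#' @param bval_path,bvec_path output gradient-table paths (omit to skip).
#' @return `image_path`, invisibly.
#' @export
write_dwi <- function(stack, image_path, bval_path = NULL, bvec_path = NULL) {
  if (inherits(stack, "dwi_volume")) {
    arr <- array(0, stack$dim)
    for (z in seq_along(stack$slices))
      arr[, , z, ] <- stack$slices[[z]]$intensities
    bvals <- stack$bvals; bvecs <- stack$bvecs
  } else {
    stopifnot(inherits(stack, "dwi_stack"))
    arr <- stack$intensities
    bvals <- stack$bvals; bvecs <- stack$bvecs
  }
  if (!all(is.finite(arr)))
    stop("refusing to write non-finite intensities", call. = FALSE)
  for (p in c(image_path, bval_path, bvec_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  }
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), image_path)
  if (!is.null(bval_path))
    writeLines(paste(format(bvals, trim = TRUE, scientific = FALSE),
                     collapse = " "), bval_path)
  if (!is.null(bvec_path))
    utils::write.table(bvecs, bvec_path, row.names = FALSE,
                       col.names = FALSE)
  invisible(image_path)
}

#' Write a 2-D map (FA, ADC, ...) as NIfTI
#'
#' @param map numeric matrix.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (!dir.exists(dirname(path))) dir.create(dirname(path), recursive = TRUE)
  m <- map
  m[is.na(m)] <- 0
  RNifti::writeNifti(RNifti::asNifti(as.matrix(m), datatype = "double"), path)
  invisible(path)
}
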