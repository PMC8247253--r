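# Thin NIfTI-1 wrappers around RNifti. Masks are written as 0/1 integers,
# everything else as float.

#' Read / write NIfTI-1 volumes
#'
#' @param x Numeric or logical array (3-D or 4-D).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm (first three pixdim entries).
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a plain array (logical if the file holds only 0/1).
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  attr(x, "pixdim") <- voxel_size
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (all(arr %in% c(0, 1))) arr <- array(arr == 1, dim(arr))
  arr
}

# Common mask plumbing: accept logical/numeric arrays, return logical.
as_mask <- function(x) {
  if (is.null(x)) return(NULL)
  array(as.logical(x != 0 & !is.na(x)), dim(x))
}

check_same_grid <- function(..., what = "volumes") {
  dims <- lapply(list(...), function(a) dim(a)[1:3])
  if (!all(vapply(dims[-1], identical, logical(1), dims[[1]]))) {
    stop(what, " are not on the same grid: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"),
                      character(1)), collapse = " vs "), call. = FALSE)
  }
  invisible(dims[[1]])
}
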