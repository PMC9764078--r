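#' Read FSL-style bval/bvec text files
#'
#' `bval` is a single whitespace-separated row of b-values; `bvec` is
#' three rows (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path file paths.
#' @return A [dti_protocol()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L) bv <- t(bv)
  dti_protocol(bvals, t(bv))
}

#' Write FSL-style bval/bvec text files
#'
#' @param protocol a [dti_protocol()].
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_bval_bvec <- function(protocol, bval_path, bvec_path) {
  stopifnot(inherits(protocol, "dti_protocol"))
  writeLines(paste(format(protocol$bvals, trim = TRUE), collapse = " "),
             bval_path)
  m <- t(protocol$bvecs)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.15g", r), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read / write DWI volumes as NIfTI
#'
#' Thin wrappers over RNifti (a suggested dependency, checked at call
#' time) for 4D diffusion-weighted volumes and 3D metric maps.
#'
#' @param path NIfTI file path.
#' @return `read_nifti_volume` returns a plain numeric array.
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' @rdname read_nifti_volume
#' @param volume numeric array (3D map or 4D DWI stack).
#' @param voxel_mm voxel edge length(s) in mm.
#' @export
write_nifti_volume <- function(volume, path, voxel_mm = 0.15) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_mm, length.out = min(3, length(dim(volume))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 2-column radial profile CSV
#'
#' Columns `q_nm_inv` and `intensity`.
#'
#' @param path CSV path.
#' @return A [radial_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  radial_profile(df$q_nm_inv, df$intensity)
}

#' @rdname read_profile_csv
#' @param profile a [radial_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  utils::write.csv(data.frame(q_nm_inv = profile$q,
                              intensity = profile$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
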