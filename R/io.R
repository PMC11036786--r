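DEFAULT_AXES <- c(x = "right", y = "anterior", z = "superior")
UNDEFINED_CODE <- 255L

#' Read a grey-matter density volume from NIfTI
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param axis_convention named character vector (x, y, z) declaring the
#'   anatomical meaning of positive grid directions. When NULL the RAS
#'   default is assumed and a message notes it; the convention is never
#'   guessed silently from the header.
#' @return An \code{\link{intensity_volume}}.
#' @export
read_volume <- function(path, axis_convention = NULL) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: expected a 3D volume, got %s dims",
                 path, length(dim(arr))), call. = FALSE)
  if (is.null(axis_convention)) {
    axis_convention <- DEFAULT_AXES
    message(sprintf("%s: assuming +x=right, +y=anterior, +z=superior",
                    basename(path)))
  }
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox) | vox <= 0)) vox <- c(1, 1, 1)
  intensity_volume(arr, voxel_size_mm = vox,
                   axis_convention = axis_convention)
}

#' Write a volume to NIfTI
#'
#' @param volume an \code{\link{intensity_volume}} or 3D array.
#' @param path output path (.nii or .nii.gz).
#' @param datatype storage type (default "double" so round-trips are
#'   exact).
#' @export
write_volume <- function(volume, path, datatype = "double") {
  arr <- as_volume_array(volume)
  vox <- attr(volume, "voxel_size_mm")
  if (!is.null(vox)) attr(arr, "pixdim") <- vox
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}

#' Write a pattern map to NIfTI with a JSON sidecar
#'
#' Codes are stored as 8-bit integers with undefined voxels encoded as
#' 255; the sidecar records the bit order, undefined sentinel and axis
#' convention so the map is self-describing.
#'
#' @param map a \code{pattern_map}.
#' @param path output NIfTI path; the sidecar goes to the same path with
#'   extension .json.
#' @param axis_convention convention to record in the sidecar.
#' @param mask_rule description of how the mask was obtained (recorded).
#' @export
write_pattern_map <- function(map, path,
                              axis_convention = DEFAULT_AXES,
                              mask_rule = "density > 0") {
  stopifnot(inherits(map, "pattern_map"))
  codes <- unclass(map)
  codes[is.na(codes)] <- UNDEFINED_CODE
  img <- RNifti::asNifti(array(as.integer(codes), dim(map)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(bit_order = attr(map, "bit_order"),
                            msb = attr(map, "msb"),
                            undefined_code = UNDEFINED_CODE,
                            axis_convention = as.list(axis_convention),
                            mask_rule = mask_rule),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pattern map written by \code{\link{write_pattern_map}}
#'
#' @param path NIfTI path (sentinel 255 becomes NA).
#' @return A \code{pattern_map}.
#' @export
read_pattern_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  codes <- array(as.integer(arr), dim(arr))
  codes[codes == UNDEFINED_CODE] <- NA_integer_
  if (any(!is.na(codes) & (codes < 0L | codes > 63L)))
    stop(sprintf("%s: codes outside [0, 63]", path), call. = FALSE)
  structure(codes, mask = !is.na(codes),
            bit_order = NEIGHBOUR_ORDER, msb = NEIGHBOUR_ORDER[1L],
            class = c("pattern_map", "array"))
}

#' Read an atlas label volume and its region table
#'
#' @param path NIfTI integer label volume (0 = background).
#' @param table_path delimited text with columns label, abbrev, name; when
#'   NULL a generic table is synthesised.
#' @return An \code{\link{atlas_labels}}.
#' @export
read_atlas <- function(path, table_path = NULL) {
  if (!file.exists(path))
    stop(sprintf("atlas file not found: %s", path), call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  labels <- array(as.integer(round(arr)), dim(arr))
  tab <- NULL
  if (!is.null(table_path)) {
    if (!file.exists(table_path))
      stop(sprintf("region table not found: %s", table_path),
           call. = FALSE)
    tab <- read.table(table_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("label", "abbrev", "name")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L)
      stop(sprintf("%s: region table missing columns: %s",
                   table_path, paste(miss, collapse = ", ")),
           call. = FALSE)
  }
  atlas_labels(labels, tab)
}

#' Write an atlas to NIfTI plus a region table
#'
#' @param atlas an \code{\link{atlas_labels}}.
#' @param path output NIfTI path.
#' @param table_path output TSV path for the region table (NULL to skip).
#' @export
write_atlas <- function(atlas, path, table_path = NULL) {
  stopifnot(inherits(atlas, "atlas_labels"))
  img <- RNifti::asNifti(atlas$labels, datatype = "int16")
  RNifti::writeNifti(img, path)
  if (!is.null(table_path))
    write.table(atlas$region_table, table_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the subject covariate table
#'
#' Delimited text (TSV or CSV by extension) with columns id, group, age,
#' sex, education, cognitive_score. Groups must be labelled "control" and
#' "case".
#'
#' @param path file path.
#' @return data.frame of subject records.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path))
    stop(sprintf("covariate table not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "education", "cognitive_score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: covariate table missing columns: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(df$group), c("control", "case"))
  if (length(bad) > 0L)
    stop(sprintf("%s: unknown group labels: %s (expected control/case)",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  df
}
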