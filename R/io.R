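# File containers. K-space and related arrays live in a directory container
# with a JSON header (meta.json) plus one raw little-endian payload per
# array (complex64 for complex data, float32/uint8 otherwise). Maps go
# through NIfTI, masks and motion curves through CSV, configs through YAML.

dtype_of <- function(x) {
  if (is.complex(x)) "complex64"
  else if (is.logical(x)) "uint8"
  else "float32"
}

write_payload <- function(x, path, dtype) {
  con <- file(path, "wb"); on.exit(close(con))
  if (dtype == "complex64") {
    v <- as.vector(x)
    inter <- as.numeric(rbind(Re(v), Im(v)))
    writeBin(inter, con, size = 4L, endian = "little")
  } else if (dtype == "uint8") {
    writeBin(as.integer(as.vector(x)), con, size = 1L)
  } else {
    writeBin(as.numeric(as.vector(x)), con, size = 4L, endian = "little")
  }
}

read_payload <- function(path, dtype, dims) {
  n <- prod(dims)
  con <- file(path, "rb"); on.exit(close(con))
  if (dtype == "complex64") {
    v <- readBin(con, "numeric", n = 2L * n, size = 4L, endian = "little")
    array(complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)]),
          dims)
  } else if (dtype == "uint8") {
    array(readBin(con, "integer", n = n, size = 1L) != 0L, dims)
  } else {
    array(readBin(con, "numeric", n = n, size = 4L, endian = "little"), dims)
  }
}

#' Write / read an array container directory
#'
#' A directory holding `meta.json` (array names, dtypes, shapes, plus
#' arbitrary scalar attributes) and one raw binary payload per array.
#' Complex arrays are stored as interleaved float32 pairs (complex64).
#'
#' @param path container directory (created if missing).
#' @param arrays named list of arrays.
#' @param attrs named list of scalar/vector metadata.
#' @return `write_array_container()` returns `path` invisibly;
#'   `read_array_container()` returns `list(arrays, attrs)`.
#' @export
write_array_container <- function(path, arrays, attrs = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "t2moco-container-v1", attrs = attrs,
               arrays = lapply(arrays, function(a)
                 list(dtype = dtype_of(a), dim = dim(a) %||% length(a))))
  for (nm in names(arrays))
    write_payload(arrays[[nm]], file.path(path, paste0(nm, ".raw")),
                  dtype_of(arrays[[nm]]))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array_container
#' @export
read_array_container <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop(sprintf("not a container: missing %s", mf))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  arrays <- list()
  for (nm in names(meta$arrays)) {
    info <- meta$arrays[[nm]]
    arrays[[nm]] <- read_payload(file.path(path, paste0(nm, ".raw")),
                                 info$dtype, unlist(info$dim))
  }
  list(arrays = arrays, attrs = meta$attrs)
}

require_field <- function(lst, nm, where) {
  if (is.null(lst[[nm]]))
    stop(sprintf("schema error: field '%s' missing from %s", nm, where))
  lst[[nm]]
}

#' Write / read a k-space container
#'
#' Stores `/kspace` (complex64, `[pe, ro, slice, coil, echo]`) with echo
#' times, TR and package labelling, and optionally coil maps, brain mask
#' and susceptibility-gradient map. Reading validates the schema and names
#' any missing field.
#'
#' @param path container directory.
#' @param kspace a [kspace_volume()].
#' @param csm optional [coil_sensitivities()].
#' @param brain_mask optional logical array.
#' @param sg_map optional susceptibility-gradient map (uT/m).
#' @param extra optional named list of further arrays.
#' @return `write_kspace_container()` returns `path` invisibly;
#'   `read_kspace_container()` a list `kspace`, `csm`, `brain_mask`,
#'   `sg_map`, `extra`.
#' @export
write_kspace_container <- function(path, kspace, csm = NULL,
                                   brain_mask = NULL, sg_map = NULL,
                                   extra = list()) {
  arrays <- c(list(kspace = kspace$data), extra)
  if (!is.null(csm))
    arrays$csm <- if (inherits(csm, "coil_sensitivities")) csm$csm else csm
  if (!is.null(brain_mask)) arrays$brain_mask <- brain_mask
  if (!is.null(sg_map)) arrays$sg_map <- sg_map
  write_array_container(path, arrays,
                        attrs = list(te_ms = kspace$te_ms,
                                     tr_ms = kspace$tr_ms,
                                     packages = kspace$packages))
}

#' @rdname write_kspace_container
#' @export
read_kspace_container <- function(path) {
  ct <- read_array_container(path)
  ks <- require_field(ct$arrays, "kspace", "container arrays")
  te <- require_field(ct$attrs, "te_ms", "container attributes")
  tr <- require_field(ct$attrs, "tr_ms", "container attributes")
  pk <- ct$attrs$packages %||% "odd_first"
  vol <- kspace_volume(ks, te_ms = unlist(te), tr_ms = tr, packages = pk)
  csm <- if (!is.null(ct$arrays$csm))
    coil_sensitivities(ct$arrays$csm, normalize = FALSE)
  extra <- ct$arrays[setdiff(names(ct$arrays),
                             c("kspace", "csm", "brain_mask", "sg_map"))]
  list(kspace = vol, csm = csm, brain_mask = ct$arrays$brain_mask,
       sg_map = ct$arrays$sg_map, extra = extra, attrs = ct$attrs)
}

#' Write a phantom dataset to a container directory
#'
#' Serializes every component of a [make_digital_phantom()] result
#' (k-space, coil maps, masks, parameter maps, clean images).
#'
#' @param path container directory.
#' @param ph a `phantom_dataset`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(path, ph) {
  write_array_container(
    path,
    arrays = list(kspace = ph$kspace$data, csm = ph$csm$csm,
                  brain_mask = ph$brain_mask, sg_map = ph$sg_map,
                  images = ph$images, s0_map = ph$s0_map,
                  t2star_map = ph$t2star_map, b0_map = ph$b0_map),
    attrs = list(te_ms = ph$te_ms, tr_ms = ph$tr_ms,
                 spacing_mm = ph$spacing_mm, seed = ph$seed,
                 packages = ph$kspace$packages))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  ct <- read_array_container(path)
  a <- ct$arrays; at <- ct$attrs
  for (nm in c("kspace", "csm", "brain_mask", "sg_map", "images",
               "s0_map", "t2star_map", "b0_map"))
    require_field(a, nm, "phantom container")
  te <- unlist(require_field(at, "te_ms", "phantom attributes"))
  structure(list(s0_map = a$s0_map, t2star_map = a$t2star_map,
                 b0_map = a$b0_map,
                 csm = coil_sensitivities(a$csm, normalize = FALSE),
                 brain_mask = a$brain_mask, sg_map = a$sg_map,
                 images = a$images,
                 kspace = kspace_volume(a$kspace, te, at$tr_ms),
                 te_ms = te, tr_ms = at$tr_ms,
                 spacing_mm = unlist(at$spacing_mm), seed = at$seed),
            class = "phantom_dataset")
}

#' Exclusion / reference masks as CSV
#'
#' One row per PE line with columns `line_index` (0-based), `weight_odd`,
#' `weight_even`.
#'
#' @param path CSV file path.
#' @param mask_odd,mask_even [exclusion_mask()] objects of equal length.
#' @return `write_mask_csv()` returns `path` invisibly; `read_mask_csv()` a
#'   list `odd`, `even` of exclusion masks.
#' @export
write_mask_csv <- function(path, mask_odd, mask_even) {
  utils::write.csv(
    data.frame(line_index = seq_along(mask_odd$line_weights) - 1L,
               weight_odd = mask_odd$line_weights,
               weight_even = mask_even$line_weights),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  df <- utils::read.csv(path)
  for (nm in c("line_index", "weight_odd", "weight_even"))
    require_field(df, nm, path)
  list(odd = exclusion_mask(df$weight_odd, "odd"),
       even = exclusion_mask(df$weight_even, "even"))
}

#' Motion curves as CSV
#'
#' Columns `time_s, tx_mm, ty_mm, tz_mm, rx_deg, ry_deg, rz_deg`.
#'
#' @param path CSV file path.
#' @param curve a [motion_curve()].
#' @return `write_motion_curve_csv()` returns `path` invisibly;
#'   `read_motion_curve_csv()` a motion curve.
#' @export
write_motion_curve_csv <- function(path, curve) {
  utils::write.csv(data.frame(time_s = curve$times_s, curve$params),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_curve_csv
#' @export
read_motion_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  for (nm in c("time_s", "tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg",
               "rz_deg"))
    require_field(df, nm, path)
  motion_curve(df$time_s, as.matrix(df[, c("tx_mm", "ty_mm", "tz_mm",
                                           "rx_deg", "ry_deg", "rz_deg")]))
}

#' Maps as NIfTI
#'
#' T2*/s0/validity maps exported as float32 NIfTI with the in-plane voxel
#' size in the header.
#'
#' @param map numeric 2D/3D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param spacing_mm in-plane voxel size.
#' @return `write_map_nifti()` returns `path` invisibly;
#'   `read_map_nifti()` the array.
#' @export
write_map_nifti <- function(map, path, spacing_mm = c(2, 2)) {
  img <- RNifti::asNifti(map * 1.0,
                         pixdim = c(spacing_mm[1], spacing_mm[2], 3))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Run manifest
#'
#' Writes a JSON manifest (resolved configuration, seed, package version,
#' input hashes, outputs) next to a command's outputs so that each result
#' is reproducible from the manifest alone.
#'
#' @param path manifest path (`.json`).
#' @param command command name.
#' @param config resolved configuration list.
#' @param inputs character vector of input paths (hashed if files).
#' @param outputs character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(),
                           outputs = character()) {
  hash_one <- function(p) {
    if (dir.exists(p)) {
      fs <- list.files(p, full.names = TRUE, recursive = TRUE)
      paste(unname(tools::md5sum(sort(fs))), collapse = "")
    } else if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("t2moco")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = config,
                   inputs = lapply(stats::setNames(as.list(inputs), inputs),
                                   hash_one),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
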