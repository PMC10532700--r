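#' Read a 3D volume from NIfTI, NRRD or MetaImage
#'
#' Geometry (spacing, origin, direction matrix) is taken from the file
#' header; values are returned unmodified. NIfTI (`.nii`, `.nii.gz`) is read
#' through RNifti; NRRD (`.nrrd`, raw encoding) and MetaImage
#' (`.mha`/`.mhd`, uncompressed) use a built-in reader covering the subset
#' of each format that this package writes.
#'
#' @param path File path.
#' @param labels Logical: return a [label_volume()] (values must be
#'   non-negative integers).
#' @return A [volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  v <- switch(ext,
    ".nii" = , ".nii.gz" = read_nifti_volume(path),
    ".nrrd" = read_nrrd_volume(path),
    ".mha" = , ".mhd" = read_meta_volume(path),
    stop("unsupported volume format: ", ext)
  )
  if (labels) label_volume(v$values, v$spacing, v$origin, v$axes) else v
}

#' Write a 3D volume to NIfTI, NRRD or MetaImage
#'
#' The format is chosen from the file extension. Integer (label) volumes are
#' stored as integers so labels round-trip bit-exactly; intensity volumes
#' are stored as 64-bit floats.
#'
#' @param vol A [volume()] or [label_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.nrrd`, `.mha` or
#'   `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  switch(ext,
    ".nii" = , ".nii.gz" = write_nifti_volume(vol, path),
    ".nrrd" = write_nrrd_volume(vol, path),
    ".mha" = , ".mhd" = write_meta_volume(vol, path),
    stop("unsupported volume format: ", ext)
  )
  invisible(path)
}

vol_affine <- function(vol) {
  rbind(cbind(vol$axes %*% diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D image: ", path)
  aff <- RNifti::xform(img)
  m <- unclass(aff)[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  axes <- sweep(m, 2, spacing, `/`)
  volume(as.array(img), spacing, unclass(aff)[1:3, 4], axes)
}

write_nifti_volume <- function(vol, path) {
  arr <- vol$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing  # scale lives in pixdim; xforms keep direction
  aff <- structure(vol_affine(vol), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header: ", path)
    if (line == "") break
    header <- c(header, line)
  }
  if (!grepl("^NRRD", header[1])) stop("not a NRRD file: ", path)
  fields <- header[grepl(":", header, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", fields))
  vals <- trimws(sub("^[^:]*:=?", "", fields))
  names(vals) <- tolower(keys)
  if (as.integer(vals[["dimension"]]) != 3L) stop("expected 3D NRRD: ", path)
  if (tolower(vals[["encoding"]]) != "raw") stop("only raw-encoded NRRD is supported")
  sizes <- as.integer(strsplit(vals[["sizes"]], "\\s+")[[1]])
  type <- tolower(vals[["type"]])
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs <- regmatches(vals[["space directions"]],
                     gregexpr("\\([^)]*\\)", vals[["space directions"]]))[[1]]
  m <- vapply(dirs, parse_vec, numeric(3))  # columns = spacing * axes columns
  spacing <- sqrt(colSums(m^2))
  axes <- sweep(m, 2, spacing, `/`)
  origin <- parse_vec(vals[["space origin"]])
  n <- prod(sizes)
  is_int <- type %in% c("int", "int32", "signed int", "short", "int16")
  raw_vals <- if (is_int)
    readBin(con, "integer", n = n, size = if (type %in% c("short", "int16")) 2L else 4L,
            endian = "little")
  else readBin(con, "double", n = n, size = if (type == "float") 4L else 8L,
               endian = "little")
  volume(array(raw_vals, sizes), spacing, origin, axes)
}

write_nrrd_volume <- function(vol, path) {
  is_int <- is.integer(vol$values)
  m <- vol$axes %*% diag(vol$spacing)
  fmt_vec <- function(x) sprintf("(%s)", paste(format(x, digits = 17), collapse = ","))
  header <- c(
    "NRRD0004",
    sprintf("type: %s", if (is_int) "int" else "double"),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(vol$values), collapse = " ")),
    "space dimension: 3",
    sprintf("space directions: %s %s %s",
            fmt_vec(m[, 1]), fmt_vec(m[, 2]), fmt_vec(m[, 3])),
    sprintf("space origin: %s", fmt_vec(vol$origin)),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeBin(as.vector(vol$values), con, size = if (is_int) 4L else 8L,
           endian = "little")
}

read_meta_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header is ASCII; locate the end of the ElementDataFile line byte-wise
  marker <- charToRaw("ElementDataFile")
  hits <- which(raw == marker[1])
  hdr_end <- NA
  for (h in hits) {
    if (h + length(marker) - 1 <= length(raw) &&
        identical(raw[h:(h + length(marker) - 1)], marker)) {
      nl <- which(raw[h:length(raw)] == as.raw(10))[1]
      hdr_end <- h + nl - 1
      break
    }
  }
  if (is.na(hdr_end)) stop("not a MetaImage header: ", path)
  fields <- strsplit(rawToChar(raw[1:hdr_end]), "\n")[[1]]
  keys <- trimws(sub("=.*$", "", fields))
  vals <- trimws(sub("^[^=]*=", "", fields))
  names(vals) <- keys
  sizes <- as.integer(strsplit(vals[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(vals[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(vals[["Offset"]], "\\s+")[[1]])
  axes <- matrix(as.numeric(strsplit(vals[["TransformMatrix"]], "\\s+")[[1]]),
                 3, 3, byrow = TRUE)
  type <- vals[["ElementType"]]
  n <- prod(sizes)
  datafile <- vals[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    con <- rawConnection(raw[-seq_len(hdr_end)])
  } else {
    con <- file(file.path(dirname(path), datafile), "rb")
  }
  on.exit(close(con))
  raw_vals <- switch(type,
    MET_INT = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported MetaImage element type: ", type)
  )
  volume(array(raw_vals, sizes), spacing, origin, axes)
}

write_meta_volume <- function(vol, path) {
  is_int <- is.integer(vol$values)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(format(as.vector(t(vol$axes)), digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(vol$origin, digits = 17), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(vol$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %s", paste(dim(vol$values), collapse = " ")),
    sprintf("ElementType = %s", if (is_int) "MET_INT" else "MET_DOUBLE"),
    sprintf("ElementDataFile = %s", datafile)
  )
  con <- file(path, "wb")
  writeLines(header, con)
  if (local) {
    writeBin(as.vector(vol$values), con, size = if (is_int) 4L else 8L,
             endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.vector(vol$values), con2, size = if (is_int) 4L else 8L,
             endian = "little")
    close(con2)
  }
  invisible(path)
}
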