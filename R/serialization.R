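#' Write / read rigid transforms as ITK text transform files
#'
#' The ITK insight transform file convention stores an affine transform as
#' nine row-major matrix entries followed by the translation, plus a fixed
#' center of rotation. Rigid transforms written by this package always use
#' a zero center (the rotation is folded into the translation).
#'
#' @param transform A [rigid_transform()].
#' @param path Output `.tfm` path.
#' @return `path` (write) / the [rigid_transform()] (read).
#' @export
write_itk_transform <- function(transform, path) {
  r <- rt_rotation(transform)
  t <- rt_translation(transform)
  lines <- c(
    "#Insight Transform File V1.0",
    "#Transform 0",
    "Transform: AffineTransform_double_3_3",
    sprintf("Parameters: %s",
            paste(format(c(as.vector(t(r)), t), digits = 17), collapse = " ")),
    "FixedParameters: 0 0 0"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_itk_transform
#' @export
read_itk_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- grep("^Parameters:", lines, value = TRUE)[1]
  if (is.na(pl)) stop("no Parameters line in transform file: ", path)
  p <- as.numeric(strsplit(trimws(sub("^Parameters:", "", pl)), "\\s+")[[1]])
  if (length(p) != 12) stop("expected 12 affine parameters")
  r <- matrix(p[1:9], 3, 3, byrow = TRUE)
  t <- p[10:12]
  fl <- grep("^FixedParameters:", lines, value = TRUE)[1]
  if (!is.na(fl)) {
    ctr <- as.numeric(strsplit(trimws(sub("^FixedParameters:", "", fl)),
                               "\\s+")[[1]])
    if (length(ctr) == 3 && any(ctr != 0))
      t <- t + as.numeric(ctr - r %*% ctr)
  }
  rigid_transform(r, t)
}

#' Export screw detections as CSV
#'
#' One row per detection: supporting-point count, center of mass, axis
#' direction (toward the head) and entry point, all in world mm.
#'
#' @param detections List of detections from [quantify_screws()].
#' @param path Output `.csv` path.
#' @export
write_screws_csv <- function(detections, path) {
  rows <- lapply(detections, function(s) data.frame(
    n_points = s$n_points,
    center_x = s$center[1], center_y = s$center[2], center_z = s$center[3],
    dir_x = s$direction[1], dir_y = s$direction[2], dir_z = s$direction[3],
    entry_x = s$entry_point[1], entry_y = s$entry_point[2],
    entry_z = s$entry_point[3]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export an evaluation report as flat CSV
#'
#' Flattens the nested report into `metric, value` rows (numeric leaves
#' only; vector leaves are indexed `name.1`, `name.2`, ...).
#'
#' @param report Named list of evaluation results.
#' @param path Output `.csv` path.
#' @export
write_report_csv <- function(report, path) {
  flat <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, if (nzchar(prefix)) "." else "", nm))
    } else if (is.numeric(x) || is.logical(x)) {
      if (length(x) == 1) flat[[prefix]] <<- as.numeric(x)
      else for (i in seq_along(x))
        flat[[paste0(prefix, ".", i)]] <<- as.numeric(x[i])
    }
  }
  walk(report, "")
  utils::write.csv(data.frame(metric = names(flat),
                              value = as.numeric(unlist(flat))),
                   path, row.names = FALSE)
  invisible(path)
}
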