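# Dataset serialization.
#
# Datasets are written either as RDS (compact, lossless) or as a plain-text
# directory mirror: one CSV per array with real/imag columns plus a JSON
# header carrying the grid size, channel count, and FOV. The text form is
# the interchange format for fixtures and external tools.

#' Save a k-space dataset
#'
#' @param ds a [kspace_dataset()]
#' @param path output `.rds` file, or a directory for the plain-text mirror
#' @param format `"rds"` or `"text"`
#' @export
write_dataset <- function(ds, path, format = c("rds", "text")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(ds, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  flatten <- function(a) data.frame(re = as.vector(Re(a)),
                                    im = as.vector(Im(a)))
  utils::write.csv(flatten(ds$s), file.path(path, "kspace.csv"),
                   row.names = FALSE)
  utils::write.csv(flatten(ds$maps), file.path(path, "maps.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(N0 = ds$N0, L = ds$L, fov_mm = ds$fov_mm,
                            id = ds$id),
                       file.path(path, "header.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a k-space dataset written by [write_dataset()]
#'
#' @param path `.rds` file or text-mirror directory
#' @return a [kspace_dataset()]
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) return(readRDS(path))
  hdr <- jsonlite::read_json(file.path(path, "header.json"),
                             simplifyVector = TRUE)
  unflatten <- function(f) {
    tab <- utils::read.csv(f)
    array(complex(real = tab$re, imaginary = tab$im),
          c(hdr$N0, hdr$N0, hdr$L))
  }
  kspace_dataset(unflatten(file.path(path, "kspace.csv")),
                 unflatten(file.path(path, "maps.csv")),
                 fov_mm = hdr$fov_mm, id = hdr$id)
}
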