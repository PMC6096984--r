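## File round-tripping.  One CSV dialect package-wide: comma separated,
## header row, UTF-8, dot decimal, no index column.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

write_csv_strict <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a budded-vesicle radius table
#'
#' CSV with columns \code{vesicle_id}, \code{R_alpha_um}, \code{R_beta_um}.
#'
#' @param path File path.
#' @return Data frame suitable for \code{\link{neck_fit}}.
#' @export
read_radius_table <- function(path) {
  df <- read_csv_strict(path, c("vesicle_id", "R_alpha_um", "R_beta_um"))
  if (nrow(df) == 0L) stop("empty radius table: ", path)
  df
}

#' Read an electrodeformation time series
#'
#' CSV with columns \code{t_s}, \code{a_um}, \code{b_um}, \code{uv_on}
#' (0/1).
#'
#' @param path File path.
#' @return A \code{\link{deformation_series}}.
#' @export
read_deformation_csv <- function(path) {
  deformation_series(read_csv_strict(path, c("t_s", "a_um", "b_um", "uv_on")))
}

#' Read a contour point table
#'
#' CSV with columns \code{vesicle_id}, \code{point_index}, \code{x_um},
#' \code{y_um}.
#'
#' @param path File path.
#' @return Named list of \code{\link{vesicle_contour}} objects, one per
#'   vesicle, points ordered by \code{point_index}.
#' @export
read_contour_csv <- function(path) {
  df <- read_csv_strict(path, c("vesicle_id", "point_index", "x_um", "y_um"))
  out <- lapply(split(df, df$vesicle_id), function(d) {
    d <- d[order(d$point_index), ]
    vesicle_contour(d$x_um, d$y_um)
  })
  out
}

#' Read an SEC elution trace
#'
#' CSV with columns \code{volume_mL}, \code{absorbance_AU}.
#'
#' @param path File path.
#' @return An \code{\link{elution_trace}}.
#' @export
read_elution_csv <- function(path) {
  df <- read_csv_strict(path, c("volume_mL", "absorbance_AU"))
  elution_trace(df$volume_mL, df$absorbance_AU)
}
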