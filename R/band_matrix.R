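#' @keywords internal
"_PACKAGE"

.meta_cols <- c("individual_id", "line", "temperature", "replicate")

#' Band-intensity matrix with individual metadata
#'
#' Container for reference-band intensities of venom gel lanes: one row per
#' individual wasp, one column per reference band, plus metadata columns
#' (`individual_id`, `line`, `temperature`, `replicate`). This is the common
#' currency of the densitometry, trend and screening functions.
#'
#' @param intensities numeric matrix (individuals x bands); column names are
#'   used as band names, otherwise `band_1..band_N` are assigned.
#' @param temperature numeric vector of rearing temperatures (degrees C), one
#'   per row.
#' @param replicate replicate identifiers, one per row.
#' @param line parasitoid line label (e.g. `"ISm"` or `"ISy"`), length 1 or
#'   one per row.
#' @param individual_id optional individual identifiers; generated if `NULL`.
#'
#' @return A data frame of class `band_matrix` whose first four columns are
#'   the metadata and remaining columns the band intensities.
#' @export
band_matrix <- function(intensities, temperature, replicate, line = "ISm",
                        individual_id = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (anyNA(intensities)) stop("band intensities must not contain missing values")
  if (length(temperature) != n) stop("'temperature' must have one value per row")
  if (length(replicate) != n) stop("'replicate' must have one value per row")
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- paste0("band_", seq_len(ncol(intensities)))
  }
  if (is.null(individual_id)) individual_id <- sprintf("ind_%03d", seq_len(n))
  line <- rep_len(as.character(line), n)
  out <- data.frame(
    individual_id = as.character(individual_id),
    line = line,
    temperature = as.numeric(temperature),
    replicate = as.character(replicate),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(intensities))
  class(out) <- c("band_matrix", "data.frame")
  out
}

#' Extract the numeric band-intensity block of a band matrix
#'
#' @param x a `band_matrix` (or plain numeric matrix, returned as is).
#' @return numeric matrix, individuals x bands.
#' @export
band_values <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(inherits(x, "band_matrix") || is.data.frame(x))
  cols <- setdiff(names(x), .meta_cols)
  as.matrix(x[, cols, drop = FALSE])
}

#' Extract the metadata columns of a band matrix
#'
#' @param x a `band_matrix`.
#' @return data frame with columns `individual_id`, `line`, `temperature`,
#'   `replicate`.
#' @export
band_meta <- function(x) {
  stopifnot(inherits(x, "band_matrix") || is.data.frame(x))
  x[, intersect(.meta_cols, names(x)), drop = FALSE]
}

# replace the intensity block, keeping metadata and class
set_band_values <- function(x, values) {
  cols <- setdiff(names(x), .meta_cols)
  stopifnot(ncol(values) == length(cols), nrow(values) == nrow(x))
  x[, cols] <- values
  x
}

#' Read / write band matrices as CSV
#'
#' The on-disk layout is the metadata columns first
#' (`individual_id,line,temperature,replicate`) followed by one column per
#' band.
#'
#' @param file path to a CSV file.
#' @return `read_band_matrix` returns a `band_matrix`.
#' @export
read_band_matrix <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.meta_cols, names(df))
  if (length(missing) > 0) {
    stop("band matrix CSV lacks metadata columns: ", paste(missing, collapse = ", "))
  }
  bands <- setdiff(names(df), .meta_cols)
  band_matrix(as.matrix(df[, bands, drop = FALSE]),
              temperature = df$temperature, replicate = df$replicate,
              line = df$line, individual_id = df$individual_id)
}

#' @rdname read_band_matrix
#' @param x a `band_matrix`.
#' @export
write_band_matrix <- function(x, file) {
  stopifnot(inherits(x, "band_matrix"))
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.band_matrix <- function(x, ...) {
  nb <- ncol(x) - length(intersect(.meta_cols, names(x)))
  cat(sprintf("band_matrix: %d individuals x %d reference bands\n", nrow(x), nb))
  tt <- table(temperature = x$temperature, replicate = x$replicate)
  cat("individuals per temperature x replicate cell:\n")
  print(tt)
  invisible(x)
}
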