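#' Read a labelled feature matrix
#'
#' Reads a delimited-text feature matrix whose header is `f0,...,f{d-1},label`
#' (the format written by [write_feature_matrix()]), or its columnar binary
#' twin (Parquet, when the file extension is `.parquet` and the arrow package
#' is available). Labels travel inside the file as the last column so row
#' alignment survives every stage.
#'
#' @param path File to read.
#' @param expected_d Optional feature dimension to validate against.
#' @return A tibble with numeric feature columns and a factor `label`.
#' @export
read_feature_matrix <- function(path, expected_d = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading Parquet requires the arrow package.")
    }
    out <- as_tibble(arrow::read_parquet(path))
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    probs <- readr::problems(out)
    if (nrow(probs) > 0L) {
      abort(sprintf("Parse error in '%s' at line %d: %s.",
                    path, probs$row[1] + 1L, probs$expected[1]))
    }
  }
  if (!"label" %in% names(out) || names(out)[ncol(out)] != "label") {
    abort(sprintf("'%s' must end in a `label` column.", path))
  }
  fc <- feature_cols(out)
  bad <- fc[!vapply(out[fc], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric feature column(s) in '%s': %s.",
                  path, paste(bad, collapse = ", ")))
  }
  if (!is.null(expected_d) && length(fc) != expected_d) {
    abort(sprintf("'%s' has %d feature columns; expected %d.",
                  path, length(fc), as.integer(expected_d)))
  }
  out$label <- factor(out$label)
  out
}

#' Write a labelled feature matrix
#'
#' Writes delimited text with header `f0,...,f{d-1},label`. Text output
#' round-trips numeric values to full double precision; a `.parquet` path
#' writes the columnar binary twin (bit-exact round trip) via arrow.
#'
#' @param data Tibble with feature columns and a `label` column.
#' @param path Destination; extension `.parquet` selects the binary form.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(data, path) {
  check_feature_data(data)
  data <- data[c(feature_cols(data), "label")]
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Writing Parquet requires the arrow package.")
    }
    arrow::write_parquet(data, path)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

# List a class-per-subdirectory image tree into a manifest tibble with a
# deterministic (alphabetical) class-to-index mapping.
image_manifest <- function(images) {
  if (is.data.frame(images)) {
    if (!all(c("path", "label") %in% names(images))) {
      abort("An image manifest needs `path` and `label` columns.")
    }
    m <- as_tibble(images[c("path", "label")])
  } else {
    if (!dir.exists(images)) abort(sprintf("No such directory: '%s'.", images))
    classes <- sort(list.dirs(images, recursive = FALSE, full.names = FALSE))
    if (length(classes) == 0L) abort(sprintf("'%s' has no class subdirectories.", images))
    m <- purrr::map_dfr(classes, function(cls) {
      files <- sort(list.files(file.path(images, cls),
                               pattern = "\\.(png|PNG)$", full.names = TRUE))
      tibble(path = files, label = cls)
    })
  }
  if (nrow(m) == 0L) abort("Empty image set.")
  m$label <- factor(m$label, levels = sort(unique(as.character(m$label))))
  m
}
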