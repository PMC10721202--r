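#' Scored image datasets and pipeline output files
#'
#' A scored dataset is a manifest of image files with mean-opinion
#' ratings on a declared instrument scale (e.g. a 1-7 Likert scale).
#' Ratings are mapped onto the common `[0, 5]` scale using the declared
#' instrument bounds — not the empirical min/max, which would make the
#' rescaled scores dataset-dependent.
#'
#' @name dataset-io
NULL

#' Rescale ratings to the common [0, 5] scale
#'
#' Affine map `5 * (raw - scale_min) / (scale_max - scale_min)`; strictly
#' monotone and exactly invertible.
#'
#' @param raw numeric rating(s) on the instrument scale.
#' @param scale_min,scale_max declared instrument bounds,
#'   `scale_min < scale_max`.
#' @return numeric value(s) in `[0, 5]`.
#' @export
rescale_scores <- function(raw, scale_min, scale_max) {
  if (!is.numeric(scale_min) || !is.numeric(scale_max) ||
      scale_min >= scale_max) {
    stop("invalid scale bounds: need scale_min < scale_max", call. = FALSE)
  }
  if (any(raw < scale_min | raw > scale_max)) {
    stop("raw score outside declared bounds [", scale_min, ", ",
         scale_max, "]", call. = FALSE)
  }
  5 * (raw - scale_min) / (scale_max - scale_min)
}

#' Load a scored-dataset manifest
#'
#' The manifest is a UTF-8 CSV with mandatory header columns
#' `image_path` and `score`. Dataset metadata may be carried in leading
#' comment lines of the form `# key: value` (keys `dataset_name`,
#' `scale_min`, `scale_max`) or passed as arguments, which take
#' precedence. Image paths are resolved relative to the manifest's
#' directory and must be unique; every score must lie inside the
#' declared bounds; at least two rows are required (downstream models
#' need n >= 2).
#'
#' @param path manifest CSV file.
#' @param dataset_name,scale_min,scale_max optional metadata overriding
#'   the manifest's comment header.
#' @return a `scored_dataset`: list with `records` (data.frame
#'   `image_path`, `raw_score`, `score_05`, row order preserved),
#'   `scale_min`, `scale_max`, `name`.
#' @export
load_manifest <- function(path, dataset_name = NULL, scale_min = NULL,
                          scale_max = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  dataset_name <- dataset_name %||% meta$dataset_name %||% "unnamed"
  scale_min <- scale_min %||% as.numeric(meta$scale_min %||% NA)
  scale_max <- scale_max %||% as.numeric(meta$scale_max %||% NA)
  if (is.na(scale_min) || is.na(scale_max)) {
    stop("manifest metadata must declare scale_min and scale_max ",
         "(comment header or arguments)", call. = FALSE)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("image_path", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("manifest must contain at least 2 records", call. = FALSE)
  }
  dup <- duplicated(df$image_path)
  if (any(dup)) {
    stop("duplicate image path(s) in manifest: ",
         paste(unique(df$image_path[dup]), collapse = ", "), call. = FALSE)
  }
  bad <- which(df$score < scale_min | df$score > scale_max)
  if (length(bad)) {
    stop("score outside declared bounds [", scale_min, ", ", scale_max,
         "] at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$image_path),
                     df$image_path, file.path(base, df$image_path))
  structure(
    list(
      records = data.frame(
        image_path = resolved,
        raw_score = df$score,
        score_05 = rescale_scores(df$score, scale_min, scale_max),
        stringsAsFactors = FALSE
      ),
      scale_min = scale_min, scale_max = scale_max, name = dataset_name
    ),
    class = "scored_dataset"
  )
}

#' @export
print.scored_dataset <- function(x, ...) {
  cat("<scored_dataset>", x$name, "-", nrow(x$records), "images, scale [",
      x$scale_min, ",", x$scale_max, "] -> [0, 5]\n")
  invisible(x)
}

#' Write a manifest CSV for a scored dataset
#'
#' Inverse of [load_manifest()]: emits the comment metadata header plus
#' `image_path,score` rows.
#'
#' @param paths image file paths.
#' @param scores raw scores on the instrument scale.
#' @param path output CSV file.
#' @param dataset_name,scale_min,scale_max instrument metadata.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(paths, scores, path, dataset_name,
                           scale_min, scale_max) {
  stopifnot(length(paths) == length(scores))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# dataset_name: ", dataset_name),
    paste0("# scale_min: ", format(scale_min, digits = 17)),
    paste0("# scale_max: ", format(scale_max, digits = 17)),
    "image_path,score",
    paste0(paths, ",", format_full(scores))
  ), con)
  invisible(path)
}

# shortest decimal strings that round-trip double precision exactly
format_full <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write all tabular pipeline outputs
#'
#' Emits under `out_dir`:
#' \describe{
#'   \item{`sparsity_<metric>.csv`}{image x layer sparsity table at full
#'     double precision (round-trips exactly via [read_sparsity_table()]).}
#'   \item{`model_battery.csv`}{one row per model family of the battery.}
#'   \item{`per_layer.csv`}{per-layer R-squared, coefficient and p-value.}
#'   \item{`run_metadata.json`}{seeds, configuration, backend, package and
#'     R versions, and a timestamp.}
#' }
#'
#' @param results list with components `sparsity` (matrix from
#'   [sparsity_profile()]), `battery` (data.frame), `per_layer`
#'   (data.frame) and `metadata` (list); any component may be omitted.
#' @param out_dir output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  written <- character()
  if (!is.null(results$sparsity)) {
    metric <- attr(results$sparsity, "metric") %||% "gini"
    f <- file.path(out_dir, paste0("sparsity_", metric, ".csv"))
    write_sparsity_table(results$sparsity, f)
    written <- c(written, f)
  }
  if (!is.null(results$battery)) {
    f <- file.path(out_dir, "model_battery.csv")
    utils::write.csv(results$battery, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$per_layer)) {
    f <- file.path(out_dir, "per_layer.csv")
    utils::write.csv(results$per_layer, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(results$metadata)) {
    f <- file.path(out_dir, "run_metadata.json")
    meta <- results$metadata
    meta$package_version <- as.character(utils::packageVersion("sparsebeauty"))
    meta$r_version <- R.version.string
    meta$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

write_sparsity_table <- function(profile, path) {
  metric <- attr(profile, "metric") %||% "gini"
  vals <- lapply(seq_len(ncol(profile)), function(j) format_full(profile[, j]))
  names(vals) <- colnames(profile)
  df <- cbind(
    data.frame(image = rownames(profile), metric = metric,
               stringsAsFactors = FALSE),
    as.data.frame(vals, stringsAsFactors = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a sparsity table written by [write_results()]
#'
#' @param path `sparsity_<metric>.csv` file.
#' @return numeric matrix with the metric in `attr(, "metric")`.
#' @export
read_sparsity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("image", "metric")), drop = FALSE])
  rownames(m) <- df$image
  attr(m, "metric") <- unique(df$metric)
  m
}
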