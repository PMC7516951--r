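# Delimited-text result tables: comma-separated, '.' decimal, header row,
# '#'-prefixed metadata lines. Numbers at 17 significant digits so tables
# round-trip losslessly.

#' Write a result table with metadata header
#'
#' @param df data frame of numeric results.
#' @param path output file.
#' @param meta named list of metadata (tool version, parameters, seed, ...)
#'   written as `# key: value` lines above the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("dgpop ",
                               as.character(utils::packageVersion("dgpop"))),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
               con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(df))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return data frame; metadata lines are parsed into attribute `"meta"`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write a spike raster as delimited text
#'
#' One trial per row, columns `neuron_0..neuron_{n-1}`, 0/1 entries, with
#' '#' metadata lines recording the generating parameters and seed.
#'
#' @param raster a `"dg_raster"` or plain binary matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  p <- attr(raster, "params")
  meta <- list(trials = nrow(raster), n = ncol(raster))
  if (!is.null(p)) meta <- c(meta, list(h = sprintf("%.17g", p$h),
                                        alpha = sprintf("%.17g", p$alpha)))
  if (!is.null(attr(raster, "seed"))) meta$seed <- attr(raster, "seed")
  df <- as.data.frame(unclass(raster)[, , drop = FALSE])
  names(df) <- paste0("neuron_", seq_len(ncol(df)) - 1L)
  write_result_table(df, path, meta)
}

#' Read a spike raster from delimited text
#'
#' @param path file written by [write_raster()] (or any 0/1 CSV with one
#'   trial per row; '#' lines are ignored).
#' @return a binary matrix of class `"dg_raster"` (without generating
#'   parameters unless recorded in the metadata).
#' @export
read_raster <- function(path) {
  df <- read_result_table(path)
  x <- as.matrix(df)
  if (!all(x %in% c(0, 1)))
    stop("raster file must contain only 0/1 entries", call. = FALSE)
  storage.mode(x) <- "integer"
  meta <- attr(df, "meta")
  params <- NULL
  if (!is.null(meta$h) && !is.null(meta$alpha))
    params <- dg_model(ncol(x), h = as.numeric(meta$h),
                       alpha = as.numeric(meta$alpha))
  structure(x, params = params,
            seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NULL,
            class = c("dg_raster", "matrix", "array"))
}
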