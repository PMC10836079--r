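# Tabular readers/writers and result serialisation.

#' Read a data matrix from CSV/TSV
#'
#' Wide layout: one column per variable, header row of variable names. Long
#' layout: one value column plus a group column with exactly two levels; the
#' two groups are returned as separate matrices in lexicographic level order
#' (the first level becomes `x`, which fixes the sign convention of
#' two-sample statistics). Empty cells, `NA` and `NaN` are read as missing;
#' any other non-numeric cell is an error naming its row and column.
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`; default guesses from the extension.
#' @param layout `"wide"` (default) or `"long"`.
#' @param group_col Name of the grouping column (long layout; default
#'   `"group"`).
#' @return Wide: a numeric matrix. Long: a list with matrices `x` and `y`
#'   and `levels`, the two group labels in sorted order.
#' @export
read_data_matrix <- function(path, format = c("auto", "csv", "tsv"),
                             layout = c("wide", "long"),
                             group_col = "group") {
  format <- match.arg(format)
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA", "NaN"))
  to_numeric <- function(df) {
    out <- matrix(NA_real_, nrow(df), ncol(df),
                  dimnames = list(NULL, colnames(df)))
    for (j in seq_len(ncol(df))) {
      col <- df[[j]]
      if (is.numeric(col)) { out[, j] <- col; next }
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(parsed))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1]], bad[1], colnames(df)[j]), call. = FALSE)
      out[, j] <- parsed
    }
    out
  }
  if (layout == "wide") return(to_numeric(raw))
  if (!group_col %in% colnames(raw))
    stop(sprintf("group column '%s' not found", group_col), call. = FALSE)
  g <- as.character(raw[[group_col]])
  levels_ <- sort(unique(g))
  if (length(levels_) != 2)
    stop(sprintf("long layout requires exactly 2 group levels, found %d",
                 length(levels_)), call. = FALSE)
  vals <- raw[, setdiff(colnames(raw), group_col), drop = FALSE]
  m <- to_numeric(vals)
  list(x = m[g == levels_[1], , drop = FALSE],
       y = m[g == levels_[2], , drop = FALSE],
       levels = levels_)
}

result_meta <- function(result) {
  if (inherits(result, "perm_test")) {
    list(type = "perm_test", test = result$test, tail = result$tail,
         correction = result$correction, alpha = result$alpha,
         n_resamples = result$n_resamples, exhaustive = result$exhaustive,
         seed = result$seed, add_one = result$add_one,
         version = as.character(utils::packageVersion("maxperm")))
  } else if (inherits(result, "boot_effect")) {
    list(type = "boot_effect", measure = result$measure,
         measure_name = result$measure_name,
         bias_corrected = result$bias_corrected,
         correction_factor = result$correction_factor,
         n_boot = result$n_boot, alpha = result$alpha, seed = result$seed,
         paired = result$paired, variance_mode = result$variance_mode,
         version = as.character(utils::packageVersion("maxperm")))
  } else {
    stop("unsupported result type", call. = FALSE)
  }
}

#' Write a test or effect-size result to TSV or JSON
#'
#' TSV output has one row per variable with the statistic first after the
#' variable name, followed by df, estimate, p, confidence bounds and the run
#' metadata (n_resamples, correction, tail, seed) repeated per row; no
#' dichotomous decision column is ever emitted — results are continuous
#' quantities. JSON output nests the per-variable table under full metadata
#' and round-trips losslessly via [read_results()]; with
#' `save_null = TRUE` the permutation null distribution is included.
#'
#' @param result A `perm_test` or `boot_effect` object.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"` (default guesses from the extension).
#' @param save_null Include the null distribution in JSON output.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("auto", "tsv", "json"),
                          save_null = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  tab <- result$table
  meta <- result_meta(result)
  if (format == "tsv") {
    if (meta$type == "perm_test") {
      tab$n_resamples <- meta$n_resamples
      tab$correction <- meta$correction
      tab$tail <- meta$tail
    } else {
      tab$measure <- meta$measure_name
      tab$bias_corrected <- meta$bias_corrected
      tab$n_boot <- meta$n_boot
    }
    tab$seed <- meta$seed
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) format(v, digits = 17))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(meta = meta, table = result$table)
    if (save_null && !is.null(result$null_distribution))
      payload$null_distribution <- result$null_distribution
    if (meta$type == "perm_test" && !is.null(result$groups))
      payload$groups <- result$groups
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON result written by [write_results()]
#'
#' Reconstructs the result's table and metadata; numeric values round-trip
#' at full double precision.
#'
#' @param path JSON file path.
#' @return A `perm_test` or `boot_effect` object (without the resampled null
#'   distribution unless it was saved).
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- payload$meta
  tab <- as.data.frame(payload$table, stringsAsFactors = FALSE)
  if (identical(meta$type, "perm_test")) {
    structure(list(test = meta$test, table = tab,
                   null_distribution = payload$null_distribution,
                   shared_null = NULL, correction = meta$correction,
                   tail = meta$tail, alpha = meta$alpha,
                   n_resamples = meta$n_resamples,
                   exhaustive = meta$exhaustive, seed = meta$seed,
                   add_one = meta$add_one,
                   groups = if (!is.null(payload$groups))
                     as.data.frame(payload$groups) else NULL),
              class = "perm_test")
  } else {
    structure(list(table = tab, measure = meta$measure,
                   measure_name = meta$measure_name,
                   bias_corrected = meta$bias_corrected,
                   correction_factor = meta$correction_factor,
                   n_boot = meta$n_boot, alpha = meta$alpha,
                   seed = meta$seed, paired = meta$paired,
                   variance_mode = meta$variance_mode),
              class = "boot_effect")
  }
}
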