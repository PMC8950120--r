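#' Metastatistics ensembles
#'
#' A `meta_ensemble` is the per-frame record of a biased ("metastatistics")
#' simulation: one row per stored configuration with its walker id, time (ps),
#' collective-variable value and any named observable columns (enthalpy in
#' kcal/mol, volume, energy components, SASA, distances...). Frames carry a
#' multiplicity weight (default 1): degeneracy is encoded by repetition.
#'
#' @param frames data.frame with at least a `cv` column; `walker` and `time`
#'   default to 0 and the row index.
#' @param weights per-frame multiplicities, recycled; must sum to > 0.
#' @param provenance free text recorded with the ensemble.
#' @return An object of class `meta_ensemble`.
#' @export
meta_ensemble <- function(frames, weights = 1, provenance = "") {
  if (!is.data.frame(frames) || !nrow(frames)) stopf("empty frame table")
  if (is.null(frames$cv)) stopf("frame table lacks a 'cv' column")
  if (!all(is.finite(frames$cv))) stopf("non-finite CV values")
  if (is.null(frames$walker)) frames$walker <- 0L
  if (is.null(frames$time)) frames$time <- seq_len(nrow(frames)) - 1
  weights <- rep_len(weights, nrow(frames))
  if (any(weights < 0) || sum(weights) <= 0) stopf("frame weights must be >= 0 and sum > 0")
  schema <- setdiff(names(frames), c("walker", "time", "cv"))
  structure(list(frames = frames, weights = weights, schema = schema,
                 provenance = provenance),
            class = "meta_ensemble")
}

#' @export
print.meta_ensemble <- function(x, ...) {
  cat(sprintf("meta_ensemble: %d frames, %d walkers, cv in [%.3g, %.3g]\n",
              nrow(x$frames), length(unique(x$frames$walker)),
              min(x$frames$cv), max(x$frames$cv)))
  if (length(x$schema)) cat("observables:", paste(x$schema, collapse = ", "), "\n")
  invisible(x)
}

#' Normalized frame probabilities of a metastatistics
#'
#' @param meta a [meta_ensemble].
#' @return Per-frame probabilities summing to 1.
#' @export
frame_probs <- function(meta) meta$weights / sum(meta$weights)

#' Extract an observable column (or pass a numeric vector through)
#' @param meta a [meta_ensemble].
#' @param observable a column name in the schema, "cv", or a numeric vector
#'   of per-frame values.
#' @return Numeric per-frame vector.
#' @export
get_observable <- function(meta, observable) {
  if (is.numeric(observable)) {
    if (length(observable) != nrow(meta$frames))
      stopf("observable vector length %d != %d frames", length(observable), nrow(meta$frames))
    return(observable)
  }
  if (identical(observable, "cv")) return(meta$frames$cv)
  if (!observable %in% meta$schema)
    stopf("unknown observable '%s' (schema: %s)", observable,
          paste(meta$schema, collapse = ", "))
  v <- meta$frames[[observable]]
  if (!all(is.finite(v))) stopf("observable '%s' has non-finite entries", observable)
  v
}

#' Subset the frames of an ensemble
#' @param meta a [meta_ensemble].
#' @param idx integer or logical frame index.
#' @return A [meta_ensemble]; probabilities renormalize automatically.
#' @export
subset_frames <- function(meta, idx) {
  meta_ensemble(meta$frames[idx, , drop = FALSE], weights = meta$weights[idx],
                provenance = meta$provenance)
}

#' Read a metastatistics table
#'
#' Whitespace- or comma-delimited text with a header row. A `cv` column is
#' required; `walker` and `time` are optional (defaults 0 and the row index);
#' every other numeric column becomes an observable. Comment lines start
#' with '#'.
#'
#' @param path file path.
#' @param schema optional character vector of observable columns that must be
#'   present.
#' @return A [meta_ensemble].
#' @export
read_meta_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("metastatistics table not found: %s", path)
  first <- readLines(path, n = 50)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (!length(first)) stopf("empty metastatistics table: %s", path)
  sep <- if (grepl(",", first[1])) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!nrow(df)) stopf("empty metastatistics table: %s", path)
  if (is.null(df$cv)) stopf("schema error: table %s lacks a 'cv' column", path)
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stopf("non-numeric value in column '%s', data row %d of %s", cn, bad, path)
    }
    if (anyNA(df[[cn]])) stopf("missing value in column '%s', data row %d of %s",
                               cn, which(is.na(df[[cn]]))[1], path)
  }
  if (!is.null(schema)) {
    miss <- setdiff(schema, names(df))
    if (length(miss)) stopf("schema error: %s lacks column(s): %s", path,
                            paste(miss, collapse = ", "))
  }
  meta_ensemble(df, provenance = path)
}

#' Write a metastatistics table
#'
#' Tab-separated with a commented header stating units and provenance;
#' round-trips through [read_meta_table()].
#'
#' @param meta a [meta_ensemble].
#' @param path output file.
#' @export
write_meta_table <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# metastatistics table written by maxentfes",
               "# time in ps, cv dimensionless, energies kcal/mol",
               sprintf("# provenance: %s", meta$provenance)), con)
  cols <- c("walker", "time", "cv", meta$schema)
  writeLines(paste(cols, collapse = "\t"), con)
  utils::write.table(meta$frames[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
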