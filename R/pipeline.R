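#' Pipeline manifests
#'
#' A manifest is an ordered list of steps, each calling one exported
#' function with fixed arguments, with optional input-file MD5 pinning
#' (stale-input protection) and declared outputs. Re-running a manifest
#' with identical inputs reproduces outputs bit-identically for
#' deterministic steps.
#'
#' @param steps list of lists with elements `fn` (exported function name),
#'   `args` (named list), optional `inputs` (paths), `input_md5` (named
#'   character), `write` (path: the step result is written there as TSV if
#'   a data.frame, else RDS-free plain text via `format`).
#' @param seed integer seed set before the first step.
#' @param version free-text pipeline version tag.
#' @return An object of class `pipeline_manifest`.
#' @export
pipeline_manifest <- function(steps = list(), seed = 1L, version = "1") {
  structure(list(steps = steps, seed = as.integer(seed), version = version),
            class = "pipeline_manifest")
}

#' Execute a pipeline manifest
#'
#' Runs the steps in order, failing fast on the first error, logging each
#' step's name, parameters and wall time to stderr (and optionally a file).
#' Steps receive earlier results via the special argument placeholder
#' `step:<k>` (the value returned by step k).
#'
#' @param manifest a [pipeline_manifest].
#' @param log_file optional path appended with the run log.
#' @return Invisibly, the list of step results.
#' @export
run_pipeline <- function(manifest, log_file = NULL) {
  logline <- function(...) {
    msg <- sprintf(...)
    message(msg)
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  }
  set.seed(manifest$seed)
  results <- vector("list", length(manifest$steps))
  for (k in seq_along(manifest$steps)) {
    st <- manifest$steps[[k]]
    if (is.null(st$fn)) stopf("step %d lacks 'fn'", k)
    if (!is.null(st$input_md5)) {
      for (pth in names(st$input_md5)) {
        got <- unname(tools::md5sum(pth))
        if (is.na(got)) stopf("step %d: declared input missing: %s", k, pth)
        if (got != st$input_md5[[pth]])
          stopf("step %d: stale input %s (md5 %s != declared %s)", k, pth,
                got, st$input_md5[[pth]])
      }
    }
    fn <- get(st$fn, envir = asNamespace("maxentfes"))
    args <- lapply(st$args %||% list(), function(v) {
      if (is.character(v) && length(v) == 1 && startsWith(v, "step:")) {
        # "step:<k>" is step k's result; "step:<k>:<el>" one of its elements
        parts <- strsplit(v, ":", fixed = TRUE)[[1]]
        res <- results[[as.integer(parts[2])]]
        for (el in parts[-(1:2)]) res <- res[[el]]
        res
      } else v
    })
    t0 <- proc.time()[3]
    results[[k]] <- do.call(fn, args)
    logline("[maxentfes] step %d/%d %s (%.2fs)", k, length(manifest$steps),
            st$fn, proc.time()[3] - t0)
    if (!is.null(st$write)) {
      res <- results[[k]]
      if (inherits(res, "fes_profile")) res <- res$grid
      if (inherits(res, "meta_ensemble")) {
        write_meta_table(res, st$write)
      } else if (is.data.frame(res)) {
        utils::write.table(res, st$write, sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        writeLines(utils::capture.output(print(res)), st$write)
      }
      logline("[maxentfes] step %d wrote %s", k, st$write)
    }
  }
  invisible(results)
}
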