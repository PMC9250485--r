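# Funnel accounting: an ordered record of how many variants enter and
# survive each filtering stage, with the surviving variant ids, so the
# whole prioritization can be audited and serialized.

#' Create an empty funnel report
#'
#' A funnel report is an ordered list of stages; each stage records its
#' name, the number of variants entering and leaving, and the surviving
#' variant ids.  Stages must chain: the input ids of stage *k* are the
#' surviving ids of stage *k - 1*.
#'
#' @return object of class `funnel_report`.
#' @seealso [funnel_add_stage()], [write_funnel_report()]
#' @export
funnel_report <- function() {
  structure(list(stages = list()), class = "funnel_report")
}

#' Append a stage to a funnel report
#'
#' @param report a [funnel_report()].
#' @param name stage name.
#' @param ids_in character vector of variant ids entering the stage.
#' @param ids_out character vector of surviving variant ids; must be a
#'   subset of `ids_in`.
#' @return the updated report.
#' @export
funnel_add_stage <- function(report, name, ids_in, ids_out) {
  stopifnot(inherits(report, "funnel_report"))
  ids_in <- as.character(ids_in); ids_out <- as.character(ids_out)
  if (!all(ids_out %in% ids_in))
    stop_famvar("stage '%s': surviving ids are not a subset of input ids", name)
  k <- length(report$stages)
  if (k > 0L) {
    prev <- report$stages[[k]]$surviving_ids
    if (!setequal(ids_in, prev))
      stop_famvar("stage '%s': input ids differ from previous stage's survivors",
                  name)
  }
  report$stages[[k + 1L]] <- list(name = name,
                                  n_in = length(ids_in),
                                  n_out = length(ids_out),
                                  surviving_ids = ids_out)
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant prioritization funnel\n")
  for (s in x$stages)
    cat(sprintf("  %-22s %6d -> %6d\n", s$name, s$n_in, s$n_out))
  invisible(x)
}

#' Summarize a funnel report as a data frame
#' @param object a [funnel_report()].
#' @param ... unused.
#' @return data frame with columns `stage`, `n_in`, `n_out`.
#' @export
summary.funnel_report <- function(object, ...) {
  data.frame(stage = vapply(object$stages, `[[`, "", "name"),
             n_in = vapply(object$stages, `[[`, 0L, "n_in"),
             n_out = vapply(object$stages, `[[`, 0L, "n_out"),
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a funnel report
#'
#' The JSON form holds the full report (including surviving ids); the
#' optional TSV is a human-readable per-stage count table.
#'
#' @param report a [funnel_report()].
#' @param path output JSON path.
#' @param tsv optional path for a TSV stage-count table.
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "funnel_report"))
  jsonlite::write_json(list(stages = report$stages), path,
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv))
    utils::write.table(summary.funnel_report(report), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_funnel_report
#' @export
read_funnel_report <- function(path) {
  obj <- jsonlite::read_json(path)
  rep <- funnel_report()
  rep$stages <- lapply(obj$stages, function(s)
    list(name = s$name, n_in = as.integer(s$n_in), n_out = as.integer(s$n_out),
         surviving_ids = as.character(unlist(s$surviving_ids))))
  rep
}
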