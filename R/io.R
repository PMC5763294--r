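#' Write diffusion predictions to TSV
#'
#' Fixed eight-column layout: `protein_id`, `term_id`, `namespace`,
#' `source_protein`, `source_term`, `iteration`, `ideal_value`,
#' `selected_value`; rows sorted by (iteration, protein, term); floats at six
#' decimals. Two runs on identical inputs produce byte-identical files.
#'
#' @param state a `diffusion_state` from [diffuse()], or its history
#'   data.frame.
#' @param path output file path.
#' @param dag the companion [go_dag()] (supplies the namespace column).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(state, path, dag) {
  hist <- if (inherits(state, "diffusion_state")) state$history else state
  out <- data.frame(
    protein_id = hist$protein,
    term_id = hist$term,
    namespace = if (nrow(hist)) unname(dag$namespace[hist$term]) else character(0),
    source_protein = hist$source_protein,
    source_term = hist$source_term,
    iteration = hist$iteration,
    ideal_value = sprintf("%.6f", hist$ideal_value),
    selected_value = sprintf("%.6f", hist$selected_value),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$iteration, out$protein_id, out$term_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV back into a history data.frame
#'
#' @param path file written by [write_predictions()].
#' @return data.frame with the diffusion-history columns.
#' @export
read_predictions <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(rep("character", 5L), "integer",
                                        "numeric", "numeric"))
  data.frame(iteration = x$iteration, protein = x$protein_id,
             term = x$term_id, source_protein = x$source_protein,
             source_term = x$source_term, ideal_value = x$ideal_value,
             selected_value = x$selected_value, stringsAsFactors = FALSE)
}

#' Write a JSON sidecar echoing the configuration of an output file
#'
#' Every CLI output is accompanied by `<output>.config.json` recording the
#' inputs and flags that produced it.
#'
#' @param config named list of configuration values.
#' @param output_path the output file the sidecar describes.
#' @return the sidecar path, invisibly.
#' @export
write_config_sidecar <- function(config, output_path) {
  sidecar <- paste0(output_path, ".config.json")
  jsonlite::write_json(config, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(sidecar)
}
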