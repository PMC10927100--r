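#' Export analysis results to standard text formats
#'
#' Dispatches on the result type: distance matrices and trait matrices go to
#' CSV, trees (`consensus_tree`, `phylo`, `hclust`) to Newick with bootstrap
#' supports as internal node labels, SES tables, correlograms and disparity
#' tables to tidy CSV, and any list-like result to JSON. Written files round
#' trip through the corresponding reader where one exists.
#'
#' @param x result object.
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path, format = c("csv", "json", "newick")) {
  format <- match.arg(format)
  if (inherits(x, "dist_matrix") && format == "csv") {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  } else if (inherits(x, "trait_matrix") && format == "csv") {
    write_trait_matrix(x, path)
  } else if (inherits(x, c("consensus_tree", "phylo", "hclust")) &&
             format == "newick") {
    phy <- if (inherits(x, "consensus_tree")) x$tree
           else if (inherits(x, "hclust")) ape::as.phylo(x) else x
    ape::write.tree(phy, file = path)
  } else if (inherits(x, c("ses_table", "data.frame")) && format == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "correlogram_result") && format == "csv") {
    utils::write.csv(x$classes, path, row.names = FALSE)
  } else if (inherits(x, "disparity_result") && format == "csv") {
    utils::write.csv(x$table, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(.jsonable(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop(sprintf("unsupported export: %s -> %s",
                 paste(class(x), collapse = "/"), format), call. = FALSE)
  }
  invisible(path)
}

.jsonable <- function(x) {
  if (inherits(x, "dist_matrix")) {
    list(metric = dist_metric(x), labels = rownames(x),
         values = unclass(unname(x)))
  } else if (inherits(x, "ses_result")) {
    unclass(x)
  } else if (is.list(x)) {
    lapply(x, function(el) if (is.list(el)) .jsonable(el) else el)
  } else {
    x
  }
}
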