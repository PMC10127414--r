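#' Default network node set
#'
#' The 17 nodes of the subcortical structural covariance network: the five
#' basal forebrain subfields (Ch4p, Ch4a-i, Ch3, NSP, Ch1/2) followed by the
#' twelve right-hippocampal subfields.  Node names match the canonical column
#' labels of the cohort table (including characters such as `"-"` and `"/"`);
#' use [sanitize_names()] for filesystem-safe variants.
#'
#' @return Character vector of 17 unique node names.
#' @seealso [sanitize_names()]
#' @export
default_node_set <- function() {
  c(scn_bf_subfields, scn_hc_subfields)
}

#' Validate a node set
#'
#' @param nodes Character vector of node (ROI) names.
#' @return The node set, invisibly, after validation.
#' @export
validate_node_set <- function(nodes) {
  if (!is.character(nodes) || length(nodes) < 2) {
    stop("a node set must be a character vector with at least 2 names")
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  invisible(nodes)
}

#' Filesystem-safe aliases for node and column names
#'
#' Canonical ROI labels such as `"Ch4a-i"`, `"Ch1/2"` or `"Molecular layer"`
#' are kept verbatim in cohort tables for traceability; this helper maps them
#' to safe tokens (`"Ch4a_i"`, `"Ch1_2"`, `"Molecular_layer"`) for use in
#' file names.
#'
#' @param x Character vector of names.
#' @return Character vector of the same length, named by the input, with all
#'   non-alphanumeric runs replaced by a single underscore.
#' @export
sanitize_names <- function(x) {
  out <- gsub("[^A-Za-z0-9]+", "_", x)
  out <- gsub("^_+|_+$", "", out)
  stats::setNames(out, x)
}
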