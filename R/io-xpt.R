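#' Read real NHANES SAS transport files into the participant layout
#'
#' Replication path for the 1999-2000 and 2001-2002 NHANES cycles: reads
#' a set of SAS transport (XPT) files with `foreign::read.xport()`,
#' merges them on the participant sequence number, and renames survey
#' item codes to the participant-record columns via a user-editable
#' mapping (the item codes themselves are not shipped; they are a
#' configuration the user supplies with the downloaded files). Four-year
#' weights for a two-cycle analysis are conventionally half of each
#' cycle's two-year MEC exam weight; set `halve_weights = TRUE` to apply
#' that.
#'
#' @param paths Character vector of XPT file paths (demographics, blood
#'   pressure, lipids, etc. for one cycle).
#' @param mapping Named character vector or list: names are participant
#'   columns (`"weight"`, `"age"`, `"total_cholesterol"`, ...), values
#'   the NHANES variable names; or a path to a YAML file of the same.
#' @param id_var Join key, by default `"SEQN"`.
#' @param halve_weights Halve the weight column (two-cycle convention).
#' @return Participant tibble in the layout [apply_inclusion()] consumes.
#' @export
read_cohort_xpt <- function(paths, mapping, id_var = "SEQN",
                            halve_weights = FALSE) {
  if (!requireNamespace("foreign", quietly = TRUE))
    stop("reading XPT files requires the 'foreign' package")
  tabs <- lapply(paths, foreign::read.xport)
  merged <- Reduce(function(a, b) merge(a, b, by = id_var, all = TRUE), tabs)
  out <- map_nhanes_columns(merged, mapping, id_var = id_var)
  if (halve_weights && "weight" %in% names(out))
    out$weight <- out$weight / 2
  out
}

#' @rdname read_cohort_xpt
#' @param data Merged raw data frame (item-coded columns).
#' @export
map_nhanes_columns <- function(data, mapping, id_var = "SEQN") {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- yaml::read_yaml(mapping)
  mapping <- unlist(mapping)
  missing_items <- setdiff(unname(mapping), names(data))
  if (length(missing_items))
    stop("mapped items absent from input: ",
         paste(missing_items, collapse = ", "))
  out <- as_tibble(data[, unname(mapping), drop = FALSE])
  names(out) <- names(mapping)
  if (id_var %in% names(data) && !"participant_id" %in% names(out))
    out$participant_id <- as.character(data[[id_var]])
  out
}
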