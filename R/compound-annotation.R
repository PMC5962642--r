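#' Read and validate a compound annotation table
#'
#' Reads the screen's compound set: one row per compound with its peak plasma
#' concentration (C-max, in micromolar), FDA DILI-concern label
#' (no / ambiguous / less / most, or control for reference treatments), the
#' derived two-class severity label, and the eight-level hepatotoxicity class.
#'
#' The table must be comma-separated UTF-8 with header
#' `name,abbreviation,cmax_uM,dili_concern,severity,hepatotox_class,is_control`.
#' The `severity` column may be left empty; it is (re)derived from
#' `dili_concern` via [assign_severity()] and, when present, checked for
#' consistency.
#'
#' @param path Path to the CSV file. Defaults to the annotation table
#'   packaged with stressdyn (the 123-compound screen set: 118 drugs with
#'   known DILI liability plus 5 reference controls).
#' @return A tibble with one validated row per compound, in file order.
#' @examples
#' ann <- read_compound_table()
#' class_counts(ann)
#' @export
read_compound_table <- function(path = stressdyn_annotation_path()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           name = "character", abbreviation = "character",
                           cmax_uM = "numeric", dili_concern = "character",
                           severity = "character", hepatotox_class = "integer",
                           is_control = "logical"
                         ))
  ann <- as_tibble(raw)
  validate_compound_table(ann)
  # severity is derivable; trust dili_concern and re-derive
  ann$severity <- assign_severity(ann$dili_concern)
  ann
}

#' Path to the packaged compound annotation table
#' @return File path of the CSV shipped in `inst/extdata`.
#' @export
stressdyn_annotation_path <- function() {
  system.file("extdata", "compound_annotations.csv", package = "stressdyn",
              mustWork = TRUE)
}

#' Write a compound annotation table
#'
#' Inverse of [read_compound_table()]; a read / write / read cycle
#' round-trips to an identical table.
#'
#' @param annotations Validated annotation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(annotations, path) {
  validate_compound_table(annotations)
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

validate_compound_table <- function(ann) {
  required <- c("name", "abbreviation", "cmax_uM", "dili_concern",
                "severity", "hepatotox_class", "is_control")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!ann$dili_concern %in% DILI_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown dili_concern token(s) in row(s) ",
                 paste(bad, collapse = ", "), ": ",
                 paste(unique(ann$dili_concern[bad]), collapse = ", ")))
  }
  dup <- which(duplicated(ann$abbreviation))
  if (length(dup) > 0) {
    abort(paste0("duplicate abbreviation(s) in row(s) ",
                 paste(dup, collapse = ", "), ": ",
                 paste(unique(ann$abbreviation[dup]), collapse = ", ")))
  }
  ctrl_mismatch <- which(ann$is_control != (ann$dili_concern == "control"))
  if (length(ctrl_mismatch) > 0) {
    abort(paste0("is_control inconsistent with dili_concern in row(s) ",
                 paste(ctrl_mismatch, collapse = ", ")))
  }
  bad_cmax <- which(!ann$is_control &
                      (is.na(ann$cmax_uM) | ann$cmax_uM <= 0))
  if (length(bad_cmax) > 0) {
    abort(paste0("non-control compounds need a positive cmax_uM; row(s) ",
                 paste(bad_cmax, collapse = ", ")))
  }
  bad_hep <- which(!is.na(ann$hepatotox_class) &
                     !(ann$hepatotox_class %in% 1:8))
  if (length(bad_hep) > 0) {
    abort(paste0("hepatotox_class outside 1-8 in row(s) ",
                 paste(bad_hep, collapse = ", ")))
  }
  sev_given <- !is.na(ann$severity) & ann$severity != ""
  expect_sev <- assign_severity(ann$dili_concern)
  sev_bad <- which(sev_given & ann$severity != expect_sev)
  if (length(sev_bad) > 0) {
    abort(paste0("severity inconsistent with dili_concern in row(s) ",
                 paste(sev_bad, collapse = ", ")))
  }
  invisible(ann)
}

#' Map DILI-concern labels to the two-class severity labels
#'
#' The binary classification problem groups most-severe-DILI-concern drugs as
#' `severe` and all other annotated drugs (no-, ambiguous- and
#' less-DILI-concern) as `non_severe`; reference controls stay `control`.
#'
#' @param dili_concern Character vector of labels in
#'   `c("no", "ambiguous", "less", "most", "control")`.
#' @return Character vector of `"severe"`, `"non_severe"` or `"control"`.
#' @examples
#' assign_severity(c("most", "ambiguous", "control"))
#' @export
assign_severity <- function(dili_concern) {
  bad <- setdiff(unique(dili_concern), DILI_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("invalid dili_concern token(s): ",
                 paste(bad, collapse = ", ")))
  }
  case_when(
    dili_concern == "most" ~ "severe",
    dili_concern == "control" ~ "control",
    TRUE ~ "non_severe"
  )
}

#' Count compounds per DILI-concern label and per severity class
#'
#' @param annotations Annotation tibble from [read_compound_table()].
#' @return A one-row tibble with counts per DILI-concern label
#'   (`n_no`, `n_ambiguous`, `n_less`, `n_most`, `n_control`), per severity
#'   class (`n_severe`, `n_non_severe`), the non-control total
#'   (`n_annotated`) and the total row count (`n_total`).
#' @export
class_counts <- function(annotations) {
  dc <- annotations$dili_concern
  sev <- assign_severity(dc)
  tibble(
    n_no = sum(dc == "no"),
    n_ambiguous = sum(dc == "ambiguous"),
    n_less = sum(dc == "less"),
    n_most = sum(dc == "most"),
    n_control = sum(dc == "control"),
    n_severe = sum(sev == "severe"),
    n_non_severe = sum(sev == "non_severe"),
    n_annotated = sum(dc != "control"),
    n_total = length(dc)
  )
}
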