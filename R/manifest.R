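#' Cohort manifest
#'
#' The unit of cohort I/O: one row per slide with its patient, its
#' tissue-submitting site, and declared outcome columns. Outcome columns are
#' declared `"categorical"` or `"continuous"`; missing outcome values are
#' kept as `NA` (written as the empty string), never dropped.
#'
#' Invariants enforced at construction: slide ids are unique, every row has
#' a non-empty slide/patient/site id, and a patient maps to exactly one site.
#'
#' @param slides data.frame with columns `slide_id`, `patient_id`, `site_id`
#'   plus one column per declared outcome
#' @param outcomes named character vector mapping outcome column names to
#'   `"categorical"` or `"continuous"`
#' @return an object of class `cohort_manifest`
#' @export
cohort_manifest <- function(slides, outcomes = character()) {
  slides <- as.data.frame(slides, stringsAsFactors = FALSE)
  req <- c("slide_id", "patient_id", "site_id")
  miss <- setdiff(req, names(slides))
  if (length(miss)) stop("manifest lacks required column(s): ",
                         paste(miss, collapse = ", "))
  outcomes <- validate_outcome_schema(outcomes)
  lack <- setdiff(names(outcomes), names(slides))
  if (length(lack)) stop("declared outcome column(s) absent: ",
                         paste(lack, collapse = ", "))
  for (cl in req) {
    slides[[cl]] <- as.character(slides[[cl]])
    bad <- which(is.na(slides[[cl]]) | !nzchar(slides[[cl]]))
    if (length(bad)) stop("row ", bad[1], ": empty or missing ", cl)
  }
  if (anyDuplicated(slides$slide_id))
    stop("duplicate slide_id: ",
         slides$slide_id[duplicated(slides$slide_id)][1])
  ps <- unique(slides[, c("patient_id", "site_id")])
  dup <- ps$patient_id[duplicated(ps$patient_id)]
  if (length(dup))
    stop("patient ", dup[1], " is mapped to more than one site")
  for (col in names(outcomes)) {
    slides[[col]] <- if (outcomes[[col]] == "continuous")
      as.numeric(slides[[col]]) else as.character(slides[[col]])
  }
  slides <- slides[, c(req, names(outcomes)), drop = FALSE]
  rownames(slides) <- NULL
  structure(list(slides = slides, outcomes = outcomes),
            class = "cohort_manifest")
}

validate_outcome_schema <- function(outcomes) {
  if (is.list(outcomes)) outcomes <- unlist(outcomes)
  outcomes <- as.character(outcomes) |> setNames(names(outcomes))
  if (length(outcomes) && is.null(names(outcomes)))
    stop("outcome declarations must be a named vector")
  bad <- setdiff(outcomes, c("categorical", "continuous"))
  if (length(bad)) stop("outcome kind must be categorical or continuous, got: ",
                        paste(bad, collapse = ", "))
  outcomes
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest: %d slides, %d patients, %d sites, %d outcome column(s)>\n",
              nrow(x$slides), length(unique(x$slides$patient_id)),
              length(unique(x$slides$site_id)), length(x$outcomes)))
  invisible(x)
}

#' Read a cohort manifest from CSV
#'
#' The manifest dialect is comma-separated UTF-8 with a header row; the
#' empty string encodes a missing outcome value. All `cohort_manifest`
#' invariants are checked on read.
#'
#' @param path CSV file path
#' @param outcomes named character vector declaring outcome columns, e.g.
#'   `c(er_status = "categorical", age = "continuous")`
#' @return a [cohort_manifest()]
#' @export
read_manifest <- function(path, outcomes = character()) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- tryCatch(
    read.csv(path, colClasses = "character", na.strings = "",
             check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed manifest ", path, ": ",
                             conditionMessage(e)))
  cohort_manifest(df, outcomes)
}

#' Write a cohort manifest to CSV
#'
#' Inverse of [read_manifest()]; missing outcome values are written as the
#' empty string so that write/read round trips are cell-exact.
#'
#' @param manifest a [cohort_manifest()]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  write.csv(manifest$slides, path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

# One row per patient (first slide's outcomes; patients have one site by
# invariant). Used wherever the patient, not the slide, is the unit.
patient_table <- function(manifest) {
  sl <- manifest$slides
  sl[!duplicated(sl$patient_id), c("patient_id", "site_id", names(manifest$outcomes)),
     drop = FALSE]
}
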