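#' Read a subject table
#'
#' Reads a CSV (comma) or TSV (tab; extensions `.tsv`/`.txt`) subject table
#' and validates the schema. Required columns: `subject_id`, `status`
#' (`case`/`control`), `sex` (`male`/`female`), `lmp2` (`RR`/`RH`/`HH` or
#' empty), `a02_carrier` and `drb115_carrier` (`yes`/`no`/`unknown`),
#' `onset_age` (years, cases only), `cohort`. Schema violations are reported
#' with the offending row numbers.
#'
#' @param path file path.
#' @return validated subject data.frame.
#' @export
read_subjects <- function(path) {
  d <- read_delim_auto(path)
  need <- c("subject_id", "status", "sex", "lmp2", "a02_carrier",
            "drb115_carrier", "onset_age", "cohort")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$lmp2[d$lmp2 %in% c("", "NA")] <- NA_character_
  d$onset_age <- suppressWarnings(as.numeric(d$onset_age))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("invalid %s at row(s) %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!d$status %in% c("case", "control"), "status")
  bad(!d$sex %in% c("male", "female"), "sex")
  bad(!is.na(d$lmp2) & !d$lmp2 %in% c("RR", "RH", "HH"), "lmp2 genotype")
  bad(!d$a02_carrier %in% c("yes", "no", "unknown"), "a02_carrier")
  bad(!d$drb115_carrier %in% c("yes", "no", "unknown"), "drb115_carrier")
  bad(d$status == "control" & !is.na(d$onset_age),
      "onset_age (controls cannot have one)")
  d
}

#' Read a digestion table
#'
#' Reads a CSV/TSV digestion time-course table with columns `set_id`,
#' `preparation_id`, `genotype` (`RR`/`RH`/`HH`), `pa28`
#' (`present`/`absent`), `time_min`, `substrate_signal`, `frag_1_9`,
#' `frag_10_18`, `frag_19_28`. Violations are reported with row numbers.
#'
#' @param path file path.
#' @return validated digestion data.frame.
#' @export
read_digestion <- function(path) {
  d <- read_delim_auto(path)
  check_digestion(d)
  num <- c("time_min", "substrate_signal", "frag_1_9", "frag_10_18",
           "frag_19_28")
  for (col in num) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("invalid %s at row(s) %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(!d$genotype %in% c("RR", "RH", "HH"), "genotype")
  bad(!d$pa28 %in% c("present", "absent"), "pa28")
  bad(is.na(d$time_min) | d$time_min < 0, "time_min")
  bad(is.na(d$substrate_signal) | d$substrate_signal < 0, "substrate_signal")
  d
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a results object as JSON
#'
#' Serializes a (possibly nested) results list to JSON with scalars unboxed
#' and full numeric precision, so that identical inputs and seeds produce
#' byte-identical files.
#'
#' @param x results list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
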