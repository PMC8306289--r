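#' @keywords internal
GROUP_LEVELS <- c(paste0("G", 1:6), "DONOR")

#' @keywords internal
TIMEPOINT_LEVELS <- paste0("T", 0:5)

#' Validate a sample metadata table
#'
#' Checks the contract shared by all downstream analyses: donor samples carry
#' group `DONOR`, no timepoint, and role `donor`; recipient samples carry a
#' group `G1`..`G6`, a timepoint `T0`..`T5`, and role `recipient`; and no
#' recipient (subject, timepoint) combination is duplicated.
#'
#' @param metadata data.frame with columns `sample_id`, `subject_id`,
#'   `group`, `timepoint`, `role`.
#' @return The validated data.frame (invisibly unchanged), with `timepoint`
#'   as character and `NA` for donors.
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "subject_id", "group", "timepoint", "role")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  metadata$timepoint <- as.character(metadata$timepoint)
  metadata$timepoint[!is.na(metadata$timepoint) &
                       metadata$timepoint == ""] <- NA_character_

  fail_row <- function(rows, why) {
    stop(sprintf("metadata row(s) %s: %s", paste(rows, collapse = ", "), why),
         call. = FALSE)
  }
  dup <- which(duplicated(metadata$sample_id))
  if (length(dup)) fail_row(dup, "duplicated sample_id")
  bad_group <- which(!metadata$group %in% GROUP_LEVELS)
  if (length(bad_group)) {
    fail_row(bad_group, paste0("unknown group label (expected ",
                               paste(GROUP_LEVELS, collapse = "/"), ")"))
  }
  bad_role <- which(!metadata$role %in% c("donor", "recipient"))
  if (length(bad_role)) fail_row(bad_role, "role must be 'donor' or 'recipient'")

  is_donor <- metadata$role == "donor"
  mismatch <- which(is_donor != (metadata$group == "DONOR"))
  if (length(mismatch)) fail_row(mismatch, "role=donor if and only if group=DONOR")
  donor_tp <- which(is_donor & !is.na(metadata$timepoint))
  if (length(donor_tp)) fail_row(donor_tp, "donor samples must not carry a timepoint")
  rec_no_tp <- which(!is_donor & is.na(metadata$timepoint))
  if (length(rec_no_tp)) fail_row(rec_no_tp, "recipient samples require a timepoint")
  bad_tp <- which(!is_donor & !metadata$timepoint %in% TIMEPOINT_LEVELS)
  if (length(bad_tp)) fail_row(bad_tp, "timepoint must be one of T0..T5")

  rec <- metadata[!is_donor, ]
  key <- paste(rec$subject_id, rec$timepoint)
  if (anyDuplicated(key)) {
    fail_row(which(!is_donor)[duplicated(key)],
             "duplicated (subject_id, timepoint) among recipients")
  }
  metadata
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `group`
#'   (`G1`..`G6` or `DONOR`), `timepoint` (`T0`..`T5`, empty for donors) and
#'   `role` (`donor`/`recipient`).
#' @return Validated metadata data.frame (see [validate_metadata()]).
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  validate_metadata(md)
}

#' Write sample metadata to TSV
#' @param metadata metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Subset helpers used across modules ----------------------------------------

donor_sample_ids <- function(metadata) {
  metadata$sample_id[metadata$role == "donor"]
}

group_sample_ids <- function(metadata, group, timepoint = NULL) {
  keep <- metadata$role == "recipient" & metadata$group == group
  if (!is.null(timepoint)) keep <- keep & metadata$timepoint %in% timepoint
  metadata$sample_id[keep]
}

check_samples_present <- function(table, ids) {
  missing <- setdiff(ids, rownames(table))
  if (length(missing)) {
    stop("sample(s) in metadata missing from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
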