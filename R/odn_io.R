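# Reading, writing and labelling of oligodeoxynucleotide (ODN) records.
#
# An ODN record set is an ordinary data.frame with columns
#   id        character, unique identifier
#   sequence  character, uppercase DNA over {A,C,G,T}
#   activity  numeric reporter-assay score (optional, NA when unknown)
#   label     character "high"/"low" (optional, NA when unassigned)

#' Construct a validated set of ODN records
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of DNA sequences; lowercase is accepted
#'   and uppercased, any character outside A/C/G/T is an error.
#' @param activity optional numeric activity scores (reporter-assay optical
#'   density, unitless, typically in \[0, 1.14\]).
#' @param label optional character vector of `"high"`/`"low"` class labels.
#' @return data.frame with columns `id`, `sequence`, `activity`, `label`.
#' @export
odn_records <- function(id, sequence, activity = NULL, label = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    abort("duplicate record id '%s'", id[anyDuplicated(id)])
  }
  n <- length(id)
  if (length(sequence) != n) abort("id and sequence lengths differ")
  sequence <- if (n) validate_sequences(as.character(sequence), id) else character(0)
  if (is.null(activity)) activity <- rep(NA_real_, n)
  if (is.null(label)) label <- rep(NA_character_, n)
  activity <- as.numeric(activity)
  if (any(!is.na(activity) & activity < 0)) abort("negative activity score")
  label <- as.character(label)
  if (any(!is.na(label) & !label %in% c("high", "low"))) {
    abort("labels must be 'high' or 'low'")
  }
  data.frame(
    id = id, sequence = sequence, activity = activity, label = label,
    stringsAsFactors = FALSE
  )
}

#' Read ODN sequences from a FASTA file
#'
#' Sequences are uppercased; any residue outside A/C/G/T (including IUPAC
#' ambiguity codes and gaps) is rejected with an error naming the record.
#'
#' @param path FASTA file path.
#' @return ODN record data.frame (activity and label are `NA`).
#' @export
read_odn_fasta <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(set))
  odn_records(id = ids, sequence = as.character(set))
}

#' Write ODN sequences to a FASTA file
#'
#' @param records ODN record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_odn_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an ODN activity table
#'
#' Expects delimited text (tab or comma, auto-detected from the header line)
#' with a header naming at least the columns `id`, `sequence` and `activity`.
#'
#' @param path file path.
#' @return ODN record data.frame with parsed activity (label `NA`).
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) abort("empty file: %s", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("id", "sequence", "activity")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort("activity table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    abort("duplicate id '%s' in activity table", tab$id[anyDuplicated(tab$id)])
  }
  act <- suppressWarnings(as.numeric(tab$activity))
  bad <- which(is.na(act))
  if (length(bad)) {
    abort("non-numeric activity '%s' for id '%s' (row %d)",
          tab$activity[bad[1]], tab$id[bad[1]], bad[1])
  }
  odn_records(id = tab$id, sequence = tab$sequence, activity = act)
}

#' Write an ODN activity table
#'
#' @param records ODN record data.frame with activity values.
#' @param path output path (tab-delimited, header `id sequence activity`).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(records, path) {
  write.table(records[, c("id", "sequence", "activity")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign high/low activity class labels
#'
#' An ODN is labelled `"high"` when its activity score is at or above the
#' cutoff and `"low"` otherwise. The boundary is inclusive: a score exactly
#' equal to the cutoff is high activity.
#'
#' @param records ODN record data.frame; every record must have an activity.
#' @param cutoff activity threshold (default 0.4).
#' @return the records with the `label` column filled in.
#' @export
assign_labels <- function(records, cutoff = 0.4) {
  stopifnot(cutoff > 0)
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$activity)) {
    abort("record '%s' has no activity value",
          records$id[which(is.na(records$activity))[1]])
  }
  records$label <- ifelse(records$activity >= cutoff, "high", "low")
  records
}

#' Count labelled records per class
#'
#' @param records labelled ODN record data.frame.
#' @return named integer vector `c(high = ..., low = ...)`.
#' @export
label_counts <- function(records) {
  c(high = sum(records$label == "high", na.rm = TRUE),
    low = sum(records$label == "low", na.rm = TRUE))
}
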