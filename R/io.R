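# CSV dialect: UTF-8, comma-separated, dot decimal, mandatory header row,
# '#'-prefixed comment lines carry provenance. Numeric columns are written
# with 12 significant digits so a write/read round trip is lossless at the
# precision the estimators care about.

provenance_lines <- function(seed = NULL) {
  c(
    paste0("# betakin ", as.character(utils::packageVersion("betakin"))),
    if (!is.null(seed)) paste0("# seed ", seed)
  )
}

write_csv_prov <- function(df, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", blank.lines.skip = TRUE,
                    strip.white = TRUE),
    error = function(e) stop("malformed CSV ", path, ": ", conditionMessage(e))
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (header row with these names is mandatory)")
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in column ", col, " of ", path,
           if (!is.na(bad)) paste0(" (data line ", bad, ")"))
    }
  }
  df
}

#' Read a saturation-curve CSV
#'
#' Expects columns `substrate_mM` and `rate_uM_per_min` (an optional
#' `replicate` column is carried through untouched).
#'
#' @param path CSV file path.
#' @return A [saturation_curve()].
#' @export
read_saturation <- function(path) {
  df <- read_csv_checked(path, c("substrate_mM", "rate_uM_per_min"))
  out <- saturation_curve(df$substrate_mM, df$rate_uM_per_min)
  if (!is.null(df$replicate)) out$replicate <- df$replicate
  out
}

#' Read / write a cascade time course as CSV
#'
#' Columns: `time_h` plus the six species. Numeric values round-trip at 12
#' significant digits.
#'
#' @param path CSV file path.
#' @param course A `cascade_timecourse` data frame.
#' @param seed Optional seed recorded in the provenance header.
#' @return `read_timecourse`: a `cascade_timecourse`;
#'   `write_timecourse`: the path, invisibly.
#' @export
read_timecourse <- function(path) {
  df <- read_csv_checked(path, c("time_h", CASCADE_SPECIES))
  class(df) <- c("cascade_timecourse", "data.frame")
  df
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(course, path, seed = NULL) {
  stopifnot(all(c("time_h", CASCADE_SPECIES) %in% names(course)))
  write_csv_prov(as.data.frame(course)[c("time_h", CASCADE_SPECIES)], path,
                 seed = seed)
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file path (single- or multi-record).
#' @param id Optional record identifier; by default the first record is used
#'   and a warning is raised when others are present.
#' @return A single upper-case amino-acid sequence string.
#' @export
read_fasta <- function(path, id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta requires the Biostrings package")
  }
  if (!file.exists(path)) stop("input file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  if (is.null(id)) {
    if (length(seqs) > 1) {
      warning("FASTA has ", length(seqs), " records; using the first (",
              names(seqs)[1], ")")
    }
    rec <- seqs[[1]]
  } else {
    hit <- which(sub("\\s.*$", "", names(seqs)) == id)
    if (!length(hit)) stop("FASTA record not found: ", id)
    rec <- seqs[[hit[1]]]
  }
  toupper(as.character(rec))
}
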