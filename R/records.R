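chain_cols <- function() c("cause_a", "cause_b", "cause_c", "cause_d")

record_columns <- function() {
  c("record_id", "age", "sex", "region", chain_cols(), "history", "underlying")
}

#' Validate a data frame of death records
#'
#' A death record is one decedent: a `record_id`, integer `age` in years,
#' `sex` (`male`/`female`), an opaque `region` identifier, an ordered
#' cause-of-death chain of 1-4 ICD-10 codes (`cause_a` is the direct cause,
#' `cause_b`..`cause_d` the antecedent conditions), a `history` field of
#' zero or more past-medical-history codes separated by `";"`, and an
#' optional labeled `underlying` cause (required for training/evaluation).
#'
#' Enforced invariants: age >= 0; chain length 1-4 with no gaps and pairwise
#' distinct codes; all codes syntactically valid ICD-10 (normalized on
#' ingestion); if `underlying` is present it must be a member of the chain
#' or the history; `record_id` unique and delimiter-free.
#'
#' @param df data frame with columns `record_id, age, sex, region, cause_a`
#'   (required) and `cause_b, cause_c, cause_d, history, underlying`
#'   (optional; missing columns are treated as empty).
#' @param strict if `TRUE` (default) any invalid row aborts with an error
#'   naming the record and the reason; if `FALSE` invalid rows are dropped
#'   with a warning reporting how many were skipped.
#' @return the validated, normalized records: a data frame of class
#'   `death_records` with empty fields stored as `NA`.
#' @export
as_death_records <- function(df, strict = TRUE) {
  required <- c("record_id", "age", "sex", "region", "cause_a")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(record_columns(), names(df))) df[[col]] <- ""
  df <- df[record_columns()]
  for (col in record_columns()) {
    v <- df[[col]]
    v[is.na(v)] <- ""
    df[[col]] <- trimws(as.character(v))
  }

  n <- nrow(df)
  problems <- character(n)
  note <- function(i, msg) {
    problems[i] <<- ifelse(nzchar(problems[i]),
                           paste(problems[i], msg, sep = "; "), msg)
  }

  bad_age <- !grepl("^[0-9]+$", df$age)
  for (i in which(bad_age)) note(i, "age must be a non-negative integer")
  bad_sex <- !(df$sex %in% gender_levels())
  for (i in which(bad_sex)) note(i, "sex must be 'male' or 'female'")
  bad_id <- !nzchar(df$record_id) | grepl("[,;]", df$record_id)
  for (i in which(bad_id)) note(i, "record_id empty or contains a delimiter")
  if (anyDuplicated(df$record_id[nzchar(df$record_id)])) {
    dup <- unique(df$record_id[duplicated(df$record_id)])
    stop("duplicate record_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_region <- !nzchar(df$region) | grepl("[,;]", df$region)
  for (i in which(bad_region)) note(i, "region empty or contains a delimiter")

  norm_code <- function(x) {
    tryCatch(parse_icd10(x), error = function(e) NA_character_)
  }
  for (i in seq_len(n)) {
    chain_raw <- unlist(df[i, chain_cols()], use.names = FALSE)
    present <- nzchar(chain_raw)
    if (!present[1L]) note(i, "chain is empty (cause_a required)")
    if (any(diff(present) > 0)) note(i, "gap in cause-of-death chain")
    chain <- character(0)
    if (any(present)) {
      chain <- vapply(chain_raw[present], norm_code, character(1),
                      USE.NAMES = FALSE)
      if (anyNA(chain)) {
        note(i, paste0("malformed chain code(s): ",
                       paste(chain_raw[present][is.na(chain)], collapse = ", ")))
      } else if (anyDuplicated(chain)) {
        note(i, "duplicate codes within the chain")
      }
      df[i, chain_cols()] <- c(chain, rep("", 4L - length(chain)))
    }
    hist <- character(0)
    if (nzchar(df$history[i])) {
      hraw <- strsplit(df$history[i], ";", fixed = TRUE)[[1]]
      hraw <- trimws(hraw[nzchar(trimws(hraw))])
      hist <- vapply(hraw, norm_code, character(1), USE.NAMES = FALSE)
      if (anyNA(hist)) {
        note(i, paste0("malformed history code(s): ",
                       paste(hraw[is.na(hist)], collapse = ", ")))
        hist <- hist[!is.na(hist)]
      }
      df$history[i] <- paste(hist, collapse = ";")
    }
    if (nzchar(df$underlying[i])) {
      u <- norm_code(df$underlying[i])
      if (is.na(u)) {
        note(i, paste0("malformed underlying code: ", df$underlying[i]))
      } else {
        df$underlying[i] <- u
        if (!anyNA(chain) && !(u %in% c(chain, hist))) {
          note(i, "underlying cause is not in the chain or history")
        }
      }
    }
  }

  bad <- nzchar(problems)
  if (any(bad)) {
    msgs <- paste0(df$record_id[bad], ": ", problems[bad])
    if (strict) {
      shown <- utils::head(msgs, 10L)
      stop("invalid record(s):\n  ", paste(shown, collapse = "\n  "),
           if (length(msgs) > 10L) sprintf("\n  ... and %d more",
                                           length(msgs) - 10L),
           call. = FALSE)
    }
    warning(sprintf("skipped %d invalid record(s)", sum(bad)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }

  df$age <- as.integer(df$age)
  for (col in c(chain_cols(), "underlying")) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  rownames(df) <- NULL
  class(df) <- c("death_records", "data.frame")
  df
}

#' Read death records from a delimited file
#'
#' Reads the canonical comma-delimited record format: a header row
#' `record_id,age,sex,region,cause_a,cause_b,cause_c,cause_d,history,underlying`
#' with the empty string for absent fields and `";"` separating multiple
#' history codes. Rows are validated against all record invariants (see
#' [as_death_records()]); order is preserved.
#'
#' @param path path to a CSV file.
#' @inheritParams as_death_records
#' @return a `death_records` data frame.
#' @export
read_records <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  as_death_records(df, strict = strict)
}

#' Write death records to a delimited file
#'
#' Inverse of [read_records()]: writes the canonical CSV dialect so that
#' reading the file back reproduces the records field-for-field.
#'
#' @param records a `death_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- as.data.frame(records)[record_columns()]
  for (col in record_columns()) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# list-of-character-vector views used by the estimators
record_history_list <- function(records) {
  h <- records$history
  h[is.na(h)] <- ""
  lapply(strsplit(h, ";", fixed = TRUE),
         function(x) x[nzchar(x)])
}

record_chain_matrix <- function(records) {
  as.matrix(as.data.frame(records)[chain_cols()])
}
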