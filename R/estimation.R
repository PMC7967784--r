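#' Accumulate stratified occurrence and death counts
#'
#' Builds the per-(cause, age group, gender) count table that the CDCP
#' estimator is computed from. For each labeled record, every distinct cause
#' appearing on it (the chain, plus the past medical history when
#' `include_history = TRUE`, plus always the labeled underlying cause itself)
#' increments `occur` in the record's stratum; the labeled underlying cause
#' additionally increments `death`. A cause is counted at most once per
#' record (counts are numbers of decedents), so `death <= occur` holds in
#' every cell.
#'
#' @param records labeled `death_records` (every row must have `underlying`).
#' @param include_history whether history codes count as occurrences
#'   (default `TRUE`: the underlying cause may come from the history).
#' @return a `count_table`: data frame with columns `cause`, `age_group`,
#'   `gender`, `occur`, `death`; attributes `total_records` and
#'   `include_history`.
#' @export
accumulate_counts <- function(records, include_history = TRUE) {
  stopifnot(is.data.frame(records))
  unlabeled <- is.na(records$underlying) | !nzchar(records$underlying)
  if (any(unlabeled)) {
    stop("unlabeled record(s): ",
         paste(utils::head(records$record_id[unlabeled], 5L), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  ag <- as.character(age_group(records$age))
  sex <- records$sex

  cm <- record_chain_matrix(records)
  idx <- rep(seq_len(n), times = ncol(cm))
  code <- as.vector(cm)
  keep <- !is.na(code) & nzchar(code)
  idx <- idx[keep]
  code <- code[keep]
  if (include_history) {
    hl <- record_history_list(records)
    hn <- lengths(hl)
    idx <- c(idx, rep(seq_len(n), times = hn))
    code <- c(code, unlist(hl, use.names = FALSE))
  }
  # the labeled underlying cause always appears on its record
  idx <- c(idx, seq_len(n))
  code <- c(code, records$underlying)
  dup <- duplicated(paste(idx, code, sep = "\r"))
  idx <- idx[!dup]
  code <- code[!dup]

  okey <- cell_key(code, ag[idx], sex[idx])
  occur <- table(okey)
  dkey <- cell_key(records$underlying, ag, sex)
  death <- table(dkey)

  keys <- names(occur) %||% character(0)
  parts <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)) %||% character(0),
                  ncol = 3L, byrow = TRUE)
  d <- as.integer(death[match(keys, names(death))])
  d[is.na(d)] <- 0L
  cells <- data.frame(cause = as.character(parts[, 1L]),
                      age_group = as.character(parts[, 2L]),
                      gender = as.character(parts[, 3L]),
                      occur = as.integer(occur),
                      death = d,
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$cause, cells$age_group, cells$gender,
                       method = "radix"), , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, total_records = n, include_history = include_history,
            class = c("count_table", "data.frame"))
}

cdcp_value <- function(death, occur, transform, alpha) {
  raw <- (death + alpha) / (occur + 2 * alpha)
  if (transform == "log") log2(raw * 10) else raw
}

new_cdcp_table <- function(cells, transform, smoothing_alpha) {
  has_counts <- all(!is.na(cells$occur))
  pooled <- list(gender = NULL, age = NULL, global = NULL)
  if (has_counts && nrow(cells)) {
    pool <- function(keys) {
      o <- rowsum(cells$occur, keys)
      d <- rowsum(cells$death, keys)
      v <- cdcp_value(d[, 1L], o[, 1L], transform, smoothing_alpha)
      ok <- is.finite(v)
      build_env(rownames(o)[ok], v[ok])
    }
    pooled$gender <- pool(cell_key(cells$cause, cells$age_group))
    pooled$age <- pool(cell_key(cells$cause, cells$gender))
    pooled$global <- pool(cells$cause)
  }
  exact <- build_env(cell_key(cells$cause, cells$age_group, cells$gender),
                     cells$cdcp)
  structure(list(transform = transform, smoothing_alpha = smoothing_alpha,
                 cells = cells, exact = exact, pooled = pooled),
            class = "cdcp_table")
}

#' Compute the conditional death-cause proportion (CDCP) table
#'
#' CDCP for cause i in stratum (age group, gender) is the conditional
#' probability that i is the underlying cause-of-death given that i appears
#' on a decedent's record in that stratum. The `raw` estimator is the
#' smoothed ratio `(death + alpha) / (occur + 2 * alpha)`; the `log` variant
#' applies the monotone transform `log2(raw * 10)` (bounded above by
#' `log2(10)`), which compresses the spread between causes without changing
#' their within-stratum ranking, so inference is identical under either
#' variant.
#'
#' With `smoothing_alpha = 0`, cells whose raw value is zero are dropped
#' from the `log` table (the transform is undefined there) with a warning.
#'
#' @param counts a `count_table` from [accumulate_counts()].
#' @param transform `"raw"` (default; values in `[0, 1]`) or `"log"`.
#' @param smoothing_alpha additive (Laplace-style) smoothing constant
#'   (>= 0, default 0).
#' @return a `cdcp_table` object.
#' @export
compute_cdcp <- function(counts, transform = c("raw", "log"),
                         smoothing_alpha = 0) {
  transform <- match.arg(transform)
  stopifnot(smoothing_alpha >= 0)
  cells <- as.data.frame(counts)
  attr(cells, "total_records") <- NULL
  attr(cells, "include_history") <- NULL
  cells$cdcp <- cdcp_value(cells$death, cells$occur, transform,
                           smoothing_alpha)
  if (transform == "log") {
    undef <- !is.finite(cells$cdcp)
    if (any(undef)) {
      warning(sprintf("%d cell(s) with zero raw CDCP dropped from log table",
                      sum(undef)), call. = FALSE)
      cells <- cells[!undef, , drop = FALSE]
      rownames(cells) <- NULL
    }
  }
  new_cdcp_table(cells, transform, smoothing_alpha)
}

#' Build a CDCP lookup table from explicit values
#'
#' Constructs a `cdcp_table` directly from per-cell values rather than from
#' counts — for worked examples and for loading published CDCP figures as a
#' fixed lookup table. Because no counts are available, pooled-count
#' fallback is disabled for such tables (only exact cells resolve).
#'
#' @param df data frame with columns `cause`, `age_group`, `gender`, `cdcp`.
#' @param transform the scale the values are on (`"raw"` or `"log"`).
#' @return a `cdcp_table` object.
#' @export
cdcp_table_from_values <- function(df, transform = c("raw", "log")) {
  transform <- match.arg(transform)
  stopifnot(all(c("cause", "age_group", "gender", "cdcp") %in% names(df)))
  cells <- data.frame(cause = parse_icd10(df$cause),
                      age_group = as.character(df$age_group),
                      gender = as.character(df$gender),
                      occur = NA_integer_, death = NA_integer_,
                      cdcp = as.numeric(df$cdcp), stringsAsFactors = FALSE)
  stopifnot(all(cells$age_group %in% age_group_levels()),
            all(cells$gender %in% gender_levels()))
  new_cdcp_table(cells, transform, smoothing_alpha = 0)
}

#' Look up CDCP values with pooled-count fallback
#'
#' Resolves the CDCP of a cause in a stratum. With
#' `fallback_policy = "pooled"`, a missing exact cell falls back through
#' progressively pooled cells — pooled over gender (cause, age group), then
#' pooled over age (cause, gender), then global (cause) — each computed from
#' pooled *counts*, not from averaged CDCP values. `NA` (absent) is a valid
#' result when the cause was never observed.
#'
#' All arguments are vectorized over cause/age_group/gender.
#'
#' @param table a `cdcp_table`.
#' @param cause character vector of normalized ICD-10 codes.
#' @param age_group character/factor vector of age groups.
#' @param gender character vector of genders.
#' @param fallback_policy `"pooled"` (default) or `"none"` (exact cells
#'   only).
#' @return numeric vector of CDCP values, `NA` where unresolved.
#' @export
lookup_cdcp <- function(table, cause, age_group, gender,
                        fallback_policy = c("pooled", "none")) {
  fallback_policy <- match.arg(fallback_policy)
  stopifnot(inherits(table, "cdcp_table"))
  cause <- as.character(cause)
  age_group <- as.character(age_group)
  gender <- as.character(gender)
  v <- env_lookup(table$exact, cell_key(cause, age_group, gender))
  if (fallback_policy == "pooled") {
    miss <- is.na(v)
    if (any(miss)) {
      v[miss] <- env_lookup(table$pooled$gender,
                            cell_key(cause[miss], age_group[miss]))
    }
    miss <- is.na(v)
    if (any(miss)) {
      v[miss] <- env_lookup(table$pooled$age,
                            cell_key(cause[miss], gender[miss]))
    }
    miss <- is.na(v)
    if (any(miss)) {
      v[miss] <- env_lookup(table$pooled$global, cause[miss])
    }
  }
  v
}

#' Compute the regional death-cause proportion (RDCP) table
#'
#' RDCP for cause i in region j is `n_ij / N_j`: the fraction of labeled
#' deaths in region j whose underlying cause is i. Within every region the
#' proportions sum to one. Regions with no records are absent from the
#' table.
#'
#' @param records labeled `death_records`.
#' @return an `rdcp_table`: data frame with columns `region`, `cause`, `n`,
#'   `rdcp`; attribute `region_totals` (named integer vector `N_j`).
#' @export
compute_rdcp <- function(records) {
  stopifnot(is.data.frame(records))
  unlabeled <- is.na(records$underlying) | !nzchar(records$underlying)
  if (any(unlabeled)) {
    stop("unlabeled record(s): ",
         paste(utils::head(records$record_id[unlabeled], 5L), collapse = ", "),
         call. = FALSE)
  }
  tab <- table(region = records$region, cause = records$underlying)
  totals <- rowSums(tab)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3L] <- "n"
  df <- df[df$n > 0L, , drop = FALSE]
  df$rdcp <- df$n / totals[df$region]
  df <- df[order(df$region, df$cause, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, region_totals = totals,
            class = c("rdcp_table", "data.frame"))
}

#' Serialize and deserialize fitted tables
#'
#' Writes a `count_table`, `cdcp_table` or `rdcp_table` to a versioned JSON
#' file and reads it back, round-trip stable. Cell keys are
#' `"CODE|age_group|gender"` strings (`"region|CODE"` for RDCP); floats are
#' kept at full double precision; keys are written in sorted order so
#' re-serialization is byte-stable.
#'
#' @param x a fitted table.
#' @param path file path.
#' @return `serialize_table()` returns `path` invisibly;
#'   `deserialize_table()` returns the reconstructed table.
#' @export
serialize_table <- function(x, path) {
  obj <- if (inherits(x, "count_table")) {
    cells <- as.data.frame(x)
    keys <- cell_key(cells$cause, cells$age_group, cells$gender)
    o <- order(keys, method = "radix")
    list(format = "sinkcod-table", version = 1L, type = "count_table",
         total_records = attr(x, "total_records"),
         include_history = attr(x, "include_history"),
         cells = stats::setNames(
           lapply(o, function(i) list(occur = cells$occur[i],
                                      death = cells$death[i])),
           keys[o]))
  } else if (inherits(x, "cdcp_table")) {
    cells <- x$cells
    keys <- cell_key(cells$cause, cells$age_group, cells$gender)
    o <- order(keys, method = "radix")
    list(format = "sinkcod-table", version = 1L, type = "cdcp_table",
         transform = x$transform, smoothing_alpha = x$smoothing_alpha,
         cells = stats::setNames(
           lapply(o, function(i) list(occur = cells$occur[i],
                                      death = cells$death[i],
                                      cdcp = cells$cdcp[i])),
           keys[o]))
  } else if (inherits(x, "rdcp_table")) {
    cells <- as.data.frame(x)
    keys <- cell_key(cells$region, cells$cause)
    o <- order(keys, method = "radix")
    totals <- attr(x, "region_totals")
    list(format = "sinkcod-table", version = 1L, type = "rdcp_table",
         region_totals = as.list(stats::setNames(as.integer(totals),
                                                 names(totals))),
         cells = stats::setNames(as.list(as.integer(cells$n[o])), keys[o]))
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname serialize_table
#' @export
deserialize_table <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "sinkcod-table") || !identical(obj$version, 1L)) {
    stop("not a version-1 sinkcod table file: ", path, call. = FALSE)
  }
  split_keys <- function(keys, n) {
    if (!length(keys)) return(matrix(character(0), ncol = n))
    matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = n, byrow = TRUE)
  }
  if (identical(obj$type, "count_table")) {
    keys <- names(obj$cells)
    parts <- split_keys(keys, 3L)
    cells <- data.frame(cause = parts[, 1L], age_group = parts[, 2L],
                        gender = parts[, 3L],
                        occur = vapply(obj$cells, function(c) as.integer(c$occur), 0L),
                        death = vapply(obj$cells, function(c) as.integer(c$death), 0L),
                        stringsAsFactors = FALSE, row.names = NULL)
    cells <- cells[order(cells$cause, cells$age_group, cells$gender,
                         method = "radix"), , drop = FALSE]
    rownames(cells) <- NULL
    structure(cells, total_records = as.integer(obj$total_records),
              include_history = isTRUE(obj$include_history),
              class = c("count_table", "data.frame"))
  } else if (identical(obj$type, "cdcp_table")) {
    keys <- names(obj$cells)
    parts <- split_keys(keys, 3L)
    int_or_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
    cells <- data.frame(cause = parts[, 1L], age_group = parts[, 2L],
                        gender = parts[, 3L],
                        occur = vapply(obj$cells, function(c) int_or_na(c$occur), 0L),
                        death = vapply(obj$cells, function(c) int_or_na(c$death), 0L),
                        cdcp = vapply(obj$cells, function(c) as.numeric(c$cdcp), 0),
                        stringsAsFactors = FALSE, row.names = NULL)
    cells <- cells[order(cells$cause, cells$age_group, cells$gender,
                         method = "radix"), , drop = FALSE]
    rownames(cells) <- NULL
    new_cdcp_table(cells, obj$transform, as.numeric(obj$smoothing_alpha))
  } else if (identical(obj$type, "rdcp_table")) {
    keys <- names(obj$cells)
    parts <- split_keys(keys, 2L)
    totals <- vapply(obj$region_totals, as.numeric, 0)
    df <- data.frame(region = parts[, 1L], cause = parts[, 2L],
                     n = vapply(obj$cells, as.integer, 0L),
                     stringsAsFactors = FALSE, row.names = NULL)
    df$rdcp <- df$n / totals[df$region]
    df <- df[order(df$region, df$cause, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    structure(df, region_totals = totals,
              class = c("rdcp_table", "data.frame"))
  } else {
    stop("unknown table type: ", obj$type, call. = FALSE)
  }
}

#' @export
print.cdcp_table <- function(x, ...) {
  cat(sprintf("CDCP table (%s transform, alpha = %g): %d cells, %d causes\n",
              x$transform, x$smoothing_alpha, nrow(x$cells),
              length(unique(x$cells$cause))))
  print(utils::head(x$cells, 10L))
  if (nrow(x$cells) > 10L) cat("...\n")
  invisible(x)
}
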