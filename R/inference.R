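#' Sink inference of the underlying cause-of-death
#'
#' The sink algorithm treats a decedent as a boat sunk by the stones placed
#' in it: each cause on the record is a stone whose weight is its CDCP in
#' the decedent's (age group, gender) stratum, and the underlying
#' cause-of-death is the heaviest stone. Concretely, the candidate set is
#' the cause-of-death chain plus (optionally) the past medical history, and
#' the prediction is the candidate with maximal CDCP.
#'
#' Two special rules:
#' \itemize{
#'   \item External-cause short-circuit (`external_rule = TRUE`, default):
#'     when the direct cause `cause_a` is an ICD-10 Chapter XX external
#'     cause (V-Y), it is returned immediately as the underlying cause —
#'     an external underlying cause coincides with the direct cause.
#'   \item Fallback: candidates whose CDCP is unresolved (absent even after
#'     pooled-count fallback, see [lookup_cdcp()]) are excluded; if every
#'     candidate is unresolved the direct cause is returned with
#'     `source = "fallback"`.
#' }
#'
#' Ties on the maximal score are broken deterministically: the candidate
#' latest in the chain wins (the chain runs from the direct cause backwards
#' toward the originating condition, so later positions are closer to the
#' origin); chain candidates beat history candidates; remaining ties among
#' history candidates go to the lexicographically smallest code.
#' `tie_broken` flags predictions where more than one candidate attained
#' the maximal score.
#'
#' @param records a `death_records` data frame (`sink_infer()` expects a
#'   single row).
#' @param cdcp a fitted `cdcp_table`.
#' @param external_rule enable the external-cause short-circuit.
#' @param include_history include history codes in the candidate set.
#' @param fallback_policy passed to [lookup_cdcp()] (`"pooled"` or
#'   `"none"`).
#' @return data frame with one row per record: `record_id`, `predicted`
#'   (ICD-10 code), `score` (CDCP of the prediction; `NA` when the external
#'   rule fired or the fallback was used), `source` (one of `chain`,
#'   `history`, `external_rule`, `fallback`) and `tie_broken` (logical).
#'   Row order matches the input; results are independent of batch
#'   composition.
#' @export
sink_infer_batch <- function(records, cdcp, external_rule = TRUE,
                             include_history = TRUE,
                             fallback_policy = c("pooled", "none")) {
  fallback_policy <- match.arg(fallback_policy)
  stopifnot(is.data.frame(records), inherits(cdcp, "cdcp_table"))
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(record_id = character(0), predicted = character(0),
                      score = numeric(0), source = character(0),
                      tie_broken = logical(0), stringsAsFactors = FALSE))
  }
  direct <- records$cause_a
  if (any(is.na(direct) | !nzchar(direct))) {
    bad <- records$record_id[is.na(direct) | !nzchar(direct)]
    stop("empty cause-of-death chain for record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  ag <- as.character(age_group(records$age))
  sex <- records$sex

  cm <- record_chain_matrix(records)
  idx <- rep(seq_len(n), times = ncol(cm))
  code <- as.vector(cm)
  pos <- rep(seq_len(ncol(cm)), each = n)
  keep <- !is.na(code) & nzchar(code)
  idx <- idx[keep]; code <- code[keep]; pos <- pos[keep]
  is_hist <- rep(FALSE, length(idx))
  if (include_history) {
    hl <- record_history_list(records)
    hn <- lengths(hl)
    idx <- c(idx, rep(seq_len(n), times = hn))
    code <- c(code, unlist(hl, use.names = FALSE))
    pos <- c(pos, rep(0L, sum(hn)))
    is_hist <- c(is_hist, rep(TRUE, sum(hn)))
  }
  # chain rows come first, so a history duplicate of a chain code drops out
  dup <- duplicated(paste(idx, code, sep = "\r"))
  idx <- idx[!dup]; code <- code[!dup]; pos <- pos[!dup]
  is_hist <- is_hist[!dup]

  score <- lookup_cdcp(cdcp, code, ag[idx], sex[idx], fallback_policy)
  s <- ifelse(is.na(score), -Inf, score)
  o <- order(idx, -s, is_hist, -pos, code, method = "radix")
  winner <- o[!duplicated(idx[o])]
  slot <- match(seq_len(n), idx[winner])
  winner <- winner[slot]

  predicted <- code[winner]
  win_score <- score[winner]
  source <- ifelse(is_hist[winner], "history", "chain")
  # tie detection among resolvable candidates
  best <- s[winner][match(idx, seq_len(n))]
  at_max <- is.finite(s) & s == best
  n_at_max <- as.integer(rowsum(as.integer(at_max), idx)[as.character(seq_len(n)), 1L])
  tie_broken <- n_at_max > 1L

  unresolved <- !is.finite(s[winner])
  if (any(unresolved)) {
    predicted[unresolved] <- direct[unresolved]
    win_score[unresolved] <- NA_real_
    source[unresolved] <- "fallback"
    tie_broken[unresolved] <- FALSE
  }
  if (external_rule) {
    ext <- icd10_is_external(direct)
    if (any(ext)) {
      predicted[ext] <- direct[ext]
      win_score[ext] <- NA_real_
      source[ext] <- "external_rule"
      tie_broken[ext] <- FALSE
    }
  }
  data.frame(record_id = records$record_id, predicted = predicted,
             score = win_score, source = source, tie_broken = tie_broken,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname sink_infer_batch
#' @export
sink_infer <- function(records, cdcp, external_rule = TRUE,
                       include_history = TRUE,
                       fallback_policy = c("pooled", "none")) {
  stopifnot(nrow(records) == 1L)
  sink_infer_batch(records, cdcp, external_rule = external_rule,
                   include_history = include_history,
                   fallback_policy = fallback_policy)
}
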