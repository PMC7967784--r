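# Build a death_records data frame from terse per-record specs:
# list(age, sex, chain = c(...), history = c(...), underlying, region)
make_records <- function(specs, region = "R1") {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    chain <- c(s$chain, rep("", 4L - length(s$chain)))
    data.frame(record_id = s$record_id %||% sprintf("t%03d", i),
               age = s$age %||% 70L,
               sex = s$sex %||% "male",
               region = s$region %||% region,
               cause_a = chain[1], cause_b = chain[2], cause_c = chain[3],
               cause_d = chain[4],
               history = paste(s$history %||% character(0), collapse = ";"),
               underlying = s$underlying %||% "",
               stringsAsFactors = FALSE)
  })
  as_death_records(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force recount: nested loops over records x causes,
# nothing shared with accumulate_counts().
brute_force_counts <- function(records, include_history = TRUE) {
  acc <- list()
  for (i in seq_len(nrow(records))) {
    chain <- unlist(records[i, c("cause_a", "cause_b", "cause_c", "cause_d")],
                    use.names = FALSE)
    chain <- chain[!is.na(chain) & nzchar(chain)]
    hist <- character(0)
    h <- records$history[i]
    if (!is.na(h) && nzchar(h)) hist <- strsplit(h, ";", fixed = TRUE)[[1]]
    u <- records$underlying[i]
    codes <- if (include_history) unique(c(chain, hist, u))
             else unique(c(chain, u))
    ag <- if (records$age[i] <= 18) "young"
          else if (records$age[i] < 55) "middle" else "old"
    for (code in codes) {
      key <- paste(code, ag, records$sex[i], sep = "|")
      if (is.null(acc[[key]])) acc[[key]] <- c(occur = 0L, death = 0L)
      acc[[key]]["occur"] <- acc[[key]]["occur"] + 1L
      if (code == u) acc[[key]]["death"] <- acc[[key]]["death"] + 1L
    }
  }
  keys <- sort(names(acc), method = "radix")
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(cause = parts[, 1], age_group = parts[, 2],
                    gender = parts[, 3],
                    occur = vapply(acc[keys], `[[`, 0L, "occur"),
                    death = vapply(acc[keys], `[[`, 0L, "death"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$cause, out$age_group, out$gender, method = "radix"), ,
      drop = FALSE]
}

# Small, fast generator config for property tests.
small_config <- function(n = 500L, seed = 1L, ...) {
  generator_config(n_records = n, n_causes = 15L, n_regions = 3L,
                   seed = seed, ...)
}
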