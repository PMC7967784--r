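#' Configuration for the synthetic death-record generator
#'
#' Defines a cohort-generating model with known structure so the estimators
#' and the sink algorithm can be tested end-to-end: region-specific cause
#' prevalences, per-(cause, age group, gender) lethalities (the generative
#' propensity of a cause to be the underlying cause), chain-length and
#' history mechanisms, and an external-cause fraction. Unspecified
#' `cause_prevalence`, `lethality` and `region_weights` are synthesized
#' deterministically from `seed`, so a config is a pure value: the same
#' config always generates the same cohort.
#'
#' Defaults emulate a city death registry: ~50,000 records, 40 internal
#' causes over 3 regions, chains biased toward the full 4 items, deaths
#' concentrated in the oldest stratum, a small external-cause fraction, and
#' sparse past medical history.
#'
#' @param n_records cohort size.
#' @param n_causes number of internal-cause codes in the universe.
#' @param n_regions number of regions.
#' @param chain_length_probs probability vector over chain lengths 1-4.
#' @param history_rate mean number of history codes (Poisson, truncated at
#'   4 so records stay within the fixed code universe).
#' @param external_fraction fraction of records whose direct cause is an
#'   external-chapter code (those records have underlying = direct cause).
#' @param age_distribution mixture weights over the `young`/`middle`/`old`
#'   strata (ages uniform within 0-18, 19-54, 55-99).
#' @param gender_balance probability of `male`.
#' @param seed integer seed; drives both default-parameter synthesis and
#'   cohort generation.
#' @param cause_prevalence optional `n_regions x n_causes` matrix of
#'   per-region sampling probabilities (rows sum to 1).
#' @param lethality optional `n_causes x 3 x 2` array in (0, 1), dimensions
#'   (cause, age group, gender).
#' @param region_weights optional probability vector over regions.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_records = 50000L, n_causes = 40L,
                             n_regions = 3L,
                             chain_length_probs = c(0.05, 0.15, 0.3, 0.5),
                             history_rate = 0.5, external_fraction = 0.08,
                             age_distribution = c(young = 0.05, middle = 0.2,
                                                  old = 0.75),
                             gender_balance = 0.5, seed = 1L,
                             cause_prevalence = NULL, lethality = NULL,
                             region_weights = NULL) {
  stopifnot(n_records >= 1L, n_causes >= 1L, n_regions >= 1L,
            length(chain_length_probs) == 4L, all(chain_length_probs >= 0),
            abs(sum(chain_length_probs) - 1) < 1e-9,
            history_rate >= 0, external_fraction >= 0, external_fraction <= 1,
            length(age_distribution) == 3L, all(age_distribution >= 0),
            abs(sum(age_distribution) - 1) < 1e-9,
            gender_balance >= 0, gender_balance <= 1)
  n_records <- as.integer(n_records)
  n_causes <- as.integer(n_causes)
  n_regions <- as.integer(n_regions)
  max_len <- max(which(chain_length_probs > 0))
  if (n_causes < max_len) {
    stop("n_causes too small for the requested chain lengths", call. = FALSE)
  }
  pool <- icd10_code_pool(n_internal = n_causes)
  defaults <- with_seed(as.integer(seed) + 1000003L, {
    prev <- if (is.null(cause_prevalence)) {
      p <- matrix(stats::rgamma(n_regions * n_causes, shape = 1),
                  n_regions, n_causes)
      p / rowSums(p)
    } else cause_prevalence
    leth <- if (is.null(lethality)) {
      base <- 0.02 + 0.9 * stats::runif(n_causes)^2
      jitter <- array(exp(stats::rnorm(n_causes * 3 * 2, sd = 0.4)),
                      dim = c(n_causes, 3, 2))
      l <- array(base, dim = c(n_causes, 3, 2)) * jitter
      pmin(pmax(l, 0.01), 0.99)
    } else lethality
    rw <- if (is.null(region_weights)) rep(1 / n_regions, n_regions)
          else region_weights
    list(prev = prev, leth = leth, rw = rw)
  })
  prev <- defaults$prev
  leth <- defaults$leth
  stopifnot(nrow(prev) == n_regions, ncol(prev) == n_causes,
            all(abs(rowSums(prev) - 1) < 1e-9),
            identical(dim(leth), c(n_causes, 3L, 2L)),
            all(leth > 0 & leth < 1),
            abs(sum(defaults$rw) - 1) < 1e-9)
  dimnames(leth) <- list(pool$internal, age_group_levels(), gender_levels())
  colnames(prev) <- pool$internal
  structure(list(n_records = as.integer(n_records),
                 n_causes = as.integer(n_causes),
                 n_regions = as.integer(n_regions),
                 chain_length_probs = chain_length_probs,
                 history_rate = history_rate,
                 external_fraction = external_fraction,
                 age_distribution = age_distribution,
                 gender_balance = gender_balance,
                 seed = as.integer(seed),
                 cause_prevalence = prev, lethality = leth,
                 region_weights = defaults$rw,
                 internal_codes = pool$internal,
                 external_codes = pool$external),
            class = "generator_config")
}

# Weighted sampling without replacement for every record at once via the
# Gumbel-max trick: the top-t keys log(p) + Gumbel noise are a draw of t
# distinct causes with probabilities proportional to p. The first L picks
# form the chain, the rest the history, guaranteeing distinctness.
sample_distinct_causes <- function(log_prev_rows, n_take) {
  m <- nrow(log_prev_rows)
  t_max <- max(n_take)
  g <- -log(-log(stats::runif(m * ncol(log_prev_rows))))
  w <- log_prev_rows + matrix(g, m, ncol(log_prev_rows))
  picks <- matrix(NA_integer_, m, t_max)
  for (j in seq_len(t_max)) {
    mc <- max.col(w, ties.method = "first")
    picks[, j] <- mc
    w[cbind(seq_len(m), mc)] <- -Inf
  }
  picks
}

#' Generate a synthetic death-record cohort
#'
#' Samples `n_records` death records from the generative model in `config`:
#' region, age and gender are drawn from their marginals; a chain of L
#' distinct causes is drawn by region-specific prevalence; with probability
#' `external_fraction` the direct cause is replaced by an external-chapter
#' code and the underlying cause is set to it (mirroring the external-cause
#' coding rule); otherwise the underlying cause is drawn from the chain and
#' history with probability proportional to the per-stratum lethality — the
#' mechanism under which picking the maximal-CDCP candidate is the Bayes
#' decision rule. History codes share the cause universe and lethality
#' table with chain codes.
#'
#' Generation is a pure function of `config` (including its seed): the same
#' config yields the identical cohort.
#'
#' @param config a `generator_config`.
#' @return a labeled `death_records` data frame with `n_records` rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_records
  with_seed(config$seed, {
    region_idx <- sample.int(config$n_regions, n, replace = TRUE,
                             prob = config$region_weights)
    agi <- sample.int(3L, n, replace = TRUE, prob = config$age_distribution)
    lo <- c(0L, 19L, 55L)[agi]
    hi <- c(18L, 54L, 99L)[agi]
    age <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
    sexi <- ifelse(stats::runif(n) < config$gender_balance, 1L, 2L)
    len <- sample.int(4L, n, replace = TRUE,
                      prob = config$chain_length_probs)
    hcount <- pmin(stats::rpois(n, config$history_rate), 4L,
                   config$n_causes - len)
    hcount <- pmax(hcount, 0L)
    take <- len + hcount
    picks <- matrix(NA_integer_, n, max(take))
    chunk <- 100000L
    log_prev <- log(config$cause_prevalence)
    for (start in seq(1L, n, by = chunk)) {
      rows <- start:min(start + chunk - 1L, n)
      picks[rows, seq_len(max(take[rows]))] <-
        sample_distinct_causes(log_prev[region_idx[rows], , drop = FALSE],
                               take[rows])[, seq_len(max(take[rows])),
                                           drop = FALSE]
    }
    col_idx <- matrix(seq_len(ncol(picks)), n, ncol(picks), byrow = TRUE)
    picks[col_idx > take] <- NA_integer_

    is_ext <- stats::runif(n) < config$external_fraction
    ext_code <- config$external_codes[
      sample.int(length(config$external_codes), n, replace = TRUE)]

    # underlying cause: lethality-proportional draw over chain + history
    w <- matrix(0, n, ncol(picks))
    pk <- as.vector(picks)
    ok <- !is.na(pk)
    w[ok] <- config$lethality[cbind(pk[ok],
                                    rep(agi, ncol(picks))[ok],
                                    rep(sexi, ncol(picks))[ok])]
    cw <- w
    for (j in seq_len(ncol(cw))[-1L]) cw[, j] <- cw[, j] + cw[, j - 1L]
    u <- stats::runif(n) * cw[, ncol(cw)]
    sel <- rep(1L, n)
    chosen <- cw[, 1L] >= u
    for (j in seq_len(ncol(cw))[-1L]) {
      hit <- !chosen & cw[, j] >= u
      sel[hit] <- j
      chosen <- chosen | hit
    }
    und_idx <- picks[cbind(seq_len(n), sel)]
    underlying <- config$internal_codes[und_idx]

    codes <- matrix(config$internal_codes[picks], n, ncol(picks))
    chain <- matrix(NA_character_, n, 4L)
    for (j in seq_len(min(4L, ncol(codes)))) {
      has <- len >= j
      chain[has, j] <- codes[has, j]
    }
    chain[is_ext, 1L] <- ext_code[is_ext]
    underlying[is_ext] <- ext_code[is_ext]
    hist_str <- rep("", n)
    has_hist <- hcount > 0L
    if (any(has_hist)) {
      hist_str[has_hist] <- vapply(which(has_hist), function(i) {
        paste(codes[i, (len[i] + 1L):take[i]], collapse = ";")
      }, character(1))
    }
    df <- data.frame(record_id = sprintf("r%07d", seq_len(n)),
                     age = age,
                     sex = gender_levels()[sexi],
                     region = paste0("R", region_idx),
                     cause_a = chain[, 1L], cause_b = chain[, 2L],
                     cause_c = chain[, 3L], cause_d = chain[, 4L],
                     history = hist_str,
                     underlying = underlying,
                     stringsAsFactors = FALSE)
    class(df) <- c("death_records", "data.frame")
    df
  })
}

#' Monte-Carlo oracle for the generator's induced CDCP
#'
#' Estimates, by brute-force simulation from the generative model, the
#' induced conditional probability that cause i is the underlying cause
#' given that i appears on a record of stratum (age group, gender). This is
#' the recovery target for [compute_cdcp()]: it differs from the raw
#' lethality parameters because it marginalizes over the co-occurring chain
#' and history members a cause competes with.
#'
#' @param config a `generator_config`.
#' @param n_monte_carlo number of simulated records (default ten times the
#'   config's cohort size).
#' @param seed seed for the oracle simulation (kept distinct from the
#'   config seed so the oracle draw is independent of the cohort draw).
#' @return a raw `cdcp_table` whose cells carry the Monte-Carlo `occur`
#'   counts (usable to restrict comparisons to well-estimated cells).
#' @export
induced_cdcp_oracle <- function(config, n_monte_carlo = 10L * config$n_records,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  cfg$n_records <- as.integer(n_monte_carlo)
  cfg$seed <- as.integer(seed)
  sim <- generate_cohort(cfg)
  # plain tabulation, kept separate from accumulate_counts()
  n <- nrow(sim)
  ag <- as.character(age_group(sim$age))
  cm <- record_chain_matrix(sim)
  hl <- record_history_list(sim)
  idx <- c(rep(seq_len(n), times = ncol(cm)), rep(seq_len(n), lengths(hl)))
  code <- c(as.vector(cm), unlist(hl, use.names = FALSE))
  keep <- !is.na(code) & nzchar(code)
  idx <- idx[keep]; code <- code[keep]
  dup <- duplicated(paste(idx, code, sep = "\r"))
  idx <- idx[!dup]; code <- code[!dup]
  okey <- cell_key(code, ag[idx], sim$sex[idx])
  occur <- table(okey)
  death <- table(cell_key(sim$underlying, ag, sim$sex))
  keys <- names(occur)
  parts <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = 3L,
                  byrow = TRUE)
  d <- as.integer(death[match(keys, names(death))])
  d[is.na(d)] <- 0L
  cells <- data.frame(cause = parts[, 1L], age_group = parts[, 2L],
                      gender = parts[, 3L], occur = as.integer(occur),
                      death = d, stringsAsFactors = FALSE)
  cells$cdcp <- cells$death / cells$occur
  cells <- cells[order(cells$cause, cells$age_group, cells$gender,
                       method = "radix"), , drop = FALSE]
  rownames(cells) <- NULL
  new_cdcp_table(cells, transform = "raw", smoothing_alpha = 0)
}
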