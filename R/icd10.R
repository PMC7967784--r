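#' Parse and normalize ICD-10 codes
#'
#' Validates and normalizes ICD-10 codes to the canonical upper-case form.
#' A syntactically valid code is one upper-case letter, two digits, and
#' optionally a dot followed by one or two alphanumerics (so both
#' three-character category codes such as `"J60"` and subcategory codes such
#' as `"I25.1"` are accepted). Only syntax is checked; existence of the code
#' in the WHO classification is out of scope.
#'
#' Normalization is idempotent: parsing an already-normalized code returns
#' it unchanged.
#'
#' @param raw character vector of raw codes.
#' @return character vector of normalized (upper-case, trimmed) codes.
#' @examples
#' parse_icd10(c("i25.1", " j60 "))
#' icd10_is_external("V03.1")
#' @export
parse_icd10 <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  if (!length(x)) return(character(0))
  if (any(is.na(x) | !nzchar(x))) {
    stop("empty ICD-10 code (after trimming)", call. = FALSE)
  }
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[A-Z0-9]{1,2})?$", x)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname parse_icd10
#' @param code character vector of normalized ICD-10 codes.
#' @details `icd10_is_external()` reports whether a code belongs to ICD-10
#'   Chapter XX (external causes of morbidity and mortality, V01-Y98),
#'   identified by the leading letter V, W, X or Y. An external underlying
#'   cause coincides with the direct cause on the certificate, which is what
#'   the inference short-circuit rule exploits.
#' @export
icd10_is_external <- function(code) {
  substr(as.character(code), 1L, 1L) %in% c("V", "W", "X", "Y")
}

#' Age-group stratification
#'
#' Maps integer ages in years to the three analysis strata used throughout
#' the estimators: `young` (age <= 18), `middle` (18 < age < 55) and `old`
#' (age >= 55). The mapping is total for age >= 0 and the groups are
#' disjoint; the boundary ages 18 and 55 belong to `young` and `old`
#' respectively.
#'
#' @param age integer vector of ages in years (>= 0).
#' @return factor with levels `young`, `middle`, `old`.
#' @export
age_group <- function(age) {
  age <- as.integer(age)
  if (any(is.na(age)) || any(age < 0L)) {
    stop("age must be a non-negative integer", call. = FALSE)
  }
  factor(ifelse(age <= 18L, "young", ifelse(age < 55L, "middle", "old")),
         levels = age_group_levels())
}

age_group_levels <- function() c("young", "middle", "old")
gender_levels <- function() c("male", "female")

#' Pool of syntactically valid ICD-10 codes for simulation
#'
#' Deterministically enumerates syntactically valid codes for the synthetic
#' cohort generator: internal-cause codes from the disease chapters (letters
#' A-U) and external-cause codes from Chapter XX (V-Y). The pool is fixed so
#' simulated cohorts exercise the same parsing/validation path as real
#' records.
#'
#' @param n_internal number of internal-cause codes.
#' @param n_external number of external-cause codes.
#' @return list with character vectors `internal` and `external`.
#' @export
icd10_code_pool <- function(n_internal = 40L, n_external = 8L) {
  internal_letters <- c("A", "B", "C", "D", "E", "G", "I", "J", "K", "N")
  ext <- c("V03.1", "V09.2", "W19", "X59.9", "X70", "Y04", "W74", "V47.5",
           "W01", "X44", "Y14", "V89.2")
  if (n_external > length(ext)) {
    stop("at most ", length(ext), " external codes available", call. = FALSE)
  }
  i <- seq_len(n_internal) - 1L
  internal <- sprintf("%s%02d.%d",
                      internal_letters[(i %% length(internal_letters)) + 1L],
                      10L + (i %/% length(internal_letters)) * 7L %% 80L,
                      i %% 10L)
  list(internal = parse_icd10(internal),
       external = parse_icd10(ext[seq_len(n_external)]))
}
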