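#' Example stratified CDCP reference values
#'
#' A small published-style table of raw CDCP values for four ICD-10 causes
#' (pneumonia J18.9, intracerebral haemorrhage I61.9, other respiratory
#' disorders J98.4, and sepsis A41.9), tabulated overall and per stratum
#' column (male, female, and the three age groups). Shipped with the
#' package for worked examples: each stratum column can be loaded as a
#' fixed CDCP lookup table and run through [sink_infer()].
#'
#' @return data frame with columns `cause`, `overall`, `male`, `female`,
#'   `young`, `middle`, `old`.
#' @examples
#' strata <- example_cdcp_strata()
#' tbl <- example_cdcp_table("male")
#' rec <- as_death_records(data.frame(
#'   record_id = "ex1", age = 77, sex = "male", region = "X",
#'   cause_a = "J18.9", cause_b = "I61.9", cause_c = "J98.4",
#'   cause_d = "A41.9"))
#' sink_infer(rec, tbl, external_rule = FALSE)
#' @export
example_cdcp_strata <- function() {
  path <- system.file("extdata", "cdcp_example.csv", package = "sinkcod")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname example_cdcp_strata
#' @param column which stratum column to load (`"male"`, `"female"`,
#'   `"young"`, `"middle"`, `"old"` or `"overall"`).
#' @details `example_cdcp_table()` expands one stratum column into a full
#'   raw `cdcp_table`: a gender column is replicated across the three age
#'   groups, an age column across both genders, and `overall` across all
#'   six strata, so any record of the matching stratum resolves to the
#'   printed value.
#' @export
example_cdcp_table <- function(column = c("male", "female", "young",
                                          "middle", "old", "overall")) {
  column <- match.arg(column)
  strata <- example_cdcp_strata()
  ags <- if (column %in% age_group_levels()) column else age_group_levels()
  sexes <- if (column %in% gender_levels()) column else gender_levels()
  grid <- expand.grid(cause = strata$cause, age_group = ags, gender = sexes,
                      stringsAsFactors = FALSE)
  grid$cdcp <- strata[[column]][match(grid$cause, strata$cause)]
  cdcp_table_from_values(grid, transform = "raw")
}
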