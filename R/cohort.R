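# Cohort ingestion, eligibility filtering and sex/age stratification.
#
# A cohort is an ordinary data.frame in the canonical schema below; one row
# per participant.  All biochemistry is in mg/dL, height in m, waist in cm,
# blood pressure in mmHg.

#' Canonical cohort column names
#'
#' The canonical per-participant schema used throughout the package.
#' Continuous fields are numeric; `sex` is `"male"`/`"female"`; the four
#' trailing fields are logical diagnosis/treatment flags.
#'
#' @return Character vector of the 17 canonical column names.
#' @export
cohort_columns <- function() {
  c("id", "sex", "age", "weight_kg", "height_m", "bmi", "wc_cm",
    "sbp", "dbp", "chol_mgdl", "hdl_mgdl", "tg_mgdl", "glu_mgdl",
    "dx_diabetes", "dx_hypertension", "tx_tg", "dx_chol")
}

.flag_columns <- function() c("dx_diabetes", "dx_hypertension", "tx_tg", "dx_chol")

.numeric_columns <- function() {
  setdiff(cohort_columns(), c("id", "sex", .flag_columns()))
}

# Fields whose absence eliminates a record: the union of what the ten
# markers and both criteria consume.  BMI is satisfiable either directly or
# via weight+height, handled separately in apply_eligibility().
.required_fields <- function() {
  c("sex", "age", "wc_cm", "sbp", "dbp", "hdl_mgdl", "tg_mgdl", "glu_mgdl")
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[s %in% c("0", "false", "f", "no", "n")] <- FALSE
  out[is.na(x) | s == ""] <- NA
  out
}

#' Load a participant cohort from CSV
#'
#' Reads a header-rowed CSV into the canonical cohort schema.  Unparsable
#' numeric cells become `NA`; sex codes are normalised to
#' `"male"`/`"female"`; flag columns absent from the file default to
#' `FALSE` with a warning (survey extracts commonly omit them).
#'
#' @param path Path to a CSV file with a header row, decimal point `"."`.
#' @param column_map Optional named character vector mapping canonical names
#'   (names) to the file's column names (values), e.g.
#'   `c(glu_mgdl = "GLUCOSE")`.  Unmapped canonical names are looked up
#'   verbatim.
#' @param sex_codes Length-2 named character vector giving the file's codes,
#'   default `c(male = "male", female = "female")`.  Matching is
#'   case-insensitive.
#' @return A data.frame in the canonical schema (see [cohort_columns()]).
#' @export
load_cohort <- function(path, column_map = NULL,
                        sex_codes = c(male = "male", female = "female")) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path)

  resolve <- function(canon) {
    src <- if (!is.null(column_map) && canon %in% names(column_map))
      column_map[[canon]] else canon
    src
  }
  required <- setdiff(cohort_columns(), .flag_columns())
  for (canon in required) {
    if (!resolve(canon) %in% names(raw) && !canon %in% c("bmi", "weight_kg", "height_m"))
      stop("required column missing from ", path, ": '", canon, "'")
  }
  # bmi is derivable from weight+height (and vice versa is not needed), so
  # demand bmi OR (weight_kg AND height_m)
  have <- function(canon) resolve(canon) %in% names(raw)
  if (!have("bmi") && !(have("weight_kg") && have("height_m")))
    stop("required column missing from ", path,
         ": 'bmi' (or both 'weight_kg' and 'height_m')")

  n <- nrow(raw)
  out <- data.frame(id = character(n), stringsAsFactors = FALSE)
  get_col <- function(canon) {
    src <- resolve(canon)
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, n)
  }
  out$id <- as.character(get_col("id"))

  sx <- tolower(trimws(as.character(get_col("sex"))))
  sex <- rep(NA_character_, n)
  sex[sx == tolower(sex_codes[["male"]])] <- "male"
  sex[sx == tolower(sex_codes[["female"]])] <- "female"
  out$sex <- sex

  for (col in .numeric_columns()) {
    v <- suppressWarnings(as.numeric(get_col(col)))
    out[[col]] <- v
  }

  missing_flags <- character(0)
  for (col in .flag_columns()) {
    if (have(col)) {
      out[[col]] <- .parse_flag(get_col(col))
    } else {
      out[[col]] <- FALSE
      missing_flags <- c(missing_flags, col)
    }
  }
  if (length(missing_flags))
    warning("flag column(s) absent, defaulting to FALSE: ",
            paste(missing_flags, collapse = ", "))
  out[cohort_columns()]
}

#' Fill derived anthropometric quantities
#'
#' Fills `bmi = weight/height^2` where absent (an already-present BMI is
#' preserved unchanged) and attaches `whtr = wc_cm / (100 * height_m)`,
#' the waist-to-height ratio.
#'
#' @param cohort Cohort data.frame in the canonical schema.
#' @return The cohort with `bmi` filled where derivable and a `whtr` column.
#' @export
derive_anthropometrics <- function(cohort) {
  h <- cohort$height_m
  if (any(!is.na(h) & h <= 0)) stop("non-positive height")
  fill <- is.na(cohort$bmi) & !is.na(cohort$weight_kg) & !is.na(h)
  cohort$bmi[fill] <- cohort$weight_kg[fill] / h[fill]^2
  cohort$whtr <- cohort$wc_cm / (100 * h)
  cohort
}

#' Apply the eligibility, exclusion and elimination rules
#'
#' Keeps records with age >= 20, 70 <= glucose <= 500 mg/dL,
#' triglycerides <= 1200 mg/dL, height >= 1.30 m, and no missing field
#' required by any downstream marker or criterion.  Boundaries are read
#' literally ("less than"/"greater than" are strict), so 70, 500, 1200 and
#' 1.30 are all kept.  Each record is attributed to the first rule it fails,
#' in the fixed order age, glucose, triglycerides, height, missingness, so
#' the log partitions the input exactly.
#'
#' @param cohort Cohort data.frame in the canonical schema.
#' @return A list with `kept` (the filtered cohort, with `bmi`/`whtr`
#'   derived) and `log`, a filter log with counts `n_input`,
#'   `n_excluded_age`, `n_excluded_glucose`, `n_excluded_tg`,
#'   `n_excluded_height`, `n_eliminated_missing`, `n_kept`.
#' @export
apply_eligibility <- function(cohort) {
  cohort <- derive_anthropometrics(cohort)
  n <- nrow(cohort)
  assigned <- rep(NA_character_, n)

  fails <- function(cond) !is.na(cond) & cond & is.na(assigned)
  assigned[fails(cohort$age < 20)] <- "age"
  assigned[fails(cohort$glu_mgdl < 70 | cohort$glu_mgdl > 500)] <- "glucose"
  assigned[fails(cohort$tg_mgdl > 1200)] <- "tg"
  assigned[fails(cohort$height_m < 1.30)] <- "height"

  req <- .required_fields()
  miss <- Reduce(`|`, lapply(req, function(f) is.na(cohort[[f]])))
  miss <- miss | is.na(cohort$bmi)  # bmi neither given nor derivable
  assigned[fails(miss)] <- "missing"

  kept <- cohort[is.na(assigned), , drop = FALSE]
  rownames(kept) <- NULL
  log <- list(
    n_input = n,
    n_excluded_age = sum(assigned == "age", na.rm = TRUE),
    n_excluded_glucose = sum(assigned == "glucose", na.rm = TRUE),
    n_excluded_tg = sum(assigned == "tg", na.rm = TRUE),
    n_excluded_height = sum(assigned == "height", na.rm = TRUE),
    n_eliminated_missing = sum(assigned == "missing", na.rm = TRUE),
    n_kept = nrow(kept)
  )
  list(kept = kept, log = log)
}

#' Assign sex-by-age stratum
#'
#' Age groups are closed-open on integer years: 20-39, 40-59, 60 and over.
#' Crossed with sex this yields at most six strata.
#'
#' @param sex Character vector, `"male"`/`"female"`.
#' @param age Numeric vector of ages in years, all >= 20.
#' @return Character vector like `"female 20-39"`, `"male 60+"`.
#' @export
assign_stratum <- function(sex, age) {
  if (any(is.na(age)) || any(age < 20)) stop("stratum undefined for age < 20")
  grp <- cut(age, breaks = c(20, 40, 60, Inf), right = FALSE,
             labels = c("20-39", "40-59", "60+"))
  paste(sex, as.character(grp))
}

#' All six sex-by-age strata
#' @return Character vector of the 6 stratum labels in canonical order.
#' @export
all_strata <- function() {
  as.vector(outer(c("male", "female"), c("20-39", "40-59", "60+"), paste))
}

#' Write a filter log as JSON
#'
#' @param log A filter log from [apply_eligibility()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
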