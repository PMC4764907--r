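# Per-sample clinical/behavioral covariates.

metadata_columns <- c(
  "sample_id", "age", "sex", "bmi", "n_teeth", "has_decayed_teeth",
  "pct_dft", "mean_ppd", "pct_bop", "plaque_index", "smoking",
  "antibiotics_use"
)

periodontal_columns <- c("pct_dft", "mean_ppd", "pct_bop", "plaque_index")

#' Construct a sample metadata table
#'
#' Validates and types the clinical covariates used by the association
#' layer: age (years), sex, BMI (kg/m^2), number of present teeth (0-28),
#' presence of decayed teeth, percentage of teeth with caries experience
#' (%DFT), mean periodontal pocket depth (mm), percentage of tooth sites
#' bleeding on probing (%BOP), Silness-Loe plaque index (0-3), smoking
#' status and antibiotics use. The periodontal fields (%DFT, mean PPD,
#' %BOP, plaque index) may be missing; such samples are flagged via the
#' `"incomplete_periodontal"` attribute and excluded from analyses that
#' use those fields.
#'
#' @param df A data.frame with the columns listed above; `sex` must be
#'   `"male"`/`"female"` and `smoking` one of `"never"`, `"past"`,
#'   `"current"`.
#' @return A `sample_metadata` data.frame.
#' @export
sample_metadata <- function(df) {
  missing_cols <- setdiff(metadata_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- as.data.frame(df)[metadata_columns]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  df$sex <- check_levels(df$sex, c("male", "female"), "sex")
  df$smoking <- check_levels(df$smoking, c("never", "past", "current"),
    "smoking"
  )
  df$has_decayed_teeth <- check_logical(df$has_decayed_teeth,
    "has_decayed_teeth"
  )
  df$antibiotics_use <- check_logical(df$antibiotics_use, "antibiotics_use")
  check_range(df$age, 0, 150, "age")
  check_range(df$bmi, 5, 100, "bmi")
  check_range(df$n_teeth, 0, 28, "n_teeth", integer = TRUE)
  check_range(df$pct_dft, 0, 100, "pct_dft")
  check_range(df$pct_bop, 0, 100, "pct_bop")
  check_range(df$mean_ppd, 0, 30, "mean_ppd")
  check_range(df$plaque_index, 0, 3, "plaque_index")
  incomplete <- df$sample_id[!stats::complete.cases(df[periodontal_columns])]
  rownames(df) <- df$sample_id
  structure(df,
    incomplete_periodontal = incomplete,
    class = c("sample_metadata", "data.frame")
  )
}

check_levels <- function(x, levels, name) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown %s category: %s (expected %s)", name,
      paste(bad, collapse = ", "), paste(levels, collapse = "/")
    ), call. = FALSE)
  }
  factor(x, levels = levels)
}

check_logical <- function(x, name) {
  if (is.logical(x)) {
    return(x)
  }
  if (is.numeric(x) && all(x %in% c(0, 1, NA))) {
    return(as.logical(x))
  }
  stop(name, " must be logical (or 0/1)", call. = FALSE)
}

check_range <- function(x, lo, hi, name, integer = FALSE) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s out of range [%s, %s] at row %d (value %s)",
      name, lo, hi, bad[1], format(x[bad[1]])
    ), call. = FALSE)
  }
  if (integer) {
    bad <- which(!is.na(x) & x != round(x))
    if (length(bad) > 0) {
      stop(sprintf("%s must be integral at row %d", name, bad[1]),
        call. = FALSE
      )
    }
  }
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with the [sample_metadata]
#'   columns.
#' @return A `sample_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    header = TRUE, stringsAsFactors = FALSE,
    na.strings = c("NA", "")
  )
  sample_metadata(df)
}

#' Write sample metadata to TSV
#'
#' @param meta A `sample_metadata` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  df <- as.data.frame(meta)
  df$sex <- as.character(df$sex)
  df$smoking <- as.character(df$smoking)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
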