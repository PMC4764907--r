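#' Construct an OTU count table
#'
#' A sample-by-OTU table of non-negative integer read counts, the central
#' data structure of the pipeline. Rows are samples, columns are OTUs.
#'
#' @param counts A numeric matrix of non-negative integers with unique
#'   rownames (sample ids) and colnames (OTU ids).
#' @return An `otu_table` object (an integer matrix with class attribute).
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("OTU_1", "OTU_2")))
#' otu_table(m)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) {
    stop("`counts` must be a matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample rownames and OTU colnames", call. = FALSE)
  }
  validate_counts(counts)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
      paste(unique(rownames(counts)[duplicated(rownames(counts))]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU ids: ",
      paste(unique(colnames(counts)[duplicated(colnames(counts))]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

validate_counts <- function(counts) {
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at sample '%s', OTU '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])
    ), call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "OTU table: %d samples x %d OTUs, %s reads total\n",
    nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")
  ))
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads a tab-separated table (first column sample id, header row OTU ids)
#' or a BIOM file. The TSV layout is declared, never guessed: set
#' `samples_as_rows = FALSE` for an OTU-by-sample file.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"` (requires the biomformat
#'   package; BIOM is supported read-only).
#' @param samples_as_rows For TSV, whether rows are samples (default `TRUE`).
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           samples_as_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package",
        call. = FALSE
      )
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b)) # taxa x samples
    return(otu_table(t(m)))
  }
  df <- utils::read.delim(path,
    header = TRUE, row.names = 1, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(
      as.numeric(m),
      nrow(m)
    ))) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "non-numeric count at row '%s', column '%s'",
        rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
      ), call. = FALSE)
    }
    storage.mode(m) <- "numeric"
  }
  if (!samples_as_rows) m <- t(m)
  otu_table(m)
}

#' Write an OTU count table to TSV
#'
#' @param x An [otu_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(
    sample_id = rownames(x), unclass(x),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
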