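# Tabular I/O for kinomic time series. CSV is the interchange format, in
# two dialects: wide (first column the cycle, one column per peptide) and
# long (columns peptide_id, cycle, signal, optional sample_id).

#' Read a kinomic time-series table
#'
#' @param path CSV file path.
#' @param layout `"wide"` (first column cycle, one column per peptide) or
#'   `"long"` (columns `peptide_id`, `cycle`, `signal`, optional
#'   `sample_id`).
#' @param sample_id Sample identifier attached to wide files (or long
#'   files lacking a `sample_id` column); defaults to the file name.
#' @return Long tibble with columns `sample_id`, `peptide_id`, `cycle`,
#'   `signal`, validated (numeric signals, strictly increasing cycles per
#'   peptide, no duplicate (peptide, cycle) records). Missing signal values
#'   are kept as `NA` and masked per-peptide at fit time. Source path and
#'   layout are attached as attributes.
#' @export
read_kinetics <- function(path, layout = c("wide", "long"),
                          sample_id = NULL) {
  layout <- match.arg(layout)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
  if (layout == "wide") {
    if (ncol(raw) < 2) {
      stop("wide layout needs a cycle column plus >= 1 peptide column",
        call. = FALSE
      )
    }
    peptides <- names(raw)[-1]
    dup <- peptides[duplicated(peptides)]
    if (length(dup) > 0) {
      stop("duplicated peptide column(s): ", paste(unique(dup), collapse = ", "),
        call. = FALSE
      )
    }
    names(raw)[1] <- "cycle"
    check_numeric_cols(raw, names(raw))
    if (any(diff(raw$cycle) <= 0)) {
      stop("cycle column must be strictly increasing", call. = FALSE)
    }
    out <- tidyr::pivot_longer(raw, -"cycle",
      names_to = "peptide_id", values_to = "signal"
    )
    out$sample_id <- sample_id
  } else {
    need <- c("peptide_id", "cycle", "signal")
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      stop("long layout needs columns ", paste(need, collapse = ", "),
        "; missing ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    check_numeric_cols(raw, c("cycle", "signal"))
    if (!"sample_id" %in% names(raw)) raw$sample_id <- sample_id
    out <- raw
    dups <- out |>
      dplyr::count(.data$sample_id, .data$peptide_id, .data$cycle) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dups) > 0) {
      stop(
        "duplicated (peptide, cycle) record(s), e.g. peptide ",
        dups$peptide_id[1], " at cycle ", dups$cycle[1],
        call. = FALSE
      )
    }
  }
  out <- out |>
    dplyr::select("sample_id", "peptide_id", "cycle", "signal") |>
    dplyr::arrange(.data$sample_id, .data$peptide_id, .data$cycle)
  attr(out, "source") <- path
  attr(out, "layout") <- layout
  out
}

check_numeric_cols <- function(df, cols) {
  for (col in cols) {
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' contains non-numeric values", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a kinomic time-series table
#'
#' Inverse of [read_kinetics()]. The wide layout requires a single sample
#' and a shared cycle grid across peptides.
#'
#' @param data Long tibble (`sample_id`, `peptide_id`, `cycle`, `signal`).
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(data, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  data <- as_kin_long(data)
  if (layout == "long") {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    if (dplyr::n_distinct(data$sample_id) > 1) {
      stop("wide layout holds a single sample; write samples separately",
        call. = FALSE
      )
    }
    wide <- data |>
      dplyr::select("cycle", "peptide_id", "signal") |>
      tidyr::pivot_wider(names_from = "peptide_id", values_from = "signal") |>
      dplyr::arrange(.data$cycle)
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}
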