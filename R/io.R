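# Readers for the supported molecule input formats.

#' Read SMILES from a plain text file (one per line)
#'
#' Lines may carry an optional whitespace-separated name, which is
#' dropped. Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of SMILES.
#' @export
read_smiles_lines <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}

#' Read a labeled SMILES table from CSV
#'
#' @param path CSV file path.
#' @param smiles_col,label_col Column names (label optional: pass `NULL`
#'   to read structures only).
#' @param log_papp_col Optional column with continuous logPapp values.
#' @return data.frame with standardized column names `smiles` and, when
#'   present, `label` / `log_papp`.
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles",
                            label_col = "label", log_papp_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop_config("column '%s' not found in %s", smiles_col, path)
  }
  out <- data.frame(smiles = df[[smiles_col]], stringsAsFactors = FALSE)
  if (!is.null(label_col) && label_col %in% names(df)) {
    out$label <- df[[label_col]]
  }
  if (!is.null(log_papp_col) && log_papp_col %in% names(df)) {
    out$log_papp <- df[[log_papp_col]]
  }
  out
}

#' Read SMILES from an SDF file
#'
#' Converts each record's first molecule block to SMILES via OpenBabel.
#'
#' @param path SDF file path.
#' @return Character vector of SMILES (unconvertible records dropped).
#' @export
read_sdf_smiles <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste0(text, "\n")),
    error = function(e) ""
  )
  lines <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}
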