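#' Read a grouped two-column table from CSV/TSV
#'
#' Expects a delimited text file with a header row and (at least) a group
#' column and a numeric response column. The delimiter is taken from the
#' file extension (`.tsv`/`.txt` = tab, otherwise comma). Rows with missing
#' responses are dropped with a message (or rejected, per `na_action`).
#'
#' @param path Path to the file.
#' @param group_col,value_col Column names; defaults `"group"`, `"value"`.
#' @param na_action `"drop"` (default) or `"error"`.
#' @return A tibble with columns `group` (character) and `value` (numeric),
#'   group labels in lexicographic order of first appearance-independent
#'   sorting downstream.
#' @export
read_grouped_table <- function(path, group_col = "group",
                               value_col = "value", na_action = "drop") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!group_col %in% names(raw)) {
    stop("missing column \"", group_col, "\" in ", path)
  }
  if (!value_col %in% names(raw)) {
    stop("missing column \"", value_col, "\" in ", path)
  }
  out <- tibble::tibble(group = as.character(raw[[group_col]]),
                        value = suppressWarnings(as.numeric(raw[[value_col]])))
  bad <- is.na(out$value) | is.na(out$group)
  if (any(bad)) {
    if (na_action == "error") {
      stop(sum(bad), " rows with missing values in ", path)
    }
    message("read_grouped_table: dropped ", sum(bad),
            " row(s) with missing values")
    out <- out[!bad, ]
  }
  if (nrow(out) == 0L) stop("no usable rows in ", path)
  if (length(unique(out$group)) < 2L) stop("need >= 2 groups")
  if (stats::sd(out$value) == 0) stop("all-constant response")
  out
}

#' Write a synthetic grouped fixture
#'
#' Generates a heteroscedastic unbalanced one-way dataset and (optionally)
#' writes it as a two-column CSV. The default preset mimics the layout of a
#' six-group fatty-acid-content comparison: groups labelled PE3-PE7 and
#' PE9, unequal sizes, and group standard deviations spanning more than a
#' factor of two. The written file is byte-identical for a given seed.
#'
#' @param path Optional output CSV path.
#' @param sizes,means,sds,labels Generative spec; defaults give the preset.
#' @param error_law `"normal"` or `"right_skewed"`.
#' @param seed Integer seed.
#' @return The dataset as a tibble (invisibly if `path` is given).
#' @examples
#' head(make_fixture(seed = 1))
#' @export
make_fixture <- function(path = NULL,
                         sizes = c(14, 19, 19, 7, 15, 16),
                         means = c(0.92, 0.91, 0.84, 0.94, 0.91, 1.00),
                         sds = c(0.12, 0.045, 0.04, 0.035, 0.06, 0.05),
                         labels = c("PE3", "PE4", "PE5", "PE6", "PE7", "PE9"),
                         error_law = "normal", seed = 1L) {
  dat <- simulate_one_way(sizes, means = means, sds = sds,
                          error_law = error_law, seed = seed,
                          labels = labels)
  if (!is.null(path)) {
    out <- data.frame(group = dat$group,
                      value = sprintf("%.6f", dat$value))
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    return(invisible(dat))
  }
  dat
}
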