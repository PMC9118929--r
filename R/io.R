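# Readers/writers for the two interchange formats: response matrices
# (plain CSV, one header row of item ids, 0/1 cells) and item banks (CSV
# with a "# D: <value>" header comment, or JSON with a top-level D).

#' Read and write response matrices
#'
#' CSV with a header row of item identifiers and one row of 0/1 cells per
#' person. Lines starting with `#` are treated as comments. Reading
#' validates completeness and binariness, naming the offending cell.
#'
#' @param path File path.
#' @return `read_responses()` returns an integer 0/1 matrix.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) abort(sprintf("'%s' contains no data.", path))
  as_response_matrix(df, arg = path)
}

#' @rdname read_responses
#' @param responses Binary response matrix or data frame.
#' @export
write_responses <- function(responses, path) {
  responses <- as_response_matrix(responses)
  df <- as_tibble(responses, .name_repair = "minimal")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read and write item banks
#'
#' Two formats keyed on the file extension: JSON
#' (`{"D": ..., "items": [{"item": ..., "a": ..., "b": ...}, ...]}`) or CSV
#' with columns `item`, `a`, `b` and the scaling constant on a `# D: <value>`
#' comment line. A bank file without a `D` gets the default 1.702 with a
#' flag.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return `read_bank()` returns an [item_bank()].
#' @export
read_bank <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- obj$items
    d <- obj$D
    bank_df <- as_tibble(items)
  } else {
    lines <- readLines(path)
    d_line <- grep("^#\\s*D\\s*:", lines, value = TRUE)
    d <- if (length(d_line) > 0) as.numeric(sub("^#\\s*D\\s*:\\s*", "", d_line[1])) else NULL
    bank_df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                               progress = FALSE)
  }
  if (is.null(d) || !is.finite(d)) {
    dichrel_note(sprintf("'%s' carries no scaling constant; using D = 1.702.", path),
                 class = "dichrel_default_d")
    d <- 1.702
  }
  if (!all(c("a", "b") %in% names(bank_df))) {
    abort(sprintf("'%s' must provide columns `a` and `b`.", path))
  }
  item_bank(bank_df$a, bank_df$b, D = d,
            item = if ("item" %in% names(bank_df)) bank_df$item else NULL)
}

#' @rdname read_bank
#' @param bank An [item_bank()].
#' @export
write_bank <- function(bank, path) {
  bank <- assert_item_bank(bank)
  d <- scaling_constant(bank)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(D = d, items = as.data.frame(bank[, c("item", "a", "b")])),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# D: %.17g", d), con)
    utils::write.table(as.data.frame(bank[, c("item", "a", "b")]), con,
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a deterministic fixture suite
#'
#' Emits three small files into `dir`: `bank15.csv` (a 15-item bank sampled
#' from the default parameter distributions), `responses500.csv` (an N = 500
#' response matrix simulated from it), and `toy_alpha.csv` (a 4-person,
#' 3-item matrix whose Cronbach's alpha is exactly 0.75). Regeneration with
#' the same seed is bit-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Root seed.
#' @return Invisibly, the written paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(derive_seed(seed, 1))
  bank <- sample_item_parameters(15)
  set.seed(derive_seed(seed, 2))
  y <- simulate_responses(rnorm(500), bank)
  toy <- rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 0L), c(0L, 0L, 0L))
  colnames(toy) <- c("item01", "item02", "item03")
  paths <- file.path(dir, c("bank15.csv", "responses500.csv", "toy_alpha.csv"))
  write_bank(bank, paths[1])
  write_responses(y, paths[2])
  write_responses(toy, paths[3])
  invisible(paths)
}
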