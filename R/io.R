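#' Read a corpus from JSONL or CSV
#'
#' One record per document with columns/fields `doc_id`, `text` and
#' optionally `author_id` and `label`. Format is inferred from the file
#' extension (`.jsonl`/`.json` vs `.csv`) unless given.
#'
#' @param path File path.
#' @param format `"jsonl"`, `"csv"` or `"auto"`.
#' @return A data.frame with one row per document.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    cols <- unique(unlist(lapply(recs, names)))
    df <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
        v <- r[[cn]]
        if (is.null(v)) NA else v
      }), stringsAsFactors = FALSE)
    }))
  }
  stopifnot("text" %in% names(df))
  if (!"doc_id" %in% names(df)) df$doc_id <- as.character(seq_len(nrow(df)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data.frame as JSONL
#'
#' @param df A data.frame; each row becomes one JSON object on its own line.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Read a directed edge list
#'
#' CSV with columns `source_id`, `target_id`; an edge means the source
#' follows the target.
#'
#' @param path File path.
#' @return Two-column character data.frame.
#' @export
read_edges_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("source_id", "target_id") %in% names(df)))
  df[, c("source_id", "target_id")]
}

#' Read a roots file
#'
#' CSV with columns `root_id`, `k_in`, `k_out` (total follower/followee
#' counts before sampling) and optionally `group`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_roots_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("root_id", "k_in", "k_out") %in% names(df)))
  df$root_id <- as.character(df$root_id)
  df
}

#' Read per-user alignment indexes
#'
#' CSV with columns `user_id`, `alpha`. Users without a computable index are
#' simply absent from the file.
#'
#' @param path File path.
#' @return Named numeric vector (names are user ids).
#' @export
read_alpha_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("user_id", "alpha") %in% names(df)))
  stats::setNames(as.numeric(df$alpha), as.character(df$user_id))
}
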