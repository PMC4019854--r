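# Delimited-text input/output: matrix files, dataset manifests.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a connectivity matrix from a delimited text file
#'
#' Accepts comma- or tab-delimited square numeric matrices (auto-detected),
#' with or without a label header row plus label column. Unlabeled files get
#' generated labels `region_0001`, ...
#'
#' @param path File path.
#' @param subject_id,session_id,group Identity to attach to the matrix.
#' @param validate Check [connectivity_matrix()] invariants (default `TRUE`).
#' @return A [connectivity_matrix()].
#' @export
read_matrix <- function(path, subject_id = NA_character_,
                        session_id = NA_character_, group = NA_character_,
                        validate = TRUE) {
  if (!file.exists(path))
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  sep <- detect_sep(path)
  raw <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "character",
                                     stringsAsFactors = FALSE))
  # labeled files carry an empty or non-numeric top-left corner cell
  labeled <- raw[1, 1] == "" || is.na(suppressWarnings(as.numeric(raw[1, 1])))
  if (labeled) {
    labels <- as.character(raw[1, -1])
    body <- raw[-1, -1, drop = FALSE]
  } else {
    labels <- NULL
    body <- raw
  }
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals))
    stop(sprintf("non-numeric entry in matrix file: %s", path), call. = FALSE)
  w <- matrix(vals, nrow = nrow(body), ncol = ncol(body))
  if (nrow(w) != ncol(w))
    stop(sprintf("matrix file is not square (%d x %d): %s",
                 nrow(w), ncol(w), path), call. = FALSE)
  connectivity_matrix(w, labels, subject_id, session_id, group,
                      validate = validate)
}

#' Write a connectivity matrix to a delimited text file
#'
#' Writes a header row of labels, then one row per node of
#' `label, w_1, ..., w_N`. Values are written with full precision so that
#' `read_matrix(write_matrix(m))` round-trips exactly.
#'
#' @param m A [connectivity_matrix()].
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = ",") {
  w <- m$weights
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(paste(c("", m$node_labels), collapse = sep),
             vapply(seq_len(nrow(w)), function(i)
               paste(c(m$node_labels[i], fmt(w[i, ])), collapse = sep),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' A manifest is a delimited table with header columns `file_path`,
#' `subject_id`, `session_id`, `group`, one row per matrix file. Relative
#' `file_path`s are resolved against the manifest's directory. The
#' (subject, session, group) triples must be unique and every file must
#' exist.
#'
#' @param path Manifest file path (comma- or tab-delimited, auto-detected).
#' @return `data.frame` with the four columns, `file_path` resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest file not found: %s", path), call. = FALSE)
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("file_path", "subject_id", "session_id", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  key <- paste(df$subject_id, df$session_id, df$group, sep = "\r")
  if (anyDuplicated(key))
    stop("manifest has duplicate (subject_id, session_id, group) triples",
         call. = FALSE)
  base <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$file_path), df$file_path,
                     file.path(base, df$file_path))
  absent <- resolved[!file.exists(resolved)]
  if (length(absent) > 0)
    stop(sprintf("manifest refers to missing matrix file(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  df$file_path <- resolved
  df[need]
}

#' Load every matrix listed in a manifest
#'
#' @param manifest Manifest path or the `data.frame` from [read_manifest()].
#' @return List of validated [connectivity_matrix()] objects.
#' @export
read_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tryCatch(
      read_matrix(row$file_path, row$subject_id, row$session_id, row$group),
      error = function(e) stop(sprintf(
        "failed to load matrix for (subject=%s, session=%s, group=%s): %s",
        row$subject_id, row$session_id, row$group, conditionMessage(e)),
        call. = FALSE))
  })
}

#' Write a dataset of matrices plus its manifest
#'
#' Writes each matrix as `<subject>_<session>_<group>.csv` in `dir` and a
#' `manifest.csv` indexing them.
#'
#' @param dataset List of [connectivity_matrix()] objects.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(m) {
    fname <- sprintf("%s_%s_%s.csv", m$subject_id, m$session_id, m$group)
    write_matrix(m, file.path(dir, fname))
    data.frame(file_path = fname, subject_id = m$subject_id,
               session_id = m$session_id, group = m$group,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
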