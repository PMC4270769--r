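#' Construct an emotion panel
#'
#' An emotion panel holds one trial record per subject x product combination:
#' a liking score on a 0--100 visual analogue scale, an optional binary
#' choice flag (exactly one chosen product per subject), and a fixed-length
#' vector of emotion-item scores on the instrument's 0--4 response scale.
#' The design must be a complete block: every subject rated every product.
#'
#' @param data data.frame with columns `subject`, `product`, `liking`,
#'   optionally `choice`, and one numeric column per emotion item.
#' @param instrument label for the emotion instrument (e.g. `"premo"`).
#' @param emotion_names character vector naming the emotion columns, in
#'   instrument order. Defaults to all columns other than the reserved ones.
#' @param alternatives ordered product identifiers. Defaults to the sorted
#'   unique products; the first alternative is the reference downstream.
#' @return An object of class `emotion_panel`: the data.frame, rows ordered
#'   by subject then alternative, with attributes `instrument`,
#'   `emotion_names` and `alternatives`.
#' @seealso [read_panel()], [write_panel()], [merge_choice()]
#' @export
emotion_panel <- function(data, instrument = "emotion",
                          emotion_names = NULL, alternatives = NULL) {
  stopifnot(is.data.frame(data))
  reserved <- c("subject", "product", "liking", "choice")
  missing_cols <- setdiff(c("subject", "product", "liking"), names(data))
  if (length(missing_cols)) {
    stop("panel is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(emotion_names)) {
    emotion_names <- setdiff(names(data), reserved)
  }
  if (!length(emotion_names)) stop("panel has no emotion columns", call. = FALSE)
  if (length(bad <- setdiff(emotion_names, names(data)))) {
    stop("emotion column(s) not in data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data$subject <- as.character(data$subject)
  data$product <- as.character(data$product)
  if (is.null(alternatives)) alternatives <- sort(unique(data$product))

  keep <- c("subject", "product", "liking",
            if ("choice" %in% names(data)) "choice", emotion_names)
  data <- data[order(data$subject, match(data$product, alternatives)),
               keep, drop = FALSE]
  rownames(data) <- NULL

  panel <- structure(data,
                     instrument = instrument,
                     emotion_names = emotion_names,
                     alternatives = alternatives,
                     class = c("emotion_panel", "data.frame"))
  validate_panel(panel)
  panel
}

#' Validate an emotion panel
#'
#' Checks the complete-block structure (every subject has exactly one record
#' per alternative), score ranges (liking in \[0, 100\], emotions in
#' \[0, 4\]), absence of missing values, and -- when a `choice` column is
#' present -- that exactly one product is chosen per subject.
#'
#' @param panel an [emotion_panel()].
#' @return The panel, invisibly, if valid; otherwise an error describing the
#'   first violation found, with offending subjects or row indices.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "emotion_panel"))
  alts <- alternatives(panel)
  em <- emotion_names(panel)

  unknown <- setdiff(unique(panel$product), alts)
  if (length(unknown)) {
    stop("unknown product id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(panel$subject, factor(panel$product, levels = alts))
  if (any(tab != 1L)) {
    bad <- rownames(tab)[rowSums(tab != 1L) > 0]
    stop("incomplete block: subject(s) without exactly one record per ",
         "alternative: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("liking", if ("choice" %in% names(panel)) "choice", em)
  for (col in num_cols) {
    v <- panel[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not numeric", call. = FALSE)
    if (anyNA(v)) {
      stop("missing values in column '", col, "' at row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(panel$liking < 0 | panel$liking > 100)) {
    stop("liking outside [0, 100] at row(s): ",
         paste(utils::head(which(panel$liking < 0 | panel$liking > 100), 5),
               collapse = ", "), call. = FALSE)
  }
  E <- as.matrix(panel[, em, drop = FALSE])
  if (any(E < 0 | E > 4)) {
    bad_rows <- which(rowSums(E < 0 | E > 4) > 0)
    stop("emotion score outside [0, 4] at row(s): ",
         paste(utils::head(bad_rows, 5), collapse = ", "), call. = FALSE)
  }
  if ("choice" %in% names(panel)) {
    if (!all(panel$choice %in% c(0, 1))) {
      stop("choice flags must be 0 or 1", call. = FALSE)
    }
    per_subj <- tapply(panel$choice, panel$subject, sum)
    if (any(per_subj != 1)) {
      stop("subject(s) with number of chosen products != 1: ",
           paste(utils::head(names(per_subj)[per_subj != 1], 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  invisible(panel)
}

#' @export
print.emotion_panel <- function(x, ...) {
  cat(sprintf("Emotion panel '%s': %d subjects x %d alternatives, %d emotion items%s\n",
              attr(x, "instrument"), length(unique(x$subject)),
              length(alternatives(x)), length(emotion_names(x)),
              if ("choice" %in% names(x)) ", with choice flags" else ""))
  cat("Alternatives:", paste(alternatives(x), collapse = " "), "\n")
  invisible(x)
}

#' Panel accessors
#'
#' @param panel an [emotion_panel()].
#' @return `alternatives()` the ordered product identifiers,
#'   `emotion_names()` the ordered emotion-item labels, `subjects()` the
#'   sorted subject identifiers, `emotion_matrix()` the numeric trial x item
#'   score matrix in panel row order.
#' @export
alternatives <- function(panel) attr(panel, "alternatives")

#' @rdname alternatives
#' @export
emotion_names <- function(panel) attr(panel, "emotion_names")

#' @rdname alternatives
#' @export
subjects <- function(panel) unique(panel$subject)

#' @rdname alternatives
#' @export
emotion_matrix <- function(panel) {
  as.matrix(panel[, emotion_names(panel), drop = FALSE])
}

#' Describe the column layout of a panel file
#'
#' @param subject,product,liking,choice column names in the file; `choice`
#'   may be `NULL` when the file carries no choice flags (PrEmo-style file).
#' @param emotions character vector of emotion column names, or `NULL` to
#'   take every remaining column, in file order.
#' @param sep field separator; `NULL` autodetects tab vs comma from the
#'   header line (other dialects must be named explicitly).
#' @return A `panel_schema` list used by [read_panel()].
#' @export
panel_schema <- function(subject = "subject", product = "product",
                         liking = "liking", choice = "choice",
                         emotions = NULL, sep = NULL) {
  structure(list(subject = subject, product = product, liking = liking,
                 choice = choice, emotions = emotions, sep = sep),
            class = "panel_schema")
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else stop("cannot autodetect delimiter (neither tab nor comma in header); ",
            "pass sep= in the schema", call. = FALSE)
}

#' Read a long-format panel file
#'
#' Reads a delimited text file with one row per subject x product trial:
#' subject id, product id, liking (100-point VAS), an optional binary choice
#' column, and the emotion-item scores. The file is validated as a complete
#' block on return; emotion column order is preserved as given.
#'
#' @param path file path.
#' @param schema a [panel_schema()] mapping column names.
#' @param instrument label stored on the returned panel.
#' @param alternatives optional ordered product set; defaults to the sorted
#'   products found in the file.
#' @return A validated [emotion_panel()].
#' @export
read_panel <- function(path, schema = panel_schema(),
                       instrument = "emotion", alternatives = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- schema$sep %||% detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (role in c("subject", "product", "liking")) {
    if (!schema[[role]] %in% names(raw)) {
      stop("schema error: column '", schema[[role]], "' (", role,
           ") not found in ", path, call. = FALSE)
    }
  }
  has_choice <- !is.null(schema$choice) && schema$choice %in% names(raw)
  em <- schema$emotions %||%
    setdiff(names(raw), c(schema$subject, schema$product, schema$liking,
                          schema$choice))
  if (length(bad <- setdiff(em, names(raw)))) {
    stop("schema error: emotion column(s) not found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (col in c(schema$liking, if (has_choice) schema$choice, em)) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      if (anyNA(parsed) && !anyNA(v)) {
        stop("parse error: non-numeric value in column '", col,
             "' at row(s): ",
             paste(utils::head(which(is.na(parsed)), 5), collapse = ", "),
             call. = FALSE)
      }
      raw[[col]] <- parsed
    }
  }
  out <- data.frame(subject = as.character(raw[[schema$subject]]),
                    product = as.character(raw[[schema$product]]),
                    liking = raw[[schema$liking]],
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (has_choice) out$choice <- raw[[schema$choice]]
  out[em] <- raw[em]
  emotion_panel(out, instrument = instrument, emotion_names = em,
                alternatives = alternatives)
}

#' Write a panel as a long-format delimited file
#'
#' The `"s2"` format carries the choice column; `"s3"` omits it (the
#' PrEmo-style file in the original study design lacked choice flags, which
#' are joined back from the companion file with [merge_choice()]).
#'
#' @param panel an [emotion_panel()].
#' @param path output file path.
#' @param format `"s2"` (with choice) or `"s3"` (without).
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("s2", "s3"), sep = "\t") {
  format <- match.arg(format)
  validate_panel(panel)
  df <- as.data.frame(panel)
  if (format == "s3") df$choice <- NULL
  if (format == "s2" && !"choice" %in% names(df)) {
    stop("panel has no choice flags; cannot write s2 format", call. = FALSE)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join choice flags from a companion panel
#'
#' Copies the binary choice flags from `choice_source` onto `panel` by
#' (subject, product) key. Both panels must cover exactly the same keys.
#'
#' @param panel target [emotion_panel()] (may already carry flags, which are
#'   then overwritten by identical values or rejected on conflict-free join).
#' @param choice_source panel carrying a validated `choice` column.
#' @return `panel` with choice flags, validated (one chosen per subject).
#' @export
merge_choice <- function(panel, choice_source) {
  stopifnot(inherits(panel, "emotion_panel"),
            inherits(choice_source, "emotion_panel"))
  if (!"choice" %in% names(choice_source)) {
    stop("choice_source has no choice column", call. = FALSE)
  }
  key <- function(p) paste(p$subject, p$product, sep = "\r")
  k_target <- key(panel); k_source <- key(choice_source)
  orphans <- c(setdiff(k_target, k_source), setdiff(k_source, k_target))
  if (length(orphans)) {
    stop("join error: (subject, product) keys not shared by both panels: ",
         paste(utils::head(gsub("\r", "/", orphans), 5), collapse = ", "),
         call. = FALSE)
  }
  panel$choice <- choice_source$choice[match(k_target, k_source)]
  validate_panel(panel)
  panel
}

#' Write a deterministic multi-table report
#'
#' Writes a named list of data.frames as a single structured text file:
#' each table under a `## name` heading, tab-separated, numeric cells
#' formatted with a fixed format so identical inputs yield byte-identical
#' files.
#'
#' @param results named list of data.frames (an empty data.frame yields a
#'   header-only table).
#' @param path output path.
#' @param digits significant digits used for numeric formatting.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, digits = 6) {
  stopifnot(is.list(results), !is.null(names(results)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                   format = "g"))
    writeLines(paste0("## ", nm), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df)) {
      writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
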