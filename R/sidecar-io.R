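# --- schema plumbing ---------------------------------------------------------

#' Load a shipped sidecar schema
#'
#' Schemas are JSON documents under `inst/extdata/schemas/`, one per
#' metadata artifact kind: `meg`, `coordsystem`, `dataset_description`,
#' `T1w` (JSON kind) and `channels`, `events`, `scans`, `participants`
#' (TSV kind). They are the single source of truth shared by the reader,
#' the writer and the validator.
#'
#' @param id Schema identifier.
#' @return The schema as a list.
#' @export
sidecar_schema <- function(id) {
  key <- paste0("schema_", id)
  if (is.null(.megbids_cache[[key]])) {
    path <- system.file("extdata", "schemas", paste0(id, ".json"),
                        package = "megbids")
    if (!nzchar(path)) stop("unknown schema '", id, "'", call. = FALSE)
    .megbids_cache[[key]] <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                simplifyDataFrame = FALSE,
                                                simplifyMatrix = FALSE)
  }
  .megbids_cache[[key]]
}

violation <- function(code, severity, field, message) {
  data.frame(code = code, severity = severity, field = field,
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(code = character(0), severity = character(0),
             field = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

bind_violations <- function(...) {
  vs <- Filter(function(v) !is.null(v) && nrow(v) > 0, list(...))
  if (!length(vs)) return(no_violations())
  do.call(rbind, vs)
}

is_scalar_number <- function(v) {
  is.numeric(v) && length(v) == 1L && is.finite(v)
}

is_vec3 <- function(v) is.numeric(v) && length(v) == 3L && all(is.finite(v))

# type check for one JSON value; returns NULL when fine, else a message
json_type_error <- function(value, type) {
  ok <- switch(type,
    string = is.character(value) && length(value) == 1L && !is.na(value),
    number = is_scalar_number(value),
    integer = is_scalar_number(value) && value == round(value),
    boolean = is.logical(value) && length(value) == 1L && !is.na(value),
    object_or_na = (is.list(value) && !is.null(names(value))) ||
      identical(value, "n/a") ||
      (is.list(value) && length(value) == 0L),
    string_array = is.character(value) && !anyNA(value),
    vec3 = is_vec3(value),
    landmarks = is.list(value) && setequal(names(value),
                                           c("NAS", "LPA", "RPA")) &&
      all(vapply(value, is_vec3, logical(1))),
    coilmap = is.list(value) && !is.null(names(value)) &&
      all(nzchar(names(value))) &&
      all(vapply(value, is_vec3, logical(1))),
    stop("unknown schema type '", type, "'", call. = FALSE))
  if (ok) NULL else paste0("expected ", type)
}

check_json_document <- function(doc, schema, check_required = TRUE) {
  v <- no_violations()
  req <- schema$required
  opt <- schema$optional
  if (check_required) {
    for (k in setdiff(names(req), names(doc))) {
      v <- bind_violations(v, violation("MISSING-KEY", "ERROR", k,
                                        paste0("required key '", k,
                                               "' is missing")))
    }
  }
  typed <- c(req, opt)
  for (k in intersect(names(doc), names(typed))) {
    err <- json_type_error(doc[[k]], typed[[k]])
    if (!is.null(err)) {
      v <- bind_violations(v, violation("TYPE", "ERROR", k,
                                        paste0("key '", k, "': ", err)))
      next
    }
    allowed <- schema$vocab[[k]]
    if (!is.null(allowed) && !doc[[k]] %in% unlist(allowed)) {
      v <- bind_violations(v, violation("VOCAB", "ERROR", k,
        paste0("key '", k, "': value '", doc[[k]],
               "' not in {", paste(unlist(allowed), collapse = ", "), "}")))
    }
    xmin <- schema$exclusive_min[[k]]
    if (!is.null(xmin) && is.numeric(doc[[k]]) && any(doc[[k]] <= xmin)) {
      v <- bind_violations(v, violation("RANGE", "ERROR", k,
        paste0("key '", k, "' must be > ", xmin)))
    }
    mn <- schema$min[[k]]
    if (!is.null(mn) && is.numeric(doc[[k]]) && any(doc[[k]] < mn)) {
      v <- bind_violations(v, violation("RANGE", "ERROR", k,
        paste0("key '", k, "' must be >= ", mn)))
    }
  }
  for (k in setdiff(names(doc), names(typed))) {
    v <- bind_violations(v, violation("UNKNOWN-KEY", "INFO", k,
      paste0("key '", k, "' is not part of the schema (kept verbatim)")))
  }
  v
}

# --- JSON --------------------------------------------------------------------

#' Read a JSON sidecar with schema checking
#'
#' Parses strictly as UTF-8 JSON and reports typed violations (missing
#' required key, wrong type, out-of-vocabulary value, out-of-range number)
#' without aborting. Unknown keys are preserved verbatim and reported as
#' informational. Malformed JSON yields a single fatal-for-this-file
#' `JSON-PARSE` violation and a `NULL` document.
#'
#' @param path File to read.
#' @param schema Schema id (see [sidecar_schema()]) or `NULL` to skip
#'   checking.
#' @param check_required Report missing required keys? Set `FALSE` when
#'   reading a partial inheritance sidecar, where dropped keys are
#'   legitimate.
#' @return List with `document` (named list or `NULL`), `violations`
#'   (data frame `code`, `severity`, `field`, `message`), `path`.
#' @export
read_json_sidecar <- function(path, schema = NULL, check_required = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) e)
  if (inherits(doc, "error")) {
    return(list(document = NULL,
                violations = violation("JSON-PARSE", "ERROR", "<file>",
                                       paste("malformed JSON:",
                                             conditionMessage(doc))),
                path = path))
  }
  if (!is.list(doc)) {
    return(list(document = NULL,
                violations = violation("JSON-PARSE", "ERROR", "<file>",
                                       "top level is not a JSON object"),
                path = path))
  }
  v <- if (is.null(schema)) no_violations()
       else check_json_document(doc, sidecar_schema(schema), check_required)
  list(document = doc, violations = v, path = path)
}

order_keys <- function(doc, schema) {
  pref <- unlist(schema$key_order)
  known <- intersect(pref, names(doc))
  extra <- sort_c(setdiff(names(doc), pref))
  doc[c(known, extra)]
}

#' Write a JSON sidecar deterministically
#'
#' Serialisation is canonical: schema key order first, then remaining keys
#' byte-sorted; 4-space indent; trailing newline. Repeated writes of the
#' same document are byte-identical. Documents violating their schema's
#' invariants are refused (naming the offending key) unless
#' `partial = TRUE`, which permits missing required keys for inheritance
#' sidecars but still refuses type violations.
#'
#' @param document Named list.
#' @param path Output file.
#' @param schema Schema id or `NULL` (then keys are byte-sorted).
#' @param partial Allow missing required keys?
#' @return `path`, invisibly.
#' @export
write_json_sidecar <- function(document, path, schema = NULL,
                               partial = FALSE) {
  if (!is.list(document) || (length(document) && is.null(names(document)))) {
    stop("document must be a named list", call. = FALSE)
  }
  if (!is.null(schema)) {
    sc <- sidecar_schema(schema)
    v <- check_json_document(document, sc, check_required = !partial)
    v <- v[v$severity == "ERROR", , drop = FALSE]
    if (nrow(v)) {
      stop("refusing to write '", path, "': ", v$message[1], call. = FALSE)
    }
    document <- order_keys(document, sc)
  } else {
    document <- document[sort_c(names(document))]
  }
  json <- jsonlite::toJSON(document, pretty = 4, auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# --- TSV ---------------------------------------------------------------------

tsv_cell_error <- function(cells, type) {
  # returns logical vector: TRUE where the cell violates the type
  switch(type,
    string = rep(FALSE, length(cells)),
    number = is.na(suppressWarnings(as.numeric(cells))),
    number_or_na = cells != "n/a" &
      is.na(suppressWarnings(as.numeric(cells))),
    integer = is.na(suppressWarnings(as.integer(cells))),
    integer_or_na = cells != "n/a" &
      is.na(suppressWarnings(as.integer(cells))),
    datetime_or_na = cells != "n/a" &
      !grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(Z|[+-]\\d{2}:?\\d{2})?$",
             cells),
    stop("unknown column type '", type, "'", call. = FALSE))
}

#' Read a TSV metadata table with schema checking
#'
#' Tab-delimited, first row is the header; the exact lowercase string
#' `"n/a"` is the sole missing-value sentinel and decodes to `NA`. Ragged
#' rows (padded/truncated to the header), duplicate headers, missing
#' mandatory columns, type, vocabulary and uniqueness defects are reported
#' as violations; the reader never aborts on content.
#'
#' @param path File to read.
#' @param schema Schema id (see [sidecar_schema()]) or `NULL`.
#' @return List with `table` (data frame of character/numeric columns),
#'   `violations`, `path`.
#' @export
read_tsv_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  v <- no_violations()
  if (!length(lines) || !nzchar(lines[1])) {
    return(list(table = NULL,
                violations = violation("EMPTY-TABLE", "ERROR", "<file>",
                                       "file has no header row"),
                path = path))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    dup <- unique(header[duplicated(header)])
    v <- bind_violations(v, violation("DUP-COLUMN", "ERROR",
                                      paste(dup, collapse = ","),
                                      "duplicate column header"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  n <- length(header)
  ragged <- which(lengths(cells) != n)
  for (i in ragged) {
    v <- bind_violations(v, violation("RAGGED-ROW", "ERROR",
                                      paste0("row ", i),
                                      paste0("row ", i, " has ",
                                             length(cells[[i]]),
                                             " fields, header has ", n)))
    cells[[i]] <- c(cells[[i]], rep("n/a", max(0, n - length(cells[[i]]))))[
      seq_len(n)]
  }
  tab <- as.data.frame(do.call(rbind, c(list(matrix(character(0), 0, n)),
                                        cells)),
                       stringsAsFactors = FALSE)
  names(tab) <- make.unique(header)
  if (!is.null(schema)) {
    sc <- sidecar_schema(schema)
    for (col in sc$columns) {
      if (isTRUE(col$required) && !col$name %in% header) {
        v <- bind_violations(v, violation("MISSING-COLUMN", "ERROR",
                                          col$name,
                                          paste0("mandatory column '",
                                                 col$name, "' is absent")))
        next
      }
      if (!col$name %in% names(tab)) next
      cells_col <- tab[[col$name]]
      bad <- tsv_cell_error(cells_col, col$type)
      for (i in which(bad)) {
        v <- bind_violations(v, violation("TYPE", "ERROR", col$name,
          paste0("column '", col$name, "', row ", i, ": '", cells_col[i],
                 "' is not a valid ", col$type)))
      }
      if (!is.null(col$vocab)) {
        out <- !bad & cells_col != "n/a" &
          !cells_col %in% unlist(col$vocab)
        for (i in which(out)) {
          v <- bind_violations(v, violation("VOCAB", "ERROR", col$name,
            paste0("column '", col$name, "', row ", i, ": '", cells_col[i],
                   "' not in controlled vocabulary")))
        }
      }
      if (isTRUE(col$unique)) {
        dups <- unique(cells_col[duplicated(cells_col) & cells_col != "n/a"])
        for (d in dups) {
          v <- bind_violations(v, violation("DUP-VALUE", "ERROR", col$name,
            paste0("column '", col$name, "': duplicate value '", d, "'")))
        }
      }
      if (!is.null(col$pattern)) {
        nomatch <- cells_col != "n/a" & !grepl(col$pattern, cells_col)
        for (i in which(nomatch)) {
          v <- bind_violations(v, violation("PATTERN", "ERROR", col$name,
            paste0("column '", col$name, "', row ", i, ": '", cells_col[i],
                   "' does not match ", col$pattern)))
        }
      }
      if (!is.null(col$min) && col$type %in% c("number", "number_or_na",
                                               "integer", "integer_or_na")) {
        num <- suppressWarnings(as.numeric(cells_col))
        low <- which(!is.na(num) & num < col$min)
        for (i in low) {
          v <- bind_violations(v, violation("RANGE", "ERROR", col$name,
            paste0("column '", col$name, "', row ", i, ": ", cells_col[i],
                   " < ", col$min)))
        }
      }
    }
    # decode: numeric columns to numeric, "n/a" to NA
    for (col in sc$columns) {
      if (!col$name %in% names(tab)) next
      x <- tab[[col$name]]
      x[x == "n/a"] <- NA
      if (col$type %in% c("number", "number_or_na", "integer",
                          "integer_or_na")) {
        x <- suppressWarnings(as.numeric(x))
      }
      tab[[col$name]] <- x
    }
    extra <- setdiff(names(tab), vapply(sc$columns, `[[`, "", "name"))
    for (e in extra) tab[[e]][tab[[e]] == "n/a"] <- NA
  } else {
    for (j in seq_along(tab)) tab[[j]][tab[[j]] == "n/a"] <- NA
  }
  list(table = tab, violations = v, path = path)
}

format_tsv_cell <- function(x) {
  if (is.na(x)) return("n/a")
  if (is.numeric(x)) return(format(x, scientific = FALSE, trim = TRUE,
                                   drop0trailing = TRUE))
  as.character(x)
}

#' Write a TSV metadata table deterministically
#'
#' Schema column order first, then extra columns in byte order; `NA`
#' encoded as `"n/a"`; LF line endings; trailing newline. Refuses to write
#' a table missing one of its schema's mandatory columns.
#'
#' @param table Data frame.
#' @param path Output file.
#' @param schema Schema id or `NULL`.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path, schema = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(schema)) {
    sc <- sidecar_schema(schema)
    want <- vapply(sc$columns, `[[`, "", "name")
    req <- vapply(sc$columns, function(c) isTRUE(c$required), logical(1))
    missing_req <- setdiff(want[req], names(table))
    if (length(missing_req)) {
      stop("refusing to write '", path, "': mandatory column '",
           missing_req[1], "' is absent", call. = FALSE)
    }
    cols <- c(intersect(want, names(table)),
              sort_c(setdiff(names(table), want)))
    table <- table[, cols, drop = FALSE]
  }
  body <- if (nrow(table)) {
    vapply(seq_len(nrow(table)), function(i) {
      paste(vapply(seq_along(table),
                   function(j) format_tsv_cell(table[[j]][i]),
                   character(1)),
            collapse = "\t")
    }, character(1))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(table), collapse = "\t"), body), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}
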