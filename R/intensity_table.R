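#' Intensity data table
#'
#' The central measurement record of the package: one row per analyzed
#' line, carrying full provenance (file, strip, line, background
#' correction method and its parameters, grayscale conversion, inversion
#' flag) next to the measured mean and median signal, so every value in
#' the table can be reproduced from its own row.
#'
#' @return An empty intensity table (data frame with the canonical
#'   columns).
#' @export
intensity_table <- function() {
  data.frame(file = character(), strip = integer(), line = integer(),
             method = character(), offset = numeric(),
             quantile_prob = numeric(), mode = character(),
             inverted = logical(),
             mean_signal = numeric(), median_signal = numeric(),
             stringsAsFactors = FALSE)
}

intensity_key_cols <- c("file", "strip", "line", "method", "offset",
                        "quantile_prob", "mode", "inverted")

# grouping key robust to NA values (interaction() would drop NA groups);
# factor on first appearance keeps the input row order stable
group_key <- function(table, cols) {
  k <- do.call(paste, c(lapply(table[cols], function(x)
    ifelse(is.na(x), "<NA>", as.character(x))), sep = "\r"))
  factor(k, levels = unique(k))
}

#' Convert extracted line intensities to intensity records
#'
#' @param lines data frame from [extract_line_intensities()].
#' @param file source image identifier.
#' @param spec the [threshold_spec()] used.
#' @return Data frame of intensity records.
#' @export
as_intensity_records <- function(lines, file, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  data.frame(file = file, strip = lines$strip, line = lines$line,
             method = spec$method, offset = spec$offset,
             quantile_prob = if (spec$method == "quantile")
               spec$quantile_prob else NA_real_,
             mode = spec$mode, inverted = spec$inverted,
             mean_signal = lines$mean_signal,
             median_signal = lines$median_signal,
             stringsAsFactors = FALSE)
}

#' Append measurement records to an intensity table
#'
#' A record with the same key (file, strip, line and all settings) as an
#' existing row replaces that row with a warning, so re-analyzing a strip
#' updates rather than duplicates.
#'
#' @param table an intensity table.
#' @param records one or more rows with the canonical columns (e.g. from
#'   [as_intensity_records()]).
#' @return The grown table.
#' @export
append_record <- function(table, records) {
  missing <- setdiff(names(intensity_table()), names(records))
  if (length(missing))
    stop("record is missing required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  records <- records[, names(intensity_table())]
  bad <- !is.finite(records$mean_signal) | records$mean_signal < 0 |
         !is.finite(records$median_signal) | records$median_signal < 0
  if (any(bad))
    stop("signal values must be finite and non-negative", call. = FALSE)
  key <- function(df) do.call(paste, c(df[intensity_key_cols], sep = "\r"))
  dup <- key(table) %in% key(records)
  if (any(dup)) {
    warning(sum(dup), " existing record(s) replaced by re-measurement",
            call. = FALSE)
    table <- table[!dup, ]
  }
  out <- rbind(table, records)
  rownames(out) <- NULL
  out
}

#' Read / write intensity (or experiment) tables as CSV
#'
#' `read_table_csv()` understands common CSV dialects: separator comma,
#' semicolon or tab, decimal point or comma, and an optional preamble to
#' skip. `write_table_csv()` writes the default dialect (comma separator,
#' decimal point, header row), for which the round-trip is lossless.
#'
#' @param path file path.
#' @param sep field separator: `","`, `";"` or `"\t"`.
#' @param dec decimal mark: `"."` or `","`.
#' @param skip_rows preamble lines to drop before the header.
#' @return `read_table_csv()`: a data frame. `write_table_csv()`: `path`,
#'   invisibly.
#' @export
read_table_csv <- function(path, sep = ",", dec = ".", skip_rows = 0L) {
  if (!file.exists(path))
    stop("cannot read table: file not found: ", path, call. = FALSE)
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                      skip = skip_rows, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e)
      stop("failed to parse ", path, ": ", conditionMessage(e),
           call. = FALSE))
  # an all-NA column carries no type information; treat it as numeric so
  # intensity tables (quantile_prob is NA for automatic methods)
  # round-trip losslessly
  for (cl in names(out))
    if (is.logical(out[[cl]]) && all(is.na(out[[cl]])))
      out[[cl]] <- as.numeric(out[[cl]])
  out
}

#' @rdname read_table_csv
#' @param table data frame to write.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Merge intensity data with experiment metadata
#'
#' Inner join on the named key columns. Intensity rows without a match
#' are dropped and counted (attribute `n_unmatched`, plus a message);
#' duplicated keys on the experiment side are ambiguous and an error.
#'
#' @param intensity intensity table.
#' @param experiment experiment table (e.g. concentrations per sample).
#' @param key_intensity,key_experiment names of the join key columns.
#' @return Merged data frame with attribute `n_unmatched`.
#' @export
merge_experiment <- function(intensity, experiment,
                             key_intensity, key_experiment) {
  if (!key_intensity %in% names(intensity))
    stop("key column '", key_intensity, "' not found in intensity data",
         call. = FALSE)
  if (!key_experiment %in% names(experiment))
    stop("key column '", key_experiment, "' not found in experiment data",
         call. = FALSE)
  if (anyDuplicated(experiment[[key_experiment]]))
    stop("experiment key column '", key_experiment,
         "' contains duplicated values; merge would be ambiguous",
         call. = FALSE)
  merged <- merge(intensity, experiment,
                  by.x = key_intensity, by.y = key_experiment, sort = FALSE)
  n_unmatched <- nrow(intensity) - nrow(merged)
  if (n_unmatched > 0)
    message(n_unmatched, " intensity row(s) had no matching experiment key")
  attr(merged, "n_unmatched") <- n_unmatched
  merged
}

#' Average technical replicates
#'
#' Collapses the table to one row per group, replacing every numeric
#' non-grouping column by its group mean and adding a replicate count
#' column `n_replicates`. Non-numeric non-grouping columns are kept when
#' constant within every group, otherwise dropped.
#'
#' @param table data frame.
#' @param group_cols character vector of grouping column names.
#' @return Aggregated data frame.
#' @export
average_replicates <- function(table, group_cols) {
  missing <- setdiff(group_cols, names(table))
  if (length(missing))
    stop("unknown grouping column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  other <- setdiff(names(table), group_cols)
  num <- other[vapply(table[other], is.numeric, logical(1))]
  chr <- setdiff(other, num)
  idx <- split(seq_len(nrow(table)), group_key(table, group_cols))
  rows <- lapply(idx, function(i) {
    out <- table[i[1], group_cols, drop = FALSE]
    for (cl in num) out[[cl]] <- mean(table[[cl]][i])
    for (cl in chr) {
      v <- unique(table[[cl]][i])
      if (length(v) == 1L) out[[cl]] <- v
    }
    out$n_replicates <- length(i)
    out
  })
  keep <- Reduce(intersect, lapply(rows, names))
  out <- do.call(rbind, lapply(rows, function(r) r[keep]))
  rownames(out) <- NULL
  out
}

#' Reshape intensity data between long and wide layout
#'
#' `reshape_wide()` turns the long table (one row per line) into one row
#' per (file, strip) with columns `<label>_mean` and `<label>_median`,
#' where `line_labels` names the lines top to bottom — typically
#' `c("tl", "cl")` for a test line above a control line. The settings
#' columns are carried along. `reshape_long()` is its inverse.
#'
#' @param table long intensity table.
#' @param line_labels character vector, one label per distinct line
#'   index, in top-to-bottom order.
#' @return The reshaped data frame.
#' @export
reshape_wide <- function(table, line_labels) {
  lines <- sort(unique(table$line))
  if (length(line_labels) != length(lines))
    stop("need exactly ", length(lines), " line label(s), got ",
         length(line_labels), call. = FALSE)
  id_cols <- setdiff(names(table), c("line", "mean_signal", "median_signal"))
  g <- group_key(table, id_cols)
  rows <- lapply(split(seq_len(nrow(table)), g), function(i) {
    out <- table[i[1], id_cols, drop = FALSE]
    for (j in seq_along(lines)) {
      k <- i[table$line[i] == lines[j]]
      out[[paste0(line_labels[j], "_mean")]] <-
        if (length(k)) table$mean_signal[k[1]] else NA_real_
      out[[paste0(line_labels[j], "_median")]] <-
        if (length(k)) table$median_signal[k[1]] else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname reshape_wide
#' @export
reshape_long <- function(table, line_labels) {
  sig_cols <- c(paste0(line_labels, "_mean"), paste0(line_labels, "_median"))
  missing <- setdiff(sig_cols, names(table))
  if (length(missing))
    stop("wide table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  id_cols <- setdiff(names(table), sig_cols)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    do.call(rbind, lapply(seq_along(line_labels), function(j) {
      out <- table[i, id_cols, drop = FALSE]
      out$line <- j - 1L
      out$mean_signal <- table[[paste0(line_labels[j], "_mean")]][i]
      out$median_signal <- table[[paste0(line_labels[j], "_median")]][i]
      out
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- restricted filter grammar -------------------------------------------

#' Subset a table with a restricted, injection-safe predicate
#'
#' Filters rows with a small predicate language instead of evaluating
#' arbitrary code: clauses of the form `column op constant` with
#' `op` one of `==`, `!=`, `<`, `<=`, `>`, `>=`, `in`, combined with
#' `and`, `or`, `not` and parentheses. Constants are numbers, quoted
#' strings, `TRUE`/`FALSE`; `in` takes a parenthesized, comma-separated
#' constant list.
#'
#' Examples: `"concentration >= 0"`,
#' `"(strip == 1) and (line == 0)"`,
#' `"method in ('otsu', 'li') and not (offset > 0)"`.
#'
#' @param table data frame.
#' @param predicate predicate string in the grammar above.
#' @return The filtered data frame.
#' @export
subset_table <- function(table, predicate) {
  keep <- eval_predicate(parse_predicate(predicate), table)
  out <- table[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

tokenize_predicate <- function(src) {
  pats <- c(lparen = "\\(", rparen = "\\)", comma = ",",
            op = "(==|!=|<=|>=|<|>)",
            number = "-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
            string = "'[^']*'|\"[^\"]*\"",
            word = "[A-Za-z_.][A-Za-z0-9_.]*",
            ws = "[ \t\n]+")
  tokens <- list(); pos <- 1L
  while (pos <= nchar(src)) {
    hit <- NULL
    for (ty in names(pats)) {
      mm <- regexpr(paste0("^(", pats[[ty]], ")"), substring(src, pos))
      if (mm[1] == 1) {
        hit <- list(type = ty,
                    text = substring(src, pos,
                                     pos + attr(mm, "match.length") - 1L),
                    pos = pos)
        break
      }
    }
    if (is.null(hit))
      stop("malformed predicate at position ", pos, ": '",
           substring(src, pos, pos + 10L), "'", call. = FALSE)
    pos <- pos + nchar(hit$text)
    if (hit$type != "ws") tokens[[length(tokens) + 1L]] <- hit
  }
  tokens
}

parse_predicate <- function(src) {
  stopifnot(is.character(src), length(src) == 1L)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokenize_predicate(src)
  st$i <- 1L
  peek <- function() if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
  advance <- function() { tk <- peek(); st$i <- st$i + 1L; tk }
  expect <- function(type, what = type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type)
      stop("expected ", what, " at position ",
           if (is.null(tk)) nchar(src) + 1L else tk$pos, call. = FALSE)
    advance()
  }
  is_word <- function(tk, w) !is.null(tk) && tk$type == "word" &&
    tolower(tk$text) == w

  parse_const <- function() {
    tk <- peek()
    if (is.null(tk)) stop("expected a constant at end of predicate",
                          call. = FALSE)
    if (tk$type == "number") { advance(); return(as.numeric(tk$text)) }
    if (tk$type == "string") {
      advance(); return(substring(tk$text, 2L, nchar(tk$text) - 1L))
    }
    if (tk$type == "word" && tolower(tk$text) %in% c("true", "false")) {
      advance(); return(tolower(tk$text) == "true")
    }
    stop("expected a constant at position ", tk$pos, ", got '", tk$text,
         "'", call. = FALSE)
  }
  parse_clause <- function() {
    col <- expect("word", "a column name")
    tk <- peek()
    if (is_word(tk, "in")) {
      advance(); expect("lparen", "'('")
      vals <- list(parse_const())
      while (!is.null(peek()) && peek()$type == "comma") {
        advance(); vals[[length(vals) + 1L]] <- parse_const()
      }
      expect("rparen", "')'")
      return(list(kind = "in", column = col$text, pos = col$pos,
                  values = vals))
    }
    op <- expect("op", "a comparator")
    list(kind = "cmp", column = col$text, pos = col$pos, op = op$text,
         value = parse_const())
  }
  parse_factor <- function() {
    tk <- peek()
    if (is_word(tk, "not")) {
      advance(); return(list(kind = "not", arg = parse_factor()))
    }
    if (!is.null(tk) && tk$type == "lparen") {
      advance(); e <- parse_or(); expect("rparen", "')'"); return(e)
    }
    parse_clause()
  }
  parse_and <- function() {
    e <- parse_factor()
    while (is_word(peek(), "and")) {
      advance(); e <- list(kind = "and", lhs = e, rhs = parse_factor())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (is_word(peek(), "or")) {
      advance(); e <- list(kind = "or", lhs = e, rhs = parse_and())
    }
    e
  }
  ast <- parse_or()
  if (!is.null(peek()))
    stop("unexpected input at position ", peek()$pos, ": '", peek()$text,
         "'", call. = FALSE)
  ast
}

eval_predicate <- function(ast, table) {
  col <- function(node) {
    if (!node$column %in% names(table))
      stop("unknown column '", node$column, "' at position ", node$pos,
           call. = FALSE)
    table[[node$column]]
  }
  switch(ast$kind,
    cmp = {
      x <- col(ast)
      switch(ast$op,
        "==" = x == ast$value, "!=" = x != ast$value,
        "<" = x < ast$value, "<=" = x <= ast$value,
        ">" = x > ast$value, ">=" = x >= ast$value)
    },
    "in" = col(ast) %in% unlist(ast$values),
    "not" = !eval_predicate(ast$arg, table),
    "and" = eval_predicate(ast$lhs, table) & eval_predicate(ast$rhs, table),
    "or" = eval_predicate(ast$lhs, table) | eval_predicate(ast$rhs, table))
}
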