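# TQL parsing ------------------------------------------------------------
#
# A TQL program is a sequence of variable definitions ("var name = <expr>",
# with "var" and the name optionally juxtaposed as printed in published
# queries, e.g. "varstroke=") followed by a final expression executed as the
# query.  Variables are forward-only: a $reference must name a variable
# defined above it.  Command keywords are case-insensitive; codes, phrases
# and variable names are case-sensitive.  All commands are written in fully
# parenthesized call form.  Lines starting with '#' are comments.

stop_parse <- function(msg, line = NA_integer_, col = NA_integer_) {
  loc <- if (!is.na(line)) sprintf(" (line %d, col %d)", line, col) else ""
  stop(structure(class = c("tql_parse_error", "error", "condition"),
                 list(message = paste0(msg, loc), call = NULL)))
}

normalize_tql <- function(text) {
  text <- gsub("[“”„″]", "\"", text)
  text <- gsub("[‘’′]", "'", text)
  text <- gsub("[−–—]", "-", text)
  gsub(" ", " ", text)
}

#' Tokenize TQL source text
#'
#' @param text TQL source (single string; may span lines). Typographic
#'   quotes and minus signs are normalized to their ASCII forms first.
#' @return A data frame of tokens with columns `type` (`ident`, `ref`,
#'   `str`, `num`, `punct`), `text`, `num`, `line`, `col`.
#' @export
tokenize_tql <- function(text) {
  text <- normalize_tql(paste(text, collapse = "\n"))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  toks <- list()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      rest <- substring(s, i)
      if (grepl("^\\s", rest)) {
        i <- i + attr(regexpr("^\\s+", rest), "match.length")
        next
      }
      if (startsWith(rest, "#")) break  # comment to end of line
      if (startsWith(rest, "\"")) {
        m <- regexpr("^\"[^\"]*\"", rest)
        if (m == -1L) stop_parse("unterminated string", ln, i)
        len <- attr(m, "match.length")
        toks[[length(toks) + 1L]] <- list(type = "str",
                                          text = substring(rest, 2L, len - 1L),
                                          num = NA_real_, line = ln, col = i)
        i <- i + len
        next
      }
      m <- regexpr("^[0-9]+(\\.[0-9]+)?", rest)
      if (m != -1L) {
        len <- attr(m, "match.length")
        lit <- substring(rest, 1L, len)
        toks[[length(toks) + 1L]] <- list(type = "num", text = lit,
                                          num = as.numeric(lit), line = ln, col = i)
        i <- i + len
        next
      }
      m <- regexpr("^\\$[A-Za-z_][A-Za-z0-9_]*", rest)
      if (m != -1L) {
        len <- attr(m, "match.length")
        toks[[length(toks) + 1L]] <- list(type = "ref",
                                          text = substring(rest, 2L, len),
                                          num = NA_real_, line = ln, col = i)
        i <- i + len
        next
      }
      m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest)
      if (m != -1L) {
        len <- attr(m, "match.length")
        toks[[length(toks) + 1L]] <- list(type = "ident",
                                          text = substring(rest, 1L, len),
                                          num = NA_real_, line = ln, col = i)
        i <- i + len
        next
      }
      ch <- substring(rest, 1L, 1L)
      if (ch %in% c("(", ")", ",", "=", "*", "+", "-")) {
        toks[[length(toks) + 1L]] <- list(type = "punct", text = ch,
                                          num = NA_real_, line = ln, col = i)
        i <- i + 1L
        next
      }
      stop_parse(paste0("illegal character '", ch, "'"), ln, i)
    }
  }
  if (!length(toks)) {
    return(data.frame(type = character(0), text = character(0),
                      num = numeric(0), line = integer(0), col = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(toks, function(t) {
    data.frame(type = t$type, text = t$text, num = t$num,
               line = t$line, col = t$col, stringsAsFactors = FALSE)
  }))
}

UNARY_CMDS <- c("INVERT", "ORIGINAL", "FIRST_MENTION", "NO_HISTORY_OF", "NEVER_HAD")
NARY_CMDS <- c("AND", "OR", "NOT", "UNION", "INTERSECT", "DIFF")
EQ_SELECTOR_NS <- c("ICD9", "ICD10", "CPT", "RX", "ATC", "LOINC",
                    "GENDER", "RACE", "VISIT", "NOTE_TYPE")
DUR_UNITS <- c(DAY = 1, DAYS = 1, MONTH = 30, MONTHS = 30, YEAR = 365, YEARS = 365)

# parser state: token data frame + cursor in an environment
new_cursor <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$toks <- tokens
  e$i <- 1L
  e
}
peek <- function(cur, ahead = 0L) {
  j <- cur$i + ahead
  if (j > nrow(cur$toks)) NULL else cur$toks[j, ]
}
advance <- function(cur) {
  t <- peek(cur)
  cur$i <- cur$i + 1L
  t
}
at_end <- function(cur) cur$i > nrow(cur$toks)
expect_punct <- function(cur, ch) {
  t <- peek(cur)
  if (is.null(t) || t$type != "punct" || t$text != ch) {
    got <- if (is.null(t)) "end of input" else paste0("'", t$text, "'")
    stop_parse(paste0("expected '", ch, "', got ", got),
               if (is.null(t)) NA_integer_ else t$line,
               if (is.null(t)) NA_integer_ else t$col)
  }
  advance(cur)
}
peek_is_punct <- function(cur, ch, ahead = 0L) {
  t <- peek(cur, ahead)
  !is.null(t) && t$type == "punct" && t$text == ch
}
ident_upper <- function(t) if (!is.null(t) && t$type == "ident") toupper(t$text) else ""

# signed number with optional duration unit; MAX -> Inf
parse_signed_duration <- function(cur, allow_max = TRUE) {
  t <- peek(cur)
  sign <- 1
  if (!is.null(t) && t$type == "punct" && t$text %in% c("-", "+")) {
    if (t$text == "-") sign <- -1
    advance(cur)
    t <- peek(cur)
  }
  if (allow_max && ident_upper(t) == "MAX") {
    advance(cur)
    return(sign * Inf)
  }
  if (is.null(t) || t$type != "num") {
    stop_parse("expected a number or MAX in duration",
               if (is.null(t)) NA_integer_ else t$line,
               if (is.null(t)) NA_integer_ else t$col)
  }
  advance(cur)
  val <- t$num
  u <- peek(cur)
  if (ident_upper(u) %in% names(DUR_UNITS)) {
    advance(cur)
    val <- val * DUR_UNITS[[ident_upper(u)]]
  }
  sign * val
}

parse_string_or_number <- function(cur, what) {
  t <- peek(cur)
  if (is.null(t) || !(t$type %in% c("str", "num"))) {
    stop_parse(paste0("expected a quoted string or number for ", what),
               if (is.null(t)) NA_integer_ else t$line,
               if (is.null(t)) NA_integer_ else t$col)
  }
  advance(cur)
  t$text
}

parse_expr <- function(cur, defined) {
  t <- peek(cur)
  if (is.null(t)) stop_parse("unexpected end of input")
  if (t$type == "ref") {
    advance(cur)
    if (!(t$text %in% defined)) {
      stop_parse(paste0("undefined variable $", t$text), t$line, t$col)
    }
    return(list(op = "varref", name = t$text))
  }
  if (t$type != "ident") {
    stop_parse(paste0("unexpected token '", t$text, "'"), t$line, t$col)
  }
  kw <- toupper(t$text)

  # multi-word commands
  if (kw == "FIRST" && ident_upper(peek(cur, 1L)) == "MENTION") {
    advance(cur); advance(cur)
    return(parse_unary(cur, defined, "first_mention"))
  }
  if (kw == "NO" && ident_upper(peek(cur, 1L)) == "HISTORY" &&
      ident_upper(peek(cur, 2L)) == "OF") {
    advance(cur); advance(cur); advance(cur)
    return(parse_unary(cur, defined, "no_history_of"))
  }
  if (kw == "NEVER" && ident_upper(peek(cur, 1L)) == "HAD") {
    advance(cur); advance(cur)
    return(parse_unary(cur, defined, "never_had"))
  }

  if (kw %in% EQ_SELECTOR_NS) {
    advance(cur)
    expect_punct(cur, "=")
    code <- parse_string_or_number(cur, paste0(kw, " code"))
    return(list(op = "selector", ns = kw, code = code))
  }
  advance(cur)
  switch(kw,
    AGE = {
      expect_punct(cur, "(")
      lo <- parse_signed_duration(cur)
      expect_punct(cur, ",")
      hi <- parse_signed_duration(cur)
      expect_punct(cur, ")")
      if (lo > hi) stop_parse("AGE lower bound exceeds upper bound", t$line, t$col)
      list(op = "age", lo = lo, hi = hi)
    },
    YEAR = {
      expect_punct(cur, "(")
      lo <- parse_signed_duration(cur, allow_max = FALSE)
      expect_punct(cur, ",")
      hi <- parse_signed_duration(cur, allow_max = FALSE)
      expect_punct(cur, ")")
      list(op = "year", lo = lo, hi = hi)
    },
    LABS = {
      expect_punct(cur, "(")
      code <- parse_string_or_number(cur, "LABS code")
      expect_punct(cur, ",")
      lo <- parse_signed_duration(cur)
      expect_punct(cur, ",")
      hi <- parse_signed_duration(cur)
      expect_punct(cur, ")")
      list(op = "labs", code = code, lo = lo, hi = hi)
    },
    TEXT = {
      expect_punct(cur, "(")
      phrase <- parse_string_or_number(cur, "TEXT phrase")
      flag <- "plain"
      if (peek_is_punct(cur, ",")) {
        advance(cur)
        f <- peek(cur)
        fu <- ident_upper(f)
        if (!(fu %in% c("NEGATED", "FAMILY_HISTORY"))) {
          stop_parse("TEXT flag must be NEGATED or FAMILY_HISTORY",
                     f$line, f$col)
        }
        advance(cur)
        flag <- tolower(fu)
      }
      expect_punct(cur, ")")
      list(op = "text", phrase = phrase, flag = flag)
    },
    COUNT = {
      expect_punct(cur, "(")
      arg <- parse_expr(cur, defined)
      expect_punct(cur, ",")
      min_n <- parse_signed_duration(cur)
      expect_punct(cur, ",")
      max_n <- parse_signed_duration(cur)
      expect_punct(cur, ")")
      list(op = "count", arg = arg, min = min_n, max = max_n)
    },
    SEQUENCE = parse_sequence(cur, defined, t),
    EXPORT = parse_export(cur, defined, t),
    {
      if (kw %in% NARY_CMDS) {
        args <- parse_args(cur, defined)
        if (kw == "DIFF" && length(args) != 2L) {
          stop_parse("DIFF takes exactly 2 operands", t$line, t$col)
        }
        list(op = tolower(kw), args = args)
      } else if (kw %in% UNARY_CMDS) {
        parse_unary(cur, defined, tolower(kw))
      } else {
        stop_parse(paste0("unknown command '", t$text, "'"), t$line, t$col)
      }
    })
}

parse_unary <- function(cur, defined, op) {
  expect_punct(cur, "(")
  arg <- parse_expr(cur, defined)
  expect_punct(cur, ")")
  list(op = op, arg = arg)
}

parse_args <- function(cur, defined) {
  expect_punct(cur, "(")
  args <- list(parse_expr(cur, defined))
  while (peek_is_punct(cur, ",")) {
    advance(cur)
    args[[length(args) + 1L]] <- parse_expr(cur, defined)
  }
  expect_punct(cur, ")")
  args
}

parse_sequence <- function(cur, defined, t0) {
  expect_punct(cur, "(")
  first <- parse_expr(cur, defined)
  star <- 0L
  if (peek_is_punct(cur, "*")) { advance(cur); star <- 1L }
  expect_punct(cur, ",")
  second <- parse_expr(cur, defined)
  if (peek_is_punct(cur, "*")) {
    advance(cur)
    if (star != 0L) stop_parse("SEQUENCE must have exactly one starred operand",
                               t0$line, t0$col)
    star <- 2L
  }
  expect_punct(cur, ")")
  if (star == 0L) stop_parse("SEQUENCE must have exactly one starred operand",
                             t0$line, t0$col)
  window <- NULL
  if ((peek_is_punct(cur, "+") || peek_is_punct(cur, "-")) &&
      peek_is_punct(cur, "(", ahead = 1L)) {
    mode <- if (peek(cur)$text == "+") "presence" else "absence"
    advance(cur)
    expect_punct(cur, "(")
    lo <- parse_signed_duration(cur)
    expect_punct(cur, ",")
    hi <- parse_signed_duration(cur)
    expect_punct(cur, ")")
    window <- window_modifier(mode, lo, hi)
  }
  list(op = "sequence", first = first, second = second,
       star = if (star == 1L) "first" else "second", window = window)
}

parse_export <- function(cur, defined, t0) {
  expect_punct(cur, "(")
  cohort <- parse_expr(cur, defined)
  time_expr <- NULL
  labels <- list()
  while (peek_is_punct(cur, ",")) {
    advance(cur)
    lab <- peek(cur)
    if (is.null(lab) || !(lab$type %in% c("ident", "str"))) {
      stop_parse("EXPORT column must be labeled: TIME=<expr> or \"name\"=<expr>",
                 t0$line, t0$col)
    }
    advance(cur)
    expect_punct(cur, "=")
    e <- parse_expr(cur, defined)
    if (lab$type == "ident" && toupper(lab$text) == "TIME") {
      if (!is.null(time_expr)) stop_parse("duplicate TIME column in EXPORT",
                                          lab$line, lab$col)
      time_expr <- e
    } else {
      labels[[lab$text]] <- e
    }
  }
  expect_punct(cur, ")")
  list(op = "export", cohort = cohort, time = time_expr, labels = labels)
}

#' Parse a TQL program
#'
#' @param text TQL source: zero or more `var name = <expr>` definitions
#'   (`var` may be juxtaposed with the name, as in `varstroke=`) followed by
#'   a final expression executed as the query.
#' @return A `tql_program` with `vars` (named list of ASTs, in definition
#'   order) and `final` (the query AST).
#' @export
parse_tql <- function(text) {
  cur <- new_cursor(tokenize_tql(text))
  vars <- list()
  final <- NULL
  while (!at_end(cur)) {
    t <- peek(cur)
    is_vardef <- FALSE
    name <- NULL
    if (t$type == "ident") {
      low <- tolower(t$text)
      nxt <- peek(cur, 1L)
      if (low == "var" && !is.null(nxt) && nxt$type == "ident" &&
          peek_is_punct(cur, "=", ahead = 2L)) {
        advance(cur)
        name <- advance(cur)$text
        advance(cur)  # '='
        is_vardef <- TRUE
      } else if (startsWith(low, "var") && nchar(t$text) > 3L &&
                 peek_is_punct(cur, "=", ahead = 1L)) {
        advance(cur)
        name <- substring(t$text, 4L)
        advance(cur)  # '='
        is_vardef <- TRUE
      }
    }
    if (is_vardef) {
      if (name %in% names(vars)) {
        stop_parse(paste0("duplicate variable name '", name, "'"), t$line, t$col)
      }
      vars[[name]] <- parse_expr(cur, names(vars))
    } else {
      final <- parse_expr(cur, names(vars))
    }
  }
  if (is.null(final)) stop_parse("program has no final query expression")
  structure(list(vars = vars, final = final), class = "tql_program")
}

#' @export
print.tql_program <- function(x, ...) {
  cat(format_tql(x))
  invisible(x)
}

#' Validate a parsed TQL program
#'
#' Performs the well-formedness checks that are not already hard parse
#' errors.  Returns diagnostics instead of throwing.
#'
#' @param program A `tql_program`.
#' @return Character vector of diagnostic messages; empty when clean.
#' @export
validate_program <- function(program) {
  diags <- character(0)
  walk <- function(e, top) {
    if (is.null(e)) return(invisible())
    switch(e$op,
      count = {
        if (e$min > e$max) diags <<- c(diags, "COUNT lower bound exceeds upper bound")
        walk(e$arg, FALSE)
      },
      age = if (e$lo > e$hi) diags <<- c(diags, "AGE lower bound exceeds upper bound"),
      labs = if (e$lo > e$hi) diags <<- c(diags, "LABS lower bound exceeds upper bound"),
      original = {
        if (e$arg$op != "selector") {
          diags <<- c(diags, "ORIGINAL must wrap a feature selector")
        }
        walk(e$arg, FALSE)
      },
      export = {
        if (!top) {
          diags <<- c(diags, "EXPORT is only allowed as the top-level query")
        }
        if (is.null(e$time)) diags <<- c(diags, "EXPORT requires a TIME column")
        walk(e$cohort, FALSE)
        walk(e$time, FALSE)
        for (l in e$labels) walk(l, FALSE)
      },
      sequence = { walk(e$first, FALSE); walk(e$second, FALSE) },
      {
        for (a in e[["args"]]) walk(a, FALSE)
        if (!is.null(e[["arg"]])) walk(e[["arg"]], FALSE)
      })
    invisible()
  }
  for (v in program$vars) walk(v, FALSE)
  walk(program$final, TRUE)
  diags
}

fmt_num <- function(x) {
  if (is.infinite(x)) {
    if (x > 0) "MAX" else "-MAX"
  } else {
    format(x, scientific = FALSE, trim = TRUE)
  }
}
fmt_days <- function(x) if (is.infinite(x)) fmt_num(x) else paste0(fmt_num(x), " DAYS")

format_expr <- function(e) {
  switch(e$op,
    varref = paste0("$", e$name),
    selector = paste0(e$ns, "=\"", e$code, "\""),
    age = paste0("AGE(", fmt_days(e$lo), ", ", fmt_days(e$hi), ")"),
    year = paste0("YEAR(", fmt_num(e$lo), ", ", fmt_num(e$hi), ")"),
    labs = paste0("LABS(\"", e$code, "\", ", fmt_num(e$lo), ", ", fmt_num(e$hi), ")"),
    text = paste0("TEXT(\"", e$phrase, "\"",
                  if (e$flag != "plain") paste0(", ", toupper(e$flag)) else "", ")"),
    count = paste0("COUNT(", format_expr(e$arg), ", ", fmt_num(e$min), ", ",
                   fmt_num(e$max), ")"),
    first_mention = paste0("FIRST MENTION(", format_expr(e$arg), ")"),
    no_history_of = paste0("NO HISTORY OF(", format_expr(e$arg), ")"),
    never_had = paste0("NEVER HAD(", format_expr(e$arg), ")"),
    invert = paste0("INVERT(", format_expr(e$arg), ")"),
    original = paste0("ORIGINAL(", format_expr(e$arg), ")"),
    sequence = {
      a <- format_expr(e$first)
      b <- format_expr(e$second)
      if (e$star == "first") a <- paste0(a, "*") else b <- paste0(b, "*")
      w <- if (!is.null(e$window)) {
        paste0(if (e$window$mode == "presence") "+" else "-",
               "(", fmt_days(e$window$lo), ", ", fmt_days(e$window$hi), ")")
      } else ""
      paste0("SEQUENCE(", a, ", ", b, ")", w)
    },
    export = {
      parts <- c(format_expr(e$cohort),
                 if (!is.null(e$time)) paste0("TIME=", format_expr(e$time)),
                 vapply(names(e$labels), function(nm) {
                   paste0("\"", nm, "\"=", format_expr(e$labels[[nm]]))
                 }, character(1L)))
      paste0("EXPORT(", paste(parts, collapse = ", "), ")")
    },
    # n-ary Boolean/temporal commands
    paste0(toupper(e$op), "(",
           paste(vapply(e$args, format_expr, character(1L)), collapse = ", "), ")"))
}

#' Pretty-print a TQL program
#'
#' Produces canonical TQL text that reparses to a structurally identical
#' program (durations are rendered in days).
#'
#' @param program A `tql_program`.
#' @return A single string of TQL source.
#' @export
format_tql <- function(program) {
  lines <- vapply(names(program$vars), function(nm) {
    paste0("var ", nm, " = ", format_expr(program$vars[[nm]]))
  }, character(1L))
  paste(c(lines, format_expr(program$final), ""), collapse = "\n")
}
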