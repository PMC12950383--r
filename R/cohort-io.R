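#' Column dictionary for transplant cohort tables
#'
#' One row per column of the canonical cohort layout: name, storage type,
#' closed level set for categorical fields, validity range for numeric
#' fields, and whether the column is mandatory. Times are stored in years;
#' waiting time and cold ischemia time stay in their native units (days,
#' hours) as usually tabulated.
#'
#' @return A data.frame with columns `name`, `type` (one of `"id"`,
#'   `"numeric"`, `"integer"`, `"enum"`, `"flag"`), `levels`
#'   (comma-separated, first level is the reference), `min`, `max`,
#'   `required`.
#' @export
cohort_columns <- function() {
  col <- function(name, type, levels = NA_character_, min = NA_real_,
                  max = NA_real_, required = TRUE) {
    data.frame(name = name, type = type, levels = levels, min = min,
               max = max, required = required, stringsAsFactors = FALSE)
  }
  rbind(
    col("id", "id"),
    col("donor_age", "numeric", min = 0, max = 120),
    col("donor_sex", "enum", "female,male"),
    col("cause_of_death", "enum", "anoxia,stroke,trauma,tumor"),
    col("donor_bmi", "numeric", min = 5, max = 80),
    col("donor_cmv", "enum", "negative,positive,unknown"),
    col("htn_duration", "enum", "none,y0_5,y6_10,gt10,unknown"),
    col("dm_duration", "enum", "none,y0_5,y6_10,gt10,unknown"),
    col("donor_creatinine", "numeric", min = 1e-8, max = Inf),
    col("proteinuria", "enum", "no,yes,unknown"),
    col("dcd", "flag"),
    col("en_bloc", "flag"),
    col("blood_group", "enum", "O,A,B,AB", required = FALSE),
    col("recip_age", "numeric", min = 0, max = 120),
    col("recip_sex", "enum", "female,male"),
    col("ethnicity", "enum",
        "white,black,hispanic,asian,american_indian,pacific_islander,multiracial"),
    col("recip_diabetes", "flag"),
    col("dialysis_at_transplant", "flag"),
    col("recip_cmv", "enum", "negative,positive,unknown"),
    col("prev_transplants", "integer", min = 0, max = Inf),
    col("waitlist_days", "numeric", min = 0, max = Inf),
    col("hla_mismatch", "integer", min = 0, max = 6),
    col("cpra", "numeric", min = 0, max = 100),
    col("cold_ischemia_hours", "numeric", min = 0, max = Inf),
    col("unos_region", "integer", min = 1, max = 11, required = FALSE),
    col("kdpi", "numeric", min = 0, max = 1, required = FALSE),
    col("time", "numeric", min = 1e-12, max = Inf, required = FALSE),
    col("event", "integer", min = 0, max = 2, required = FALSE)
  )
}

#' Canonical delimited-text dialect
#'
#' Comma separator, `.` decimal mark, UTF-8, lower-case `true`/`false`
#' booleans, empty string for missing values.
#'
#' @param sep Field separator.
#' @param dec Decimal mark.
#' @param na String representing a missing value.
#' @return A list of dialect settings.
#' @export
cohort_dialect <- function(sep = ",", dec = ".", na = "") {
  stopifnot(nchar(sep) == 1L, dec %in% c(".", ","), sep != dec)
  list(sep = sep, dec = dec, na = na)
}

.enum_levels <- function(dict_row) strsplit(dict_row$levels, ",", fixed = TRUE)[[1]]

#' Read a transplant cohort from delimited text
#'
#' Parses and validates a cohort file against the column dictionary
#' ([cohort_columns()]). Enum strings are normalized to lower case,
#' header matching is case-insensitive, and every row violating a field
#' invariant (out-of-range numeric, unknown enum level, unparseable value,
#' missing mandatory field) is dropped with a row-indexed diagnostic, so
#' the returned table is a complete-case table. Rows whose `time` and
#' `event` are both empty are kept with outcomes unset.
#'
#' @param path Path of the file to read.
#' @param dialect Dialect settings, see [cohort_dialect()].
#' @return A `cohort_table` (a validated data.frame) with attributes
#'   `diagnostics` (data.frame of row, column, problem) and `n_dropped`.
#' @export
read_cohort <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  dict <- cohort_columns()
  missing_cols <- setdiff(dict$name[dict$required], names(raw))
  if (length(missing_cols))
    stop("schema error: mandatory column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, intersect(dict$name, names(raw)), drop = FALSE]
  as_cohort(raw, dialect = dialect)
}

#' Validate a raw table into a cohort table
#'
#' @param raw A data.frame of character (or already-typed) columns using the
#'   canonical column names.
#' @param dialect Dialect used to parse numerics and booleans.
#' @return A `cohort_table`; see [read_cohort()].
#' @export
as_cohort <- function(raw, dialect = cohort_dialect()) {
  dict <- cohort_columns()
  n <- nrow(raw)
  parsed <- raw
  bad <- data.frame(row = integer(), column = character(),
                    problem = character(), stringsAsFactors = FALSE)
  note <- function(rows, column, problem) {
    if (length(rows))
      bad <<- rbind(bad, data.frame(row = rows, column = column,
                                    problem = problem,
                                    stringsAsFactors = FALSE))
  }
  parse_num <- function(x) {
    x <- trimws(as.character(x))
    x[x == dialect$na] <- NA
    if (dialect$dec != ".") x <- gsub(dialect$dec, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  for (k in seq_len(nrow(dict))) {
    d <- dict[k, ]
    if (!d$name %in% names(parsed)) next
    x <- parsed[[d$name]]
    optional_outcome <- d$name %in% c("time", "event")
    if (d$type == "id") {
      x <- trimws(as.character(x))
      note(which(x == "" | is.na(x)), d$name, "empty identifier")
      dup <- which(duplicated(x) & x != "")
      note(dup, d$name, "duplicate identifier")
      parsed[[d$name]] <- x
    } else if (d$type %in% c("numeric", "integer")) {
      was_na <- is.na(x) | trimws(as.character(x)) == dialect$na
      v <- parse_num(x)
      note(which(!was_na & is.na(v)), d$name, "unparseable numeric")
      out <- which(!is.na(v) & (v < d$min | v > d$max))
      note(out, d$name, sprintf("outside [%g, %g]", d$min, d$max))
      if (d$type == "integer") {
        frac <- which(!is.na(v) & v != round(v))
        note(frac, d$name, "not an integer")
      }
      miss <- which(was_na)
      if (d$required) note(miss, d$name, "missing mandatory value")
      parsed[[d$name]] <- v
    } else if (d$type == "enum") {
      v <- tolower(trimws(as.character(x)))
      v[v == dialect$na] <- NA
      lev <- .enum_levels(d)
      # case-insensitive match, stored in the declared casing
      v <- ifelse(is.na(v), NA, lev[match(v, tolower(lev))])
      badlev <- which(!is.na(trimws(as.character(x))) &
                        trimws(as.character(x)) != dialect$na & is.na(v))
      note(badlev, d$name, paste0("not one of {", d$levels, "}"))
      if (d$required) note(which(is.na(v)), d$name, "missing mandatory value")
      parsed[[d$name]] <- v
    } else if (d$type == "flag") {
      v <- tolower(trimws(as.character(x)))
      v[v == dialect$na] <- NA
      out <- rep(NA, n)
      out[v %in% c("true", "1", "yes", "t")] <- TRUE
      out[v %in% c("false", "0", "no", "f")] <- FALSE
      note(which(!is.na(v) & is.na(out)), d$name, "not a boolean")
      if (d$required) note(which(is.na(v)), d$name, "missing mandatory value")
      parsed[[d$name]] <- out
    }
  }
  # outcome pair: either both set (validated above) or both unset
  if (all(c("time", "event") %in% names(parsed))) {
    t_na <- is.na(parsed$time); e_na <- is.na(parsed$event)
    note(which(xor(t_na, e_na)), "time",
         "time and event must be set together")
  }
  drop_rows <- sort(unique(bad$row))
  keep <- setdiff(seq_len(n), drop_rows)
  out <- parsed[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (length(drop_rows))
    message(length(drop_rows), " of ", n,
            " row(s) dropped by complete-case validation")
  structure(out, class = c("cohort_table", "data.frame"),
            diagnostics = bad, n_dropped = length(drop_rows))
}

#' Write a cohort table as canonical delimited text
#'
#' Formatting is deterministic so that write -> read -> write is
#' byte-identical: numerics are printed with up to 15 significant digits
#' and no scientific notation, flags as `true`/`false`, missing values as
#' the dialect's NA string.
#'
#' @param cohort A `cohort_table` or compatible data.frame.
#' @param path Output path.
#' @param dialect Dialect settings, see [cohort_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = cohort_dialect()) {
  dict <- cohort_columns()
  df <- as.data.frame(cohort)[, intersect(dict$name, names(cohort)),
                              drop = FALSE]
  fmt <- function(x, type) {
    if (type %in% c("numeric", "integer")) {
      s <- vapply(x, function(v) {
        if (is.na(v)) return(dialect$na)
        format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      if (dialect$dec != ".") s <- gsub(".", dialect$dec, s, fixed = TRUE)
      s
    } else if (type == "flag") {
      ifelse(is.na(x), dialect$na, ifelse(x, "true", "false"))
    } else {
      ifelse(is.na(x), dialect$na, as.character(x))
    }
  }
  for (nm in names(df)) {
    type <- dict$type[match(nm, dict$name)]
    df[[nm]] <- fmt(df[[nm]], type)
  }
  lines <- c(paste(names(df), collapse = dialect$sep),
             do.call(paste, c(unname(df), sep = dialect$sep)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Transplant cohort table:", nrow(x), "row(s),", ncol(x), "column(s)\n")
  diag <- attr(x, "diagnostics")
  if (!is.null(diag) && nrow(diag))
    cat("  ", attr(x, "n_dropped"), "row(s) dropped at validation\n")
  has_outcome <- "time" %in% names(x) && any(!is.na(x$time))
  cat("  outcomes:", if (has_outcome) "set" else "unset", "\n")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Encode a cohort into a numeric design matrix
#'
#' Dummy codes categorical terms against fixed reference levels (first
#' level in the column dictionary: female sex, anoxia, CMV negative, no
#' hypertension, no diabetes, no proteinuria, white, blood group O; flags
#' reference `false`). Continuous terms pass through untransformed. Each
#' dummy column carries a group label naming its parent factor so that
#' multilevel factors can be penalized at the group level; each continuous
#' or flag term is its own group.
#'
#' @param cohort A `cohort_table` or data.frame with canonical columns.
#' @param terms Character vector of column names to encode.
#' @param drop_empty Drop dummy columns of declared levels that fewer
#'   than `min_count` rows take (default `FALSE`, keeping the full
#'   declared encoding). Fitting pipelines set this to `TRUE` so that
#'   rare levels absent from a given cohort or fold do not make the
#'   design rank deficient or numerically singular.
#' @param min_count Minimum occupied rows for a dummy column to survive
#'   when `drop_empty` is `TRUE` (default 1).
#' @return A `design_matrix`: list with `X` (numeric matrix), `groups`
#'   (named character vector, one entry per column of `X`), `ref` (named
#'   list of reference levels for categorical terms), `terms`.
#' @export
encode_design <- function(cohort, terms, drop_empty = FALSE,
                          min_count = 1L) {
  dict <- cohort_columns()
  unknown <- setdiff(terms, dict$name)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  missing_in_data <- setdiff(terms, names(cohort))
  if (length(missing_in_data))
    stop("term(s) absent from cohort: ",
         paste(missing_in_data, collapse = ", "))
  cols <- list(); groups <- character(); ref <- list()
  n <- nrow(cohort)
  for (term in terms) {
    d <- dict[match(term, dict$name), ]
    x <- cohort[[term]]
    if (anyNA(x))
      stop("term '", term, "' contains missing values; encode on a ",
           "complete-case cohort")
    if (d$type %in% c("numeric", "integer")) {
      cols[[term]] <- as.numeric(x)
      groups[term] <- term
    } else if (d$type == "flag") {
      cols[[paste0(term, "_true")]] <- as.numeric(x)
      groups[paste0(term, "_true")] <- term
      ref[[term]] <- "false"
    } else if (d$type == "enum") {
      lev <- .enum_levels(d)
      bad <- setdiff(unique(x), lev)
      if (length(bad))
        stop("unseen level(s) in '", term, "': ", paste(bad, collapse = ", "))
      ref[[term]] <- lev[1L]
      for (l in lev[-1L]) {
        nm <- paste(term, l, sep = "_")
        v <- as.numeric(x == l)
        if (drop_empty && sum(v > 0) < min_count) next
        cols[[nm]] <- v
        groups[nm] <- term
      }
    } else stop("term '", term, "' is not encodable")
  }
  X <- if (length(cols)) do.call(cbind, cols)
       else matrix(numeric(0), n, 0)
  rownames(X) <- if ("id" %in% names(cohort)) cohort$id else NULL
  structure(list(X = X, groups = groups, ref = ref, terms = terms),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "x", ncol(x$X), "\n")
  cat("  groups:", length(unique(x$groups)), "-",
      paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}
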