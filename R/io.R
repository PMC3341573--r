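ACCURACY_COLUMNS <- c("finding_id", "label", "sensitivity", "specificity",
                      "lr_pos", "lr_neg", "dependence_group", "modality", "note")
MODALITIES <- c("history", "exam", "laboratory")

#' Read a diagnostic-accuracy table
#'
#' Accuracy tables are comma-separated UTF-8 files with a fixed header
#' vocabulary: `finding_id`, `label`, `sensitivity`, `specificity`, `lr_pos`,
#' `lr_neg`, `dependence_group`, `modality`, `note`.  Each row describes one
#' clinical finding's accuracy against a target proposition (a disease or a
#' disease category).  Every row must carry either an LR pair or a
#' sensitivity/specificity pair; rows with only sensitivity/specificity have
#' their LRs filled in via [lr_from_accuracy()], and rows carrying both are
#' checked for mutual consistency (5% relative tolerance).
#'
#' Findings that are statistically dependent on each other share a non-empty
#' `dependence_group` token; [select_lrs()] keeps only the most discriminative
#' applicable LR within each group.
#'
#' @param source path or connection to a CSV file.
#' @param target label of the proposition the table is about (disease name or
#'   category path); stored as an attribute.
#' @return a data.frame of class `"accuracy_table"` with one row per finding.
#' @examples
#' uti <- read_accuracy_table(catlr_example("accuracy_uti.csv"), target = "UTI")
#' nrow(uti)  # 13
#' @export
read_accuracy_table <- function(source, target = NA_character_) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  required <- c("finding_id", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("accuracy table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(ACCURACY_COLUMNS, names(df))) {
    df[[col]] <- rep(NA_character_, nrow(df))
  }
  df <- df[ACCURACY_COLUMNS]

  num <- function(col) {
    x <- df[[col]]
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("accuracy table row %d: non-numeric value '%s' in column %s",
                   bad[1], x[bad[1]], col), call. = FALSE)
    }
    out
  }
  for (col in c("sensitivity", "specificity", "lr_pos", "lr_neg")) {
    df[[col]] <- num(col)
  }
  df$dependence_group[is.na(df$dependence_group)] <- ""
  df$note[is.na(df$note)] <- ""
  df$modality[is.na(df$modality) | df$modality == ""] <- "history"

  if (anyDuplicated(df$finding_id)) {
    stop("duplicate finding_id in accuracy table: ",
         df$finding_id[anyDuplicated(df$finding_id)], call. = FALSE)
  }
  bad_mod <- setdiff(unique(df$modality), MODALITIES)
  if (length(bad_mod)) {
    stop("unknown modality value(s): ", paste(bad_mod, collapse = ", "),
         call. = FALSE)
  }

  for (i in seq_len(nrow(df))) {
    has_lr <- !is.na(df$lr_pos[i]) && !is.na(df$lr_neg[i])
    has_acc <- !is.na(df$sensitivity[i]) && !is.na(df$specificity[i])
    if (!has_lr && !has_acc) {
      stop(sprintf(
        "accuracy table row %d (%s): needs either an LR pair or sensitivity/specificity",
        i, df$finding_id[i]), call. = FALSE)
    }
    if (has_acc) {
      if (df$sensitivity[i] < 0 || df$sensitivity[i] > 1 ||
          df$specificity[i] < 0 || df$specificity[i] > 1) {
        stop(sprintf("accuracy table row %d (%s): sensitivity/specificity outside [0, 1]",
                     i, df$finding_id[i]), call. = FALSE)
      }
      pair <- lr_from_accuracy(df$sensitivity[i], df$specificity[i])
      if (has_lr) {
        rel <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
        if (rel(df$lr_pos[i], pair$lr_pos) > 0.05 ||
            rel(df$lr_neg[i], pair$lr_neg) > 0.05) {
          stop(sprintf(
            "accuracy table row %d (%s): stated LRs inconsistent with sensitivity/specificity",
            i, df$finding_id[i]), call. = FALSE)
        }
      } else {
        df$lr_pos[i] <- pair$lr_pos
        df$lr_neg[i] <- pair$lr_neg
      }
    }
    if (df$lr_pos[i] <= 0 || df$lr_neg[i] < 0) {
      stop(sprintf("accuracy table row %d (%s): LR(+) must be positive and LR(-) non-negative",
                   i, df$finding_id[i]), call. = FALSE)
    }
  }
  structure(df, class = c("accuracy_table", "data.frame"), target = target)
}

#' Write an accuracy table back to CSV
#'
#' @param table an `accuracy_table`.
#' @param file path or connection.
#' @export
write_accuracy_table <- function(table, file) {
  stopifnot(inherits(table, "accuracy_table"))
  utils::write.csv(as.data.frame(table)[ACCURACY_COLUMNS], file,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(table)
}

#' @export
print.accuracy_table <- function(x, ...) {
  tgt <- attr(x, "target")
  cat("Diagnostic accuracy table",
      if (!is.na(tgt)) paste0("(target: ", tgt, ")"), "-",
      nrow(x), "findings\n")
  print.data.frame(x[, c("finding_id", "lr_pos", "lr_neg", "dependence_group",
                         "modality")], row.names = FALSE)
  invisible(x)
}

#' Read a disease prevalence/taxonomy table
#'
#' Disease tables are CSV files with columns `disease_id`, `label`,
#' `prevalence_pct` (percent of the reference cohort) and `category_path`
#' (slash-separated, e.g. `organic/neoplasm`).  Prevalences are stored as the
#' printed percentages and additionally exposed as fractions in a
#' `prevalence` column at load.  The total prevalence may not exceed 100 plus
#' a 0.5 rounding slack.
#'
#' @param source path or connection to a CSV file.
#' @return a data.frame of class `"disease_table"`.
#' @examples
#' dz <- read_disease_table(catlr_example("diseases_abdominal.csv"))
#' category_prior(dz, "organic")  # 0.141
#' @export
read_disease_table <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("disease_id", "label", "prevalence_pct", "category_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("disease table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  disease_table(df)
}

#' Construct a disease table programmatically
#'
#' @param entries a data.frame with columns `disease_id`, `prevalence_pct`
#'   and `category_path` (and optionally `label`).
#' @return a validated `disease_table`.
#' @rdname read_disease_table
#' @export
disease_table <- function(entries) {
  df <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(df$label)) df$label <- df$disease_id
  df$prevalence_pct <- suppressWarnings(as.numeric(df$prevalence_pct))
  if (any(is.na(df$prevalence_pct))) {
    stop("disease table: non-numeric prevalence_pct in row ",
         which(is.na(df$prevalence_pct))[1], call. = FALSE)
  }
  if (any(df$prevalence_pct < 0)) {
    stop("disease table: negative prevalence in row ",
         which(df$prevalence_pct < 0)[1], call. = FALSE)
  }
  if (anyDuplicated(df$disease_id)) {
    stop("duplicate disease_id in disease table: ",
         df$disease_id[anyDuplicated(df$disease_id)], call. = FALSE)
  }
  if (any(df$category_path == "" | is.na(df$category_path))) {
    stop("disease table: empty category_path in row ",
         which(df$category_path == "" | is.na(df$category_path))[1], call. = FALSE)
  }
  total <- sum(df$prevalence_pct)
  if (total > 100.5) {
    stop(sprintf("disease table: prevalences sum to %.1f%%, exceeding 100%% plus rounding slack",
                 total), call. = FALSE)
  }
  df$prevalence <- df$prevalence_pct / 100
  structure(df, class = c("disease_table", "data.frame"))
}

#' @export
print.disease_table <- function(x, ...) {
  cat("Disease taxonomy -", nrow(x), "entries, total prevalence",
      sprintf("%.1f%%\n", sum(x$prevalence_pct)))
  for (p in sort(unique(vapply(strsplit(x$category_path, "/"), `[`, "", 1)))) {
    cat(sprintf("  %-14s %5.1f%% (%d diseases)\n", p,
                100 * category_prior(x, p), length(category_members(x, p))))
  }
  invisible(x)
}

#' Read a patient finding profile
#'
#' Profiles are JSON objects mapping `finding_id` to one of `"present"`,
#' `"absent"` or `"unknown"`.  Findings not mentioned are treated as unknown.
#'
#' @param source path or connection to a JSON file.
#' @return a named character vector of class `"patient_profile"`.
#' @export
read_profile <- function(source) {
  x <- jsonlite::read_json(source, simplifyVector = TRUE)
  if (!is.null(x$findings)) x <- x$findings
  patient_profile(unlist(x))
}

#' Construct a patient profile
#'
#' @param results named character vector (or list) mapping finding ids to
#'   `"present"`, `"absent"` or `"unknown"`.
#' @return a named character vector of class `"patient_profile"`.
#' @examples
#' patient_profile(c(dysuria = "present", fever = "absent"))
#' @export
patient_profile <- function(results) {
  results <- unlist(results)
  x <- as.character(results)
  names(x) <- if (length(x)) names(results) else character()
  if (length(x) &&
      (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x)))) {
    stop("profile results must be uniquely named by finding_id", call. = FALSE)
  }
  bad <- setdiff(unique(x), c("present", "absent", "unknown"))
  if (length(bad)) {
    stop("profile results must be 'present', 'absent' or 'unknown'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(x, class = "patient_profile")
}

#' Write a patient profile as JSON
#'
#' @param profile a `patient_profile`.
#' @param file path or connection.
#' @export
write_profile <- function(profile, file) {
  jsonlite::write_json(as.list(unclass(profile)), file, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(profile)
}

#' Write an update trace
#'
#' Writes a human-readable step table mirroring the conventional worked-odds
#' layout (`format = "text"`), a machine-readable JSON form
#' (`format = "json"`), or both.
#'
#' @param trace an `update_trace` from [sequential_update()] or
#'   [revise_category()].
#' @param file path or connection; `""` prints to stdout.
#' @param format `"text"`, `"json"` or `"both"` (text followed by JSON).
#' @param decimals display decimals for odds in the text form.
#' @export
write_trace <- function(trace, file = "", format = c("text", "json", "both"),
                        decimals = 2) {
  stopifnot(inherits(trace, "update_trace"))
  format <- match.arg(format)
  out <- character()
  if (format %in% c("text", "both")) {
    out <- c(out, utils::capture.output(print(trace, decimals = decimals)))
  }
  if (format %in% c("json", "both")) {
    out <- c(out, trace_to_json(trace))
  }
  if (identical(file, "")) writeLines(out) else writeLines(out, con = file)
  invisible(trace)
}

#' Serialize an update trace to JSON
#'
#' @param trace an `update_trace`.
#' @return a JSON string; parse back with [trace_from_json()].
#' @export
trace_to_json <- function(trace) {
  stopifnot(inherits(trace, "update_trace"))
  payload <- list(
    prior_prob = trace$prior_prob,
    prior_odds = trace$prior_odds,
    steps = trace$steps,
    posterior_odds = trace$posterior_odds,
    posterior_prob = trace$posterior_prob,
    notes = trace$notes
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

#' Parse an update trace from JSON
#'
#' @param json a JSON string or path produced by [trace_to_json()] /
#'   [write_trace()].
#' @return an `update_trace`.
#' @export
trace_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  steps <- as.data.frame(x$steps)
  if (!nrow(steps)) {
    steps <- data.frame(step = integer(), finding_id = character(),
                        lr = numeric(), odds = numeric(), prob = numeric(),
                        stringsAsFactors = FALSE)
  }
  steps$finding_id <- as.character(steps$finding_id)
  structure(list(
    prior_prob = x$prior_prob,
    prior_odds = if (is.null(x$prior_odds) || is.na(x$prior_odds)) Inf else x$prior_odds,
    steps = steps,
    posterior_odds = if (is.null(x$posterior_odds) || is.na(x$posterior_odds)) Inf else x$posterior_odds,
    posterior_prob = x$posterior_prob,
    notes = as.character(x$notes %||% character())
  ), class = "update_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled example data file
#'
#' The package ships transcriptions of published diagnostic-accuracy and
#' prevalence tables as CSV, plus JSON patient profiles and a scheme tree:
#' `accuracy_uti.csv` (symptoms/signs predicting uncomplicated urinary tract
#' infection), `accuracy_abdominal_organic.csv` (category-oriented LRs of
#' findings for organic disease in non-acute abdominal pain),
#' `diseases_abdominal.csv` (final-diagnosis prevalences in non-acute
#' abdominal pain with organic/non-organic/neoplasm taxonomy),
#' `profile_case_uti.json`, `profile_case_abdominal.json`, and
#' `scheme_abdominal.json`.
#'
#' @param file file name; with no argument, lists available files.
#' @return a file path (or a character vector of file names).
#' @export
catlr_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "catlr"))
  } else {
    path <- system.file("extdata", file, package = "catlr")
    if (path == "") stop("no bundled file named ", file, call. = FALSE)
    path
  }
}
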