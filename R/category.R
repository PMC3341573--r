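split_path <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

#' Diseases belonging to a category
#'
#' Category membership is determined by path prefix: a disease with
#' `category_path` `"organic/neoplasm"` is a member of both `"organic"` and
#' `"organic/neoplasm"`.  Members of a sub-category are therefore always a
#' subset of its parent's members.
#'
#' @param diseases a `disease_table`.
#' @param category a category path string such as `"organic"` or
#'   `"organic/neoplasm"`.
#' @return character vector of member `disease_id`s.
#' @export
category_members <- function(diseases, category) {
  stopifnot(inherits(diseases, "disease_table"), is.character(category),
            length(category) == 1L)
  want <- split_path(category)
  hit <- vapply(strsplit(diseases$category_path, "/", fixed = TRUE),
                function(p) length(p) >= length(want) &&
                  all(p[seq_along(want)] == want),
                logical(1))
  diseases$disease_id[hit]
}

all_category_paths <- function(diseases) {
  paths <- unique(diseases$category_path)
  out <- unique(unlist(lapply(strsplit(paths, "/", fixed = TRUE), function(p) {
    vapply(seq_along(p), function(k) paste(p[seq_len(k)], collapse = "/"), "")
  })))
  sort(out)
}

#' Pre-test probability of a disease category
#'
#' The prior of a category is the summed prevalence fraction of its member
#' diseases.  An unknown category label is an error; a known category with no
#' members has prior 0.
#'
#' @inheritParams category_members
#' @param allow_empty return 0 instead of erroring for a label that matches
#'   no disease (used for deliberately empty categories).
#' @return probability in `[0, 1]`.
#' @examples
#' dz <- read_disease_table(catlr_example("diseases_abdominal.csv"))
#' category_prior(dz, "organic")            # 0.141 -> prints as 14%
#' @export
category_prior <- function(diseases, category, allow_empty = FALSE) {
  members <- category_members(diseases, category)
  if (!length(members) && !allow_empty) {
    stop("unknown category: ", category, call. = FALSE)
  }
  sum(diseases$prevalence[diseases$disease_id %in% members])
}

#' Derive the category-level accuracy of a finding
#'
#' Under cohort sampling — one disease per patient drawn from the prevalence
#' vector, findings drawn conditionally on the disease — the sensitivity of a
#' finding for a *category* C is the prevalence-weighted mixture of the
#' per-disease finding probabilities within C, and the specificity is one
#' minus the same mixture over the complement:
#' \deqn{se_C = \sum_{d \in C} \pi_d p_d / \sum_{d \in C} \pi_d, \quad
#'       sp_C = 1 - \sum_{d \notin C} \pi_d p_d / \sum_{d \notin C} \pi_d.}
#' The complement runs over every non-member disease in the table, including
#' symptomatic-undiagnosed ("no diagnosis") entries.
#'
#' @param model a `generative_model` (see [generative_model()]).
#' @param category category path string.
#' @param finding_id one of the model's finding ids.
#' @return list with `sensitivity` and `specificity`.
#' @export
derive_category_accuracy <- function(model, category, finding_id) {
  stopifnot(inherits(model, "generative_model"))
  p <- finding_probs(model, finding_id)
  diseases <- model$diseases
  members <- category_members(diseases, category)
  inside <- diseases$disease_id %in% members
  w <- diseases$prevalence
  if (sum(w[inside]) <= 0 || sum(w[!inside]) <= 0) {
    stop("category and its complement must both have positive prevalence: ",
         category, call. = FALSE)
  }
  list(
    sensitivity = sum(w[inside] * p[inside]) / sum(w[inside]),
    specificity = 1 - sum(w[!inside] * p[!inside]) / sum(w[!inside])
  )
}

#' Category-oriented likelihood ratio of a finding
#'
#' The category-oriented LR quantifies how much more likely a finding is to
#' be present in patients with one of the diseases of a category than in
#' patients with a disease outside that category.  It is
#' [lr_from_accuracy()] applied to the category-level accuracy of
#' [derive_category_accuracy()].
#'
#' @inheritParams derive_category_accuracy
#' @return an `"lr_pair"`.
#' @export
category_lr <- function(model, category, finding_id) {
  acc <- derive_category_accuracy(model, category, finding_id)
  lr_from_accuracy(acc$sensitivity, acc$specificity)
}

#' Analytic category-oriented LR table for a generative model
#'
#' Derives the category accuracy and LR pair of every finding in the model
#' against one category, as an [read_accuracy_table()]-compatible
#' `accuracy_table`.
#'
#' @inheritParams derive_category_accuracy
#' @return an `accuracy_table` whose target is the category path.
#' @export
category_lr_table <- function(model, category) {
  ids <- model$finding_ids
  acc <- lapply(ids, function(f) derive_category_accuracy(model, category, f))
  se <- vapply(acc, `[[`, 0, "sensitivity")
  sp <- vapply(acc, `[[`, 0, "specificity")
  pair <- lr_from_accuracy(se, sp)
  df <- data.frame(
    finding_id = ids,
    label = ids,
    sensitivity = se,
    specificity = sp,
    lr_pos = pair$lr_pos,
    lr_neg = pair$lr_neg,
    dependence_group = "",
    modality = "history",
    note = "",
    stringsAsFactors = FALSE
  )
  structure(df, class = c("accuracy_table", "data.frame"), target = category)
}

#' Revise a category probability from a patient profile
#'
#' Selects the applicable likelihood ratio for each observed finding
#' (`lr_pos` when present, `lr_neg` when absent; unknown findings skipped),
#' applies the dependence-group filter of [select_lrs()], and runs
#' [sequential_update()].  Multi-finding category updating is a naive-Bayes
#' approximation: findings are treated as conditionally independent given
#' category membership side; [naive_vs_exact()] quantifies the resulting
#' error against the exact enumeration posterior.
#'
#' @param prior pre-test category probability, or pre-test odds when
#'   `prior_is = "odds"`.
#' @param profile a [patient_profile()].
#' @param table an `accuracy_table` whose target is the category.
#' @param prior_is whether `prior` is a probability (default) or odds.
#' @param warn_missing warn about profile findings absent from the table
#'   (they are skipped either way).
#' @return an `update_trace` with a `category` attribute.
#' @examples
#' dz <- read_disease_table(catlr_example("diseases_abdominal.csv"))
#' tab <- read_accuracy_table(catlr_example("accuracy_abdominal_organic.csv"),
#'                            target = "organic")
#' prof <- read_profile(catlr_example("profile_case_abdominal.json"))
#' revise_category(category_prior(dz, "organic"), prof, tab)
#' @export
revise_category <- function(prior, profile, table,
                            prior_is = c("probability", "odds"),
                            warn_missing = TRUE) {
  prior_is <- match.arg(prior_is)
  stopifnot(inherits(table, "accuracy_table"))
  profile <- patient_profile(profile)
  observed <- names(profile)[profile != "unknown"]
  missing <- setdiff(observed, table$finding_id)
  if (length(missing) && warn_missing) {
    warning("profile finding(s) not in accuracy table, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  sel <- select_lrs(profile, table)
  tr <- if (prior_is == "probability") {
    sequential_update(prior_prob = prior, lrs = as.numeric(sel),
                      finding_ids = names(sel))
  } else {
    sequential_update(prior_odds = prior, lrs = as.numeric(sel),
                      finding_ids = names(sel))
  }
  attr(tr, "category") <- attr(table, "target")
  attr(tr, "selection") <- attr(sel, "selection")
  tr
}
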