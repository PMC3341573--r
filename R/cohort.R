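#' Construct a generative model for a virtual patient cohort
#'
#' A generative model is the full joint specification used by both the cohort
#' simulator and the exact enumeration-Bayes oracle: a disease taxonomy with
#' prevalences (renormalised to a probability simplex) plus, for each
#' finding, the probability of that finding being present given each disease.
#' Findings are mutually independent given the disease — the minimal
#' generative assumption under which sequential LR updating is coherent.
#'
#' @param diseases a `disease_table` ([read_disease_table()]).  Prevalences
#'   are renormalised to sum to 1.
#' @param finding_probs a numeric matrix of `P(finding present | disease)`
#'   with one row per disease (rownames = `disease_id`) and one column per
#'   finding (colnames = `finding_id`); all entries in `[0, 1]`.
#' @return an object of class `"generative_model"`.
#' @export
generative_model <- function(diseases, finding_probs) {
  stopifnot(inherits(diseases, "disease_table"), is.matrix(finding_probs))
  if (is.null(rownames(finding_probs)) || is.null(colnames(finding_probs))) {
    stop("finding_probs needs disease_id rownames and finding_id colnames",
         call. = FALSE)
  }
  missing <- setdiff(diseases$disease_id, rownames(finding_probs))
  if (length(missing)) {
    stop("finding_probs is missing disease(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(finding_probs)) || any(finding_probs < 0) || any(finding_probs > 1)) {
    stop("finding probabilities must lie in [0, 1]", call. = FALSE)
  }
  total <- sum(diseases$prevalence)
  if (total <= 0) stop("total prevalence must be positive", call. = FALSE)
  diseases$prevalence <- diseases$prevalence / total
  finding_probs <- finding_probs[diseases$disease_id, , drop = FALSE]
  structure(list(
    diseases = diseases,
    probs = finding_probs,
    finding_ids = colnames(finding_probs)
  ), class = "generative_model")
}

finding_probs <- function(model, finding_id) {
  if (!finding_id %in% model$finding_ids) {
    stop("unknown finding in model: ", finding_id, call. = FALSE)
  }
  model$probs[, finding_id]
}

#' @export
print.generative_model <- function(x, ...) {
  cat("Generative cohort model:", nrow(x$diseases), "diseases,",
      length(x$finding_ids), "findings\n")
  cat("  findings:", paste(utils::head(x$finding_ids, 8), collapse = ", "),
      if (length(x$finding_ids) > 8) "...", "\n")
  invisible(x)
}

#' Read / write a generative model as JSON
#'
#' The JSON layout is `{"diseases": [{disease_id, label, prevalence_pct,
#' category_path}, ...], "findings": {finding_id: {disease_id: prob, ...},
#' ...}}`.
#'
#' @param source path or connection to a JSON file.
#' @return a `generative_model`.
#' @export
read_generative_model <- function(source) {
  x <- jsonlite::read_json(source, simplifyVector = TRUE)
  dz <- as.data.frame(x$diseases)
  dz$prevalence_pct <- as.numeric(dz$prevalence_pct)
  dz$prevalence <- dz$prevalence_pct / 100
  dz <- structure(dz, class = c("disease_table", "data.frame"))
  fids <- names(x$findings)
  probs <- sapply(fids, function(f) unlist(x$findings[[f]])[dz$disease_id])
  probs <- matrix(as.numeric(probs), nrow = nrow(dz),
                  dimnames = list(dz$disease_id, fids))
  generative_model(dz, probs)
}

#' @rdname read_generative_model
#' @param model a `generative_model`.
#' @param file path or connection.
#' @export
write_generative_model <- function(model, file) {
  stopifnot(inherits(model, "generative_model"))
  dz <- as.data.frame(model$diseases)
  payload <- list(
    diseases = dz[, c("disease_id", "label", "prevalence_pct", "category_path")],
    findings = lapply(stats::setNames(model$finding_ids, model$finding_ids),
                      function(f) as.list(model$probs[, f]))
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}

#' Simulate a virtual patient cohort
#'
#' Each patient's disease is drawn i.i.d. from the model's prevalence
#' simplex; each binary finding is then drawn independently given the
#' disease.  The cohort is reproducible: the same `(model, n, seed)` yields
#' an identical cohort, and the caller's RNG state is left untouched.
#'
#' @param model a `generative_model`.
#' @param n number of patients (non-negative).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return a data.frame of class `"cohort"` with a `disease_id` column and
#'   one 0/1 column per finding; attributes `seed`, `n` and `diseases` (the
#'   model's disease table, used by the estimators).
#' @export
simulate_cohort <- function(model, n, seed) {
  stopifnot(inherits(model, "generative_model"), length(n) == 1L,
            is.numeric(n), length(seed) == 1L)
  if (is.na(n) || n < 0) stop("cohort size must be non-negative", call. = FALSE)
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  k <- nrow(model$diseases)
  idx <- if (n) sample.int(k, n, replace = TRUE, prob = model$diseases$prevalence) else integer()
  out <- data.frame(disease_id = model$diseases$disease_id[idx],
                    stringsAsFactors = FALSE)
  for (f in model$finding_ids) {
    out[[f]] <- if (n) stats::rbinom(n, 1L, model$probs[idx, f]) else integer()
  }
  structure(out, class = c("cohort", "data.frame"),
            seed = as.integer(seed), n = n, diseases = model$diseases,
            finding_ids = model$finding_ids)
}

#' Write a simulated cohort as CSV
#'
#' One row per patient: `disease_id` plus one 0/1 column per finding.
#'
#' @param cohort a `cohort`.
#' @param file path or connection.
#' @export
write_cohort <- function(cohort, file) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Wilson score confidence interval for a proportion
#'
#' Well-behaved near 0 and 1, where small strata push empirical
#' sensitivities/specificities to the boundary.
#'
#' @param x number of successes.
#' @param n number of trials (positive).
#' @param conf confidence level (default 0.95).
#' @return list with `point`, `ci_low`, `ci_high`, `n_pos` (successes) and
#'   `n_neg` (failures).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(point = p, ci_low = max(0, centre - half), ci_high = min(1, centre + half),
       n_pos = as.integer(x), n_neg = as.integer(n - x))
}

cohort_strata <- function(cohort, finding_id, category) {
  diseases <- attr(cohort, "diseases")
  if (!finding_id %in% names(cohort)) {
    stop("unknown finding in cohort: ", finding_id, call. = FALSE)
  }
  members <- category_members(diseases, category)
  inside <- cohort$disease_id %in% members
  if (!any(inside) || all(inside)) {
    stop("cohort must contain both members and non-members of category ",
         category, call. = FALSE)
  }
  list(inside = inside, positive = cohort[[finding_id]] == 1L)
}

#' Estimate category-level accuracy of a finding from a cohort
#'
#' Empirical sensitivity = fraction finding-positive among category members;
#' empirical specificity = fraction finding-negative among non-members.
#' Wilson 95% intervals are attached to both.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param finding_id a finding column of the cohort.
#' @param category category path string.
#' @param conf confidence level for the Wilson intervals.
#' @return list with elements `sensitivity` and `specificity`, each a
#'   [wilson_ci()] estimate.
#' @export
estimate_category_accuracy <- function(cohort, finding_id, category, conf = 0.95) {
  s <- cohort_strata(cohort, finding_id, category)
  list(
    sensitivity = wilson_ci(sum(s$positive[s$inside]), sum(s$inside), conf),
    specificity = wilson_ci(sum(!s$positive[!s$inside]), sum(!s$inside), conf)
  )
}

#' Empirical category-oriented LR with standard errors
#'
#' Plug-in estimate of the category-oriented LR pair from a simulated
#' cohort, with delta-method standard errors of the log LRs:
#' `Var(log LR+) ~ (1-p1)/(n1 p1) + (1-p0)/(n0 p0)` where `p1 = P(+|C)` and
#' `p0 = P(+|not C)`.
#'
#' @inheritParams estimate_category_accuracy
#' @return list with `lr_pos`, `lr_neg`, `se_log_lr_pos`, `se_log_lr_neg`,
#'   and the underlying 2x2 counts.
#' @export
empirical_category_lr <- function(cohort, finding_id, category) {
  s <- cohort_strata(cohort, finding_id, category)
  n1 <- sum(s$inside); n0 <- sum(!s$inside)
  x1 <- sum(s$positive[s$inside]); x0 <- sum(s$positive[!s$inside])
  p1 <- x1 / n1; p0 <- x0 / n0
  se_log <- function(a, na, b, nb) {
    sqrt((1 - a) / (na * a) + (1 - b) / (nb * b))
  }
  list(
    lr_pos = p1 / p0,
    lr_neg = (1 - p1) / (1 - p0),
    se_log_lr_pos = se_log(p1, n1, p0, n0),
    se_log_lr_neg = se_log(1 - p1, n1, 1 - p0, n0),
    counts = c(n_inside = n1, n_outside = n0,
               pos_inside = x1, pos_outside = x0)
  )
}

#' Exact posterior by enumeration over the generative model
#'
#' The brute-force Bayes oracle: for a patient profile,
#' `P(d | evidence)` is proportional to
#' `prevalence_d * prod_f p_d(f)^[present] (1 - p_d(f))^[absent]`, normalised
#' over all diseases; a category's posterior is the sum over its members.
#' Unknown findings contribute nothing.  This is the ground truth against
#' which sequential (naive-Bayes) category updating is validated.
#'
#' @param model a `generative_model`.
#' @param profile a [patient_profile()]; its findings must exist in the model.
#' @return list with `disease` (named probability vector summing to 1) and
#'   `categories` (named vector over every category path in the taxonomy,
#'   each the sum of its members' posteriors).
#' @export
exact_posterior <- function(model, profile) {
  stopifnot(inherits(model, "generative_model"))
  profile <- patient_profile(profile)
  observed <- profile[profile != "unknown"]
  unknown_findings <- setdiff(names(observed), model$finding_ids)
  if (length(unknown_findings)) {
    stop("profile finding(s) not in model: ",
         paste(unknown_findings, collapse = ", "), call. = FALSE)
  }
  lik <- rep(1, nrow(model$diseases))
  for (f in names(observed)) {
    p <- model$probs[, f]
    lik <- lik * if (observed[[f]] == "present") p else 1 - p
  }
  joint <- model$diseases$prevalence * lik
  if (sum(joint) <= 0) {
    stop("evidence has probability zero under the model", call. = FALSE)
  }
  post <- joint / sum(joint)
  names(post) <- model$diseases$disease_id
  paths <- all_category_paths(model$diseases)
  categories <- vapply(paths, function(p) {
    sum(post[category_members(model$diseases, p)])
  }, 0)
  list(disease = post, categories = categories)
}

#' Compare sequential category updating against the exact posterior
#'
#' Runs the naive-Bayes sequential update (category prior from the model's
#' taxonomy, category-oriented LRs derived analytically from the model via
#' [category_lr_table()]) and the exact enumeration posterior on the same
#' profile, and reports the discrepancy.  For a single observed finding, or
#' when finding probabilities are constant within the category and within its
#' complement, the two coincide; heterogeneous categories with several
#' findings produce a nonzero approximation error, which this report
#' quantifies instead of hiding.
#'
#' @param model a `generative_model`.
#' @param profile a [patient_profile()].
#' @param category category path string.
#' @return list of class `"naive_vs_exact"` with `naive_posterior`,
#'   `exact_posterior`, `abs_diff`, `log_odds_diff` and the underlying
#'   `trace`.
#' @export
naive_vs_exact <- function(model, profile, category) {
  prior <- category_prior(model$diseases, category)
  tab <- category_lr_table(model, category)
  trace <- revise_category(prior, profile, tab, warn_missing = FALSE)
  naive <- trace$posterior_prob
  exact <- exact_posterior(model, profile)$categories[[category]]
  lodds <- function(p) log(p) - log(1 - p)
  structure(list(
    category = category,
    naive_posterior = naive,
    exact_posterior = exact,
    abs_diff = abs(naive - exact),
    log_odds_diff = lodds(naive) - lodds(exact),
    trace = trace
  ), class = "naive_vs_exact")
}

#' @export
print.naive_vs_exact <- function(x, ...) {
  cat(sprintf("Category '%s': sequential %.6f vs exact %.6f (|diff| %.2e, log-odds diff %+.3e)\n",
              x$category, x$naive_posterior, x$exact_posterior,
              x$abs_diff, x$log_odds_diff))
  invisible(x)
}

#' Recover sensitivity/specificity from a likelihood-ratio pair
#'
#' Inverts `LR(+) = se/(1-sp)`, `LR(-) = (1-se)/sp`:
#' `sp = (LR+ - 1)/(LR+ - LR-)` and `se = LR+ (1 - LR-)/(LR+ - LR-)`.  A
#' solution in `[0, 1]` exists iff the pair is on the same side of 1
#' (`LR+ > 1 > LR-` or `LR+ < 1 < LR-`).
#'
#' @param lr_pos,lr_neg the likelihood-ratio pair.
#' @return list with `sensitivity` and `specificity`.
#' @export
accuracy_from_lr <- function(lr_pos, lr_neg) {
  stopifnot(is.numeric(lr_pos), is.numeric(lr_neg),
            length(lr_pos) == length(lr_neg))
  if (any(lr_pos <= 0) || any(lr_neg < 0)) {
    stop("LR(+) must be positive and LR(-) non-negative", call. = FALSE)
  }
  sp <- ifelse(lr_pos == 1 & lr_neg == 1, 0.5,
               (lr_pos - 1) / (lr_pos - lr_neg))
  se <- ifelse(lr_pos == 1 & lr_neg == 1, 0.5,
               lr_pos * (1 - lr_neg) / (lr_pos - lr_neg))
  bad <- !is.finite(sp) | sp < 0 | sp > 1 | se < 0 | se > 1
  if (any(bad)) {
    stop("no sensitivity/specificity in [0, 1] reproduces LR pair (",
         lr_pos[which(bad)[1]], ", ", lr_neg[which(bad)[1]], ")", call. = FALSE)
  }
  list(sensitivity = se, specificity = sp)
}

#' Demonstration generative model for non-acute abdominal pain
#'
#' Builds an "abdominal-like" cohort model on the bundled final-diagnosis
#' taxonomy: each finding's probability is constant within the organic
#' category and within its complement, chosen (via [accuracy_from_lr()]) so
#' that the model's analytic organic-category LRs match the bundled
#' category-LR table.  This is a demonstration substrate for the simulator —
#' the underlying per-disease probabilities of the source cohort are not
#' published, so the model illustrates magnitudes rather than reconstructing
#' them.
#'
#' `heterogeneity > 0` perturbs the per-disease probabilities on the logit
#' scale (deterministically, spread evenly across the diseases of each side)
#' so that the naive-Bayes approximation error of multi-finding category
#' updating can be studied; 0 keeps the model homogeneous, where sequential
#' category updating is exact.
#'
#' @param heterogeneity non-negative logit-scale spread of per-disease
#'   finding probabilities within each category side (default 0).
#' @return a `generative_model`.
#' @export
demo_abdominal_model <- function(heterogeneity = 0) {
  stopifnot(heterogeneity >= 0)
  dz <- read_disease_table(catlr_example("diseases_abdominal.csv"))
  tab <- read_accuracy_table(catlr_example("accuracy_abdominal_organic.csv"),
                             target = "organic")
  inside <- dz$disease_id %in% category_members(dz, "organic")
  spread <- function(k) if (k == 1) 0 else seq(-1, 1, length.out = k)
  z <- numeric(nrow(dz))
  z[inside] <- spread(sum(inside))
  z[!inside] <- spread(sum(!inside))
  logit <- function(p) log(p) - log(1 - p)
  expit <- function(x) 1 / (1 + exp(-x))
  probs <- matrix(NA_real_, nrow(dz), nrow(tab),
                  dimnames = list(dz$disease_id, tab$finding_id))
  for (i in seq_len(nrow(tab))) {
    acc <- accuracy_from_lr(tab$lr_pos[i], tab$lr_neg[i])
    base <- ifelse(inside, acc$sensitivity, 1 - acc$specificity)
    probs[, i] <- expit(logit(base) + heterogeneity * z)
  }
  generative_model(dz, probs)
}
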