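# Small generative models and independent oracles used across the tests.

toy_disease_table <- function(ids, prev_pct, paths) {
  disease_table(data.frame(
    disease_id = ids, label = ids,
    prevalence_pct = prev_pct, category_path = paths,
    stringsAsFactors = FALSE
  ))
}

# Homogeneous two-sided model: every finding has probability p_in within
# category "C" and p_out outside it.
homogeneous_model <- function(p_in, p_out, n_in = 2, n_out = 3,
                              prev_in = NULL, prev_out = NULL) {
  stopifnot(length(p_in) == length(p_out))
  ids <- c(paste0("c", seq_len(n_in)), paste0("x", seq_len(n_out)))
  paths <- c(rep("C", n_in), rep("notC", n_out))
  prev <- c(prev_in %||% rep(14 / n_in, n_in),
            prev_out %||% rep(86 / n_out, n_out))
  fids <- paste0("f", seq_along(p_in))
  probs <- matrix(NA_real_, length(ids), length(fids),
                  dimnames = list(ids, fids))
  for (j in seq_along(fids)) {
    probs[, j] <- c(rep(p_in[j], n_in), rep(p_out[j], n_out))
  }
  generative_model(toy_disease_table(ids, prev, paths), probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arbitrary heterogeneous model with a "C" category, a "C/sub" sub-category
# and a "notC" complement; deterministic given seed.
random_model <- function(n_dis = 6, n_find = 3, seed = 1) {
  set.seed(seed)
  ids <- paste0("d", seq_len(n_dis))
  n_c <- max(2L, n_dis %/% 2L)
  paths <- c("C/sub", rep("C", n_c - 1L), rep("notC", n_dis - n_c))
  prev <- round(runif(n_dis, 0.5, 10), 1)
  fids <- paste0("f", seq_len(n_find))
  probs <- matrix(round(runif(n_dis * n_find, 0.05, 0.95), 3),
                  n_dis, n_find, dimnames = list(ids, fids))
  generative_model(toy_disease_table(ids, prev, paths), probs)
}

random_profile <- function(model, seed = 1, p_unknown = 0.2) {
  set.seed(seed)
  states <- sample(c("present", "absent", "unknown"), length(model$finding_ids),
                   replace = TRUE,
                   prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown))
  patient_profile(stats::setNames(states, model$finding_ids))
}

# Independent enumeration oracle: builds the full joint table over
# (disease, all 2^k finding patterns), then conditions on the observed
# pattern by summing the matching cells.  Deliberately brute force.
joint_table_posterior <- function(model, profile) {
  fids <- model$finding_ids
  k <- length(fids)
  patterns <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
  colnames(patterns) <- fids
  dz <- model$diseases
  joint <- matrix(0, nrow(dz), nrow(patterns))
  for (d in seq_len(nrow(dz))) {
    for (r in seq_len(nrow(patterns))) {
      p <- dz$prevalence[d]
      for (j in seq_len(k)) {
        pf <- model$probs[d, j]
        p <- p * if (patterns[r, j] == 1L) pf else 1 - pf
      }
      joint[d, r] <- p
    }
  }
  obs <- unclass(profile)
  match_row <- rep(TRUE, nrow(patterns))
  for (f in names(obs)) {
    if (obs[[f]] == "unknown") next
    want <- if (obs[[f]] == "present") 1L else 0L
    match_row <- match_row & patterns[, f] == want
  }
  num <- rowSums(joint[, match_row, drop = FALSE])
  stats::setNames(num / sum(num), dz$disease_id)
}

joint_table_category_posterior <- function(model, profile, category) {
  post <- joint_table_posterior(model, profile)
  sum(post[category_members(model$diseases, category)])
}

# P(finding | category) / P(finding | complement) straight from the joint
# distribution of (disease, single finding).
joint_table_category_accuracy <- function(model, category, finding_id) {
  dz <- model$diseases
  members <- category_members(dz, category)
  inside <- dz$disease_id %in% members
  p <- model$probs[, finding_id]
  # joint cells: (inside?, finding present?)
  in_pos <- sum(dz$prevalence[inside] * p[inside])
  in_neg <- sum(dz$prevalence[inside] * (1 - p[inside]))
  out_pos <- sum(dz$prevalence[!inside] * p[!inside])
  out_neg <- sum(dz$prevalence[!inside] * (1 - p[!inside]))
  list(sensitivity = in_pos / (in_pos + in_neg),
       specificity = out_neg / (out_pos + out_neg))
}

accuracy_csv <- function(...) {
  # builds an accuracy_table from inline CSV text
  read_accuracy_table(textConnection(paste(c(...), collapse = "\n")))
}
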