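#' Select applicable likelihood ratios for a patient profile
#'
#' For each finding of the accuracy table observed in the profile, the
#' applicable LR is `lr_pos` when the finding is present and `lr_neg` when
#' absent; unknown findings are excluded.  Sequential multiplication of LRs
#' presumes conditionally independent findings, so within each non-empty
#' `dependence_group` only the single applicable LR with the best
#' discriminatory value — the largest `|ln LR|` — is kept (ties go to the
#' earlier table row).  Output order is table row order, making the selection
#' deterministic.
#'
#' @param profile a [patient_profile()].
#' @param table an `accuracy_table`.
#' @return a named numeric vector of LRs (names are finding ids) with a
#'   `"selection"` attribute: a data.frame recording, for every observed
#'   finding, its result, the applicable LR and whether it was kept or
#'   dropped by the dependence filter.
#' @examples
#' uti <- read_accuracy_table(catlr_example("accuracy_uti.csv"), target = "UTI")
#' prof <- read_profile(catlr_example("profile_case_uti.json"))
#' select_lrs(prof, uti)   # 1.5, 1.8, 3.1, 4
#' @export
select_lrs <- function(profile, table) {
  stopifnot(inherits(table, "accuracy_table"))
  profile <- patient_profile(profile)
  res <- profile[match(table$finding_id, names(profile))]
  res[is.na(res)] <- "unknown"
  applicable <- res != "unknown"
  lr <- ifelse(res == "present", table$lr_pos, table$lr_neg)

  detail <- data.frame(
    finding_id = table$finding_id[applicable],
    result = as.character(res[applicable]),
    lr = lr[applicable],
    dependence_group = table$dependence_group[applicable],
    kept = rep(TRUE, sum(applicable)),
    stringsAsFactors = FALSE
  )
  if (nrow(detail)) {
    for (g in unique(detail$dependence_group)) {
      if (g == "") next
      in_g <- which(detail$dependence_group == g)
      if (length(in_g) > 1) {
        score <- abs(log(detail$lr[in_g]))
        best <- in_g[which.max(score)]  # which.max takes the first on ties
        detail$kept[setdiff(in_g, best)] <- FALSE
      }
    }
  }
  kept <- detail[detail$kept, , drop = FALSE]
  out <- stats::setNames(kept$lr, kept$finding_id)
  attr(out, "selection") <- detail
  out
}

#' Read an expert scheme tree from JSON
#'
#' A scheme is a tree of branching points.  Each internal node is either a
#' *router* — a deterministic branch on one profile finding (`"present"` /
#' `"absent"` children) — or a *reviser*, which revises the probability of a
#' disease category from the profile's findings and branches on whether the
#' posterior clears the node's action threshold (`"above"` / `"below"`
#' children).  Leaves carry a terminal `action` string.  Node fields:
#' `id`, `type` (`"router"` or `"reviser"`), `question`, `finding` (router),
#' `category`, `table` (name of an accuracy table supplied to
#' [run_scheme()]), optional `modalities` filter, `threshold` (default 0.1),
#' `prior` (`"diseases"` to take the category prior from the disease table,
#' `"carry"` to continue from the running posterior of the same category, or
#' a number), and `children`.
#'
#' @param source path or connection to a JSON scheme file.
#' @return the root `scheme_node` (a nested list).
#' @export
read_scheme <- function(source) {
  if (inherits(source, "connection")) {
    source <- paste(readLines(source), collapse = "\n")
    x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else {
    x <- jsonlite::read_json(source, simplifyVector = FALSE)
  }
  validate_scheme_node(x, path = "root")
  structure(x, class = "scheme_node")
}

validate_scheme_node <- function(node, path) {
  if (!is.null(node$action)) return(invisible(TRUE))
  if (is.null(node$id) || is.null(node$type)) {
    stop("scheme node at ", path, " needs id and type (or an action)", call. = FALSE)
  }
  if (!node$type %in% c("router", "reviser")) {
    stop("scheme node ", node$id, ": unknown type ", node$type, call. = FALSE)
  }
  if (node$type == "router" && is.null(node$finding)) {
    stop("router node ", node$id, " needs a finding", call. = FALSE)
  }
  if (node$type == "reviser" && (is.null(node$category) || is.null(node$table))) {
    stop("reviser node ", node$id, " needs category and table", call. = FALSE)
  }
  kids <- node$children
  want <- if (node$type == "router") c("present", "absent") else c("above", "below")
  if (is.null(kids) || !all(want %in% names(kids))) {
    stop("scheme node ", node$id, " needs children: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  for (k in names(kids)) validate_scheme_node(kids[[k]], paste0(path, "/", k))
  invisible(TRUE)
}

#' Run a patient through an expert scheme tree
#'
#' Traverses the scheme from the root: router nodes consume the profile's
#' answer to their finding; reviser nodes revise the node's category
#' probability from the profile with [revise_category()] (restricted to the
#' node's accuracy table, optionally filtered by modality) and take the
#' `"above"` branch when the posterior is at least the node's threshold.
#' Traversal is deterministic given profile and scheme.
#'
#' @param scheme a `scheme_node` from [read_scheme()].
#' @param profile a [patient_profile()].
#' @param diseases a `disease_table` supplying category priors.
#' @param tables named list of `accuracy_table`s referenced by reviser nodes.
#' @return an object of class `"scheme_traversal"`: visited node ids, one
#'   record per node (routing decisions and full `update_trace`s), and the
#'   terminal `action`.
#' @examples
#' dz   <- read_disease_table(catlr_example("diseases_abdominal.csv"))
#' tab  <- read_accuracy_table(catlr_example("accuracy_abdominal_organic.csv"),
#'                             target = "organic")
#' sch  <- read_scheme(catlr_example("scheme_abdominal.json"))
#' prof <- read_profile(catlr_example("profile_case_abdominal.json"))
#' run_scheme(sch, prof, dz, tables = list(abdominal = tab))
#' @export
run_scheme <- function(scheme, profile, diseases, tables = list()) {
  stopifnot(inherits(scheme, "scheme_node"), inherits(diseases, "disease_table"))
  profile <- patient_profile(profile)
  visited <- character()
  records <- list()
  carried <- list()  # running posterior per category
  node <- scheme
  while (is.null(node$action)) {
    visited <- c(visited, node$id)
    if (node$type == "router") {
      ans <- if (node$finding %in% names(profile)) profile[[node$finding]] else "unknown"
      if (ans == "unknown") {
        stop("router node '", node$id, "' is unanswered: profile gives no result for finding '",
             node$finding, "'", call. = FALSE)
      }
      records[[node$id]] <- list(type = "router", finding = node$finding,
                                 answer = ans, branch = ans)
      node <- node$children[[ans]]
    } else {
      tab <- tables[[node$table]]
      if (is.null(tab)) {
        stop("reviser node '", node$id, "' references accuracy table '",
             node$table, "' not supplied in tables=", call. = FALSE)
      }
      if (!is.null(node$modalities)) {
        keep <- tab$modality %in% unlist(node$modalities)
        tab <- structure(tab[keep, , drop = FALSE],
                         class = class(tab), target = attr(tab, "target"))
      }
      prior_spec <- node$prior %||% "diseases"
      prior <- if (is.numeric(prior_spec)) {
        prior_spec
      } else if (identical(prior_spec, "carry") && !is.null(carried[[node$category]])) {
        carried[[node$category]]
      } else {
        category_prior(diseases, node$category)
      }
      sub <- unclass(profile)[names(profile) %in% tab$finding_id]
      trace <- revise_category(prior, patient_profile(sub), tab,
                               warn_missing = FALSE)
      threshold <- node$threshold %||% 0.1
      branch <- if (trace$posterior_prob >= threshold) "above" else "below"
      carried[[node$category]] <- trace$posterior_prob
      records[[node$id]] <- list(type = "reviser", category = node$category,
                                 prior = prior, trace = trace,
                                 threshold = threshold, branch = branch)
      node <- node$children[[branch]]
    }
  }
  structure(list(visited = visited, records = records, action = node$action),
            class = "scheme_traversal")
}

#' @export
print.scheme_traversal <- function(x, decimals = 2, ...) {
  cat("Scheme traversal\n")
  for (id in x$visited) {
    r <- x$records[[id]]
    if (r$type == "router") {
      cat(sprintf("  [%s] router on '%s': %s\n", id, r$finding, r$answer))
    } else {
      cat(sprintf("  [%s] revise '%s': prior %s -> posterior %s (threshold %s, branch %s)\n",
                  id, r$category, format_percent(r$prior, 1),
                  format_percent(r$trace$posterior_prob, 1),
                  format(r$threshold), r$branch))
    }
  }
  cat("  terminal action:", x$action, "\n")
  invisible(x)
}

#' Serialize a scheme traversal as JSON
#'
#' @param traversal a `scheme_traversal`.
#' @return JSON string.
#' @export
traversal_to_json <- function(traversal) {
  stopifnot(inherits(traversal, "scheme_traversal"))
  recs <- lapply(traversal$records, function(r) {
    if (r$type == "reviser") {
      r$trace <- jsonlite::fromJSON(trace_to_json(r$trace), simplifyVector = TRUE)
    }
    r
  })
  as.character(jsonlite::toJSON(
    list(visited = traversal$visited, records = recs, action = traversal$action),
    auto_unbox = TRUE, digits = NA, na = "null"))
}
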