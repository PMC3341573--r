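#' Convert a probability to odds
#'
#' Odds are the multiplicative scale on which likelihood ratios act:
#' `odds = p / (1 - p)`.  A probability of exactly 1 maps to infinite odds
#' (`Inf`), the absorbing state of Bayes' rule.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of odds (non-negative, possibly `Inf`).
#' @seealso [odds_to_prob()] for the inverse.
#' @examples
#' prob_to_odds(0.14)   # 0.1628, prints as 0.16 at 2 decimals
#' prob_to_odds(0.5)    # 1
#' @export
prob_to_odds <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p == 1, Inf, p / (1 - p))
}

#' Convert odds to a probability
#'
#' Inverse of [prob_to_odds()]: `p = o / (1 + o)`, with infinite odds mapping
#' to probability 1.
#'
#' @param o numeric vector of non-negative odds (may be `Inf`).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' odds_to_prob(4.35)   # 0.813, prints as 81%
#' @export
odds_to_prob <- function(o) {
  stopifnot(is.numeric(o))
  if (any(is.na(o)) || any(o < 0)) {
    stop("odds must be non-negative", call. = FALSE)
  }
  ifelse(is.infinite(o), 1, o / (1 + o))
}

#' Likelihood-ratio pair from sensitivity and specificity
#'
#' `LR(+) = sensitivity / (1 - specificity)` and
#' `LR(-) = (1 - sensitivity) / specificity`.  A specificity of 1 yields an
#' infinite positive LR (a positive result is pathognomonic); a specificity of
#' 0 yields an infinite negative LR.
#'
#' @param sensitivity,specificity fractions in `[0, 1]` (vectorised).
#' @return for scalar input, an object of class `"lr_pair"` (a list with
#'   elements `lr_pos` and `lr_neg`); for vector input, a data.frame with
#'   columns `lr_pos` and `lr_neg`.
#' @examples
#' lr_from_accuracy(0.9, 0.8)   # LR+ 4.5, LR- 0.125
#' @export
lr_from_accuracy <- function(sensitivity, specificity) {
  stopifnot(is.numeric(sensitivity), is.numeric(specificity),
            length(sensitivity) == length(specificity))
  bad <- is.na(sensitivity) | is.na(specificity) |
    sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1
  if (any(bad)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  lr_pos <- ifelse(specificity == 1, Inf, sensitivity / (1 - specificity))
  lr_neg <- ifelse(specificity == 0, Inf, (1 - sensitivity) / specificity)
  if (length(sensitivity) == 1L) {
    structure(list(lr_pos = lr_pos, lr_neg = lr_neg), class = "lr_pair")
  } else {
    data.frame(lr_pos = lr_pos, lr_neg = lr_neg)
  }
}

#' @export
print.lr_pair <- function(x, digits = 3, ...) {
  cat("LR(+) =", format(x$lr_pos, digits = digits),
      " LR(-) =", format(x$lr_neg, digits = digits), "\n")
  invisible(x)
}

#' Classify the diagnostic strength of a likelihood ratio
#'
#' Rule-of-thumb banding: positive LRs above 10 (negative LRs below 0.1)
#' generate large, often conclusive shifts from pre- to post-test probability;
#' positive LRs in `[5, 10]` (negative LRs in `[0.1, 0.2]`) generate moderate
#' shifts; anything else a small shift.  Band boundaries belong to the
#' moderate band ("5 to 10" is read inclusively).
#'
#' @param lr positive likelihood ratio.
#' @param direction `"positive"` for an LR applied on a positive result,
#'   `"negative"` for a negative result.
#' @return one of `"conclusive"`, `"moderate"`, `"small"`.
#' @examples
#' classify_lr_strength(12, "positive")   # conclusive
#' classify_lr_strength(7, "positive")    # moderate
#' @export
classify_lr_strength <- function(lr, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(lr), length(lr) == 1L)
  if (is.na(lr) || lr <= 0) stop("likelihood ratio must be positive", call. = FALSE)
  if (direction == "positive") {
    if (lr > 10) "conclusive" else if (lr >= 5) "moderate" else "small"
  } else {
    if (lr < 0.1) "conclusive" else if (lr <= 0.2) "moderate" else "small"
  }
}

#' Sequential Bayesian updating with likelihood ratios
#'
#' Applies an ordered list of likelihood ratios to a pre-test probability (or
#' pre-test odds) on the odds scale: `post-test odds = pre-test odds x LR1 x
#' LR2 x ...`.  All arithmetic is carried out at full floating-point
#' precision; rounding is a display-layer concern (see [format_odds()] and
#' [format_percent()]).
#'
#' Exactly one of `prior_prob` and `prior_odds` must be supplied.  Priors of 0
#' or 1 (odds 0 or `Inf`) are absorbing: the posterior equals the prior and a
#' note is recorded in the trace.
#'
#' @param prior_prob pre-test probability in `[0, 1]`.
#' @param prior_odds pre-test odds (non-negative, may be `Inf`).
#' @param lrs numeric vector of positive likelihood ratios (may be empty).
#' @param finding_ids optional character vector labelling each LR in the
#'   trace (same length as `lrs`).
#' @return an object of class `"update_trace"`: a list with the prior
#'   (both scales), a `steps` data.frame (`step`, `finding_id`, `lr`,
#'   `odds`, `prob` after each LR), the posterior on both scales, and any
#'   notes.
#' @examples
#' tr <- sequential_update(prior_odds = 0.13, lrs = c(1.5, 1.8, 3.1, 4))
#' tr$posterior_odds            # 4.3524
#' format_percent(tr$posterior_prob)  # "81%"
#' @export
sequential_update <- function(prior_prob = NULL, prior_odds = NULL, lrs = numeric(),
                              finding_ids = NULL) {
  if (is.null(prior_prob) == is.null(prior_odds)) {
    stop("supply exactly one of prior_prob and prior_odds", call. = FALSE)
  }
  if (!is.null(prior_prob)) {
    stopifnot(length(prior_prob) == 1L)
    prior_odds <- prob_to_odds(prior_prob)
  } else {
    stopifnot(length(prior_odds) == 1L, is.numeric(prior_odds))
    if (is.na(prior_odds) || prior_odds < 0) {
      stop("odds must be non-negative", call. = FALSE)
    }
    prior_prob <- odds_to_prob(prior_odds)
  }
  lrs <- as.numeric(lrs)
  if (length(lrs) && (any(is.na(lrs)) || any(lrs <= 0))) {
    stop("all likelihood ratios must be positive", call. = FALSE)
  }
  if (!is.null(finding_ids)) stopifnot(length(finding_ids) == length(lrs))
  notes <- character()

  absorbing <- prior_odds == 0 || is.infinite(prior_odds)
  if (absorbing && length(lrs)) {
    notes <- "prior of 0 or 1 is absorbing; likelihood ratios leave it unchanged"
  }
  n <- length(lrs)
  odds <- numeric(n)
  running <- prior_odds
  for (i in seq_len(n)) {
    if (!absorbing) running <- running * lrs[i]
    odds[i] <- running
  }
  steps <- data.frame(
    step = seq_len(n),
    finding_id = if (is.null(finding_ids)) rep(NA_character_, n) else as.character(finding_ids),
    lr = lrs,
    odds = odds,
    prob = if (n) odds_to_prob(odds) else numeric(),
    stringsAsFactors = FALSE
  )
  structure(list(
    prior_prob = prior_prob,
    prior_odds = prior_odds,
    steps = steps,
    posterior_odds = running,
    posterior_prob = odds_to_prob(running),
    notes = notes
  ), class = "update_trace")
}

#' Round an odds value for display
#'
#' Banker's (half-even) rounding to the requested number of decimals, applied
#' only at the display layer; computation always keeps full precision.
#'
#' @param o odds value.
#' @param decimals decimal places (default 2, matching the conventional
#'   presentation of worked odds chains).
#' @return character scalar.
#' @export
format_odds <- function(o, decimals = 2) {
  if (is.infinite(o)) return("Inf")
  formatC(round(o, decimals), format = "f", digits = decimals)
}

#' Format a probability as an integer percentage
#'
#' @param p probability in `[0, 1]`.
#' @param decimals decimal places for the percentage (default 0).
#' @return character scalar such as `"81%"`.
#' @export
format_percent <- function(p, decimals = 0) {
  paste0(formatC(round(100 * p, decimals), format = "f", digits = decimals), "%")
}

#' @export
print.update_trace <- function(x, decimals = 2, ...) {
  cat("Sequential likelihood-ratio update\n")
  cat(sprintf("  Pre-test probability = %s   pre-test odds = %s\n",
              format_percent(x$prior_prob), format_odds(x$prior_odds, decimals)))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      id <- x$steps$finding_id[i]
      lab <- if (is.na(id)) "" else paste0(" [", id, "]")
      cat(sprintf("  x LR %-6s -> odds %s (%s)%s\n",
                  format(x$steps$lr[i]),
                  format_odds(x$steps$odds[i], decimals),
                  format_percent(x$steps$prob[i]),
                  lab))
    }
  } else {
    cat("  (no likelihood ratios applied)\n")
  }
  cat(sprintf("  Post-test odds = %s   post-test probability = %s\n",
              format_odds(x$posterior_odds, decimals),
              format_percent(x$posterior_prob)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
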