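#' Cognitive domain schema
#'
#' The fixed mapping of the 18 neuropsychological outcomes onto the five
#' cognitive domains used by the nested model, together with the per-outcome
#' orientation flags.  Outcomes where a *smaller* raw score indicates better
#' performance (the four Stroop measures and the two RAVLT forgetting scores)
#' carry `invert = TRUE` and are sign-flipped before standardization so that
#' larger always means better on the modelling scale.
#'
#' Domains:
#' * `D1` verbal ability - Boston naming, D-KEFS letter fluency, category
#'   fluency and category switching;
#' * `D2` Stroop - dots, words and colors naming times and the
#'   interference (colors/dots) ratio;
#' * `D3` secondary memory - seven RAVLT measures, including the short- and
#'   long-delay forgetting scores (trial 5 minus the delayed recall);
#' * `D4` primary memory - digits forward and digits backward;
#' * `D5` perceptual speed - digit-symbol coding.
#'
#' @return An object of class `domain_schema`: a data frame with columns
#'   `outcome`, `domain`, `domain_label` and `invert`, one row per outcome,
#'   plus a `domains` attribute giving the ordered domain labels.
#' @examples
#' sch <- domain_schema()
#' table(sch$domain)
#' sch$outcome[sch$invert]
#' @export
domain_schema <- function() {
  rows <- list(
    # outcome                        domain  invert
    c("boston_naming_test",          "D1",   FALSE),
    c("dkefs_letter_fluency",        "D1",   FALSE),
    c("dkefs_category_fluency",      "D1",   FALSE),
    c("dkefs_switching_total",       "D1",   FALSE),
    c("stroop_dots_time",            "D2",   TRUE),
    c("stroop_words_time",           "D2",   TRUE),
    c("stroop_colors_time",          "D2",   TRUE),
    c("stroop_interference_ratio",   "D2",   TRUE),
    c("ravlt_sum_trials_1_5",        "D3",   FALSE),
    c("ravlt_interference_list",     "D3",   FALSE),
    c("ravlt_short_delay_recall",    "D3",   FALSE),
    c("ravlt_long_delay_recall",     "D3",   FALSE),
    c("ravlt_recognition_hits",      "D3",   FALSE),
    c("ravlt_short_delay_forgetting","D3",   TRUE),
    c("ravlt_long_delay_forgetting", "D3",   TRUE),
    c("digits_forward",              "D4",   FALSE),
    c("digits_backward",             "D4",   FALSE),
    c("digit_symbol_coding",         "D5",   FALSE)
  )
  out <- data.frame(
    outcome = vapply(rows, `[`, "", 1L),
    domain  = vapply(rows, `[`, "", 2L),
    invert  = vapply(rows, `[`, "", 3L) == "TRUE",
    stringsAsFactors = FALSE
  )
  labels <- c(D1 = "verbal ability", D2 = "Stroop", D3 = "secondary memory",
              D4 = "primary memory", D5 = "perceptual speed")
  out$domain_label <- unname(labels[out$domain])
  attr(out, "domains") <- names(labels)
  attr(out, "domain_labels") <- labels
  class(out) <- c("domain_schema", "data.frame")
  out
}

#' @export
print.domain_schema <- function(x, ...) {
  cat("Domain schema:", nrow(x), "outcomes in",
      length(attr(x, "domains")), "domains\n")
  for (d in attr(x, "domains")) {
    sub <- x[x$domain == d, ]
    cat(sprintf("  %s (%s): %s\n", d, sub$domain_label[1],
                paste0(sub$outcome, ifelse(sub$invert, "*", ""),
                       collapse = ", ")))
  }
  cat("  (* = inverted before modelling: lower raw score is better)\n")
  invisible(x)
}

#' Outcome names of the neuropsychological battery
#'
#' @param schema A [domain_schema()].
#' @return Character vector of the 18 outcome column names, in schema order.
#' @export
outcome_names <- function(schema = domain_schema()) schema$outcome

# integer domain index (1..5) per outcome, in schema order
domain_index <- function(schema = domain_schema()) {
  match(schema$domain, attr(schema, "domains"))
}

validate_schema <- function(schema) {
  stopifnot(inherits(schema, "domain_schema"))
  if (nrow(schema) != 18L)
    stop("schema must contain exactly 18 outcomes")
  if (length(attr(schema, "domains")) != 5L)
    stop("schema must define exactly 5 domains")
  if (sum(schema$invert) != 6L)
    stop("exactly 6 outcomes (4 Stroop, 2 forgetting) must be inverted")
  invisible(schema)
}
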