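#' Read Likert survey responses
#'
#' One row per (respondent, relationship) answer. Experts rate, on a 1-5
#' Likert scale from "Not at all likely" to "Completely likely", how likely
#' two roles are to interact through the EHR to manage a patient; the
#' EHR-derived high/low likelihood label is blinded to respondents.
#'
#' @param path CSV with columns `respondent_id`, `relationship_id`, `label`
#'   (`high`/`low`), `likert` (integer 1-5).
#' @return Validated tibble with those columns.
#' @export
read_survey_responses <- function(path) {
  r <- readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    relationship_id = readr::col_character(),
    label = readr::col_character(),
    likert = readr::col_double()), progress = FALSE)
  validate_responses(r)
  if (!all(r$likert == round(r$likert))) {
    stop("raw survey responses must be integer Likert scores 1..5",
         call. = FALSE)
  }
  r
}

validate_responses <- function(responses) {
  req <- c("respondent_id", "relationship_id", "label", "likert")
  if (!all(req %in% names(responses))) {
    stop("responses need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(responses$label %in% c("high", "low"))) {
    stop("label must be 'high' or 'low'", call. = FALSE)
  }
  # raw responses are integers 1..5; relationship-level mean scores may be
  # fractional but must stay on the scale
  if (any(is.na(responses$likert)) ||
      any(responses$likert < 1 | responses$likert > 5)) {
    stop("likert scores must lie in [1, 5]", call. = FALSE)
  }
  invisible(responses)
}

#' Fit the likelihood-discrimination model to Likert scores
#'
#' Least-squares fit of `likert ~ theta`, where `theta` is 1 for
#' relationships the EHR analysis labeled high-likelihood and 0 for
#' low-likelihood. With a single 0/1 predictor the intercept `alpha` is
#' exactly the low-group mean and `alpha + beta` exactly the high-group
#' mean; `beta` is the high-minus-low difference, tested against 0 by the
#' model ANOVA F test (equal to the squared t statistic for `beta`) at the
#' two-sided .05 level. A significant positive `beta` means experts can
#' distinguish the EHR-derived likelihood classes.
#'
#' @param responses Tibble as from [read_survey_responses()]; each row is
#'   one observation (responses are treated as independent; respondent
#'   clustering is ignored).
#' @return A `"likelihood_fit"` list: `alpha`, `beta`, `f_stat`, `t_stat`,
#'   `p_value`, `significant`, and `group_means` (label, n, mean, ci_lo,
#'   ci_hi; 95% t CIs on response-level data).
#' @export
fit_likelihood_model <- function(responses) {
  validate_responses(responses)
  tab <- table(responses$label)
  if (!all(c("high", "low") %in% names(tab)) || any(tab < 2)) {
    stop("need at least 2 responses in each of the high and low groups",
         call. = FALSE)
  }
  theta <- as.integer(responses$label == "high")
  if (stats::sd(responses$likert) == 0) {
    # all scores identical: no between-group difference, no evidence
    alpha <- responses$likert[1]
    beta <- 0
    f_stat <- NA_real_
    t_stat <- NA_real_
    p_value <- 1
  } else {
    fit <- stats::lm(responses$likert ~ theta)
    alpha <- unname(stats::coef(fit)[1])
    beta <- unname(stats::coef(fit)[2])
    an <- suppressWarnings(stats::anova(fit))
    f_stat <- an$`F value`[1]
    p_value <- an$`Pr(>F)`[1]
    t_stat <- tryCatch(
      suppressWarnings(summary(fit)$coefficients["theta", "t value"]),
      error = function(e) NA_real_)
    if (is.nan(f_stat) || is.na(p_value)) {
      p_value <- if (beta == 0) 1 else NA_real_
    }
  }
  gm <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = responses$label,
                                   likert = responses$likert), .data$label),
    n = dplyr::n(), mean = mean(.data$likert),
    sd = stats::sd(.data$likert), .groups = "drop")
  half <- ifelse(gm$n > 1 & gm$sd > 0,
                 stats::qt(0.975, gm$n - 1) * gm$sd / sqrt(gm$n), 0)
  gm$ci_lo <- gm$mean - half
  gm$ci_hi <- gm$mean + half
  gm$sd <- NULL
  structure(list(alpha = alpha, beta = beta, f_stat = f_stat,
                 t_stat = unname(t_stat), p_value = p_value,
                 significant = !is.na(p_value) && p_value < 0.05,
                 group_means = gm),
            class = "likelihood_fit")
}

#' @export
print.likelihood_fit <- function(x, ...) {
  cat(sprintf("Likert ~ alpha + theta * beta: alpha = %.3f (low-group mean), beta = %.3f\n",
              x$alpha, x$beta))
  cat(sprintf("  F = %.3f, p = %.4g%s\n", x$f_stat, x$p_value,
              if (isTRUE(x$significant)) " (significant at .05)" else ""))
  print(x$group_means)
  invisible(x)
}

#' Bundled NICU expert-survey relationship scores
#'
#' Mean Likert scores (panel of 13 NICU experts, 1-5 scale) for 12 role-pair
#' relationships, six labeled high- and six low-likelihood by the EHR
#' concurrency analysis. Each row is a relationship-level mean score used as
#' a single observation in the worked example of the likelihood model.
#'
#' @return Tibble `respondent_id` (`"panel-mean"`), `relationship_id`,
#'   `label`, `likert`.
#' @export
nicu_survey_scores <- function() {
  path <- system.file("extdata", "nicu_survey_relationships.csv",
                      package = "ehrcollab", mustWork = TRUE)
  r <- readr::read_csv(path, col_types = "ccd", progress = FALSE)
  r$respondent_id <- "panel-mean"
  r <- r[, c("respondent_id", "relationship_id", "label", "likert")]
  validate_responses(r)
  r
}

#' Mean Likert score per surveyed relationship
#'
#' @param responses Tibble as from [read_survey_responses()].
#' @return Tibble `relationship_id`, `label`, `n`, `mean_likert`.
#' @export
summarize_survey <- function(responses) {
  validate_responses(responses)
  dplyr::summarise(
    dplyr::group_by(responses, .data$relationship_id, .data$label),
    n = dplyr::n(), mean_likert = mean(.data$likert), .groups = "drop")
}
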