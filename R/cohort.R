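#' Read a clinical cohort table
#'
#' Parses a tab-separated cohort table with the columns `id`,
#' `age_at_diagnosis`, `sex` (M/F), `family_history` (+/-), `pathology`
#' (free text, `-` for no biopsy), `hypertension`, `hyperuricemia`
#' (+/-/ND, optionally with an age annotation such as `+ (54 y)`),
#' `egfr` (a number in mL/min/1.73m2, or `RRT (x y)` marking renal
#' replacement therapy started at age x), `urinary_protein` (g/gCr
#' number, or `negative` / `ND` / `auria`), and `potassium` (mEq/L).
#'
#' @param path TSV file path. The packaged example cohort is available
#'   via [example_cohort_path()].
#' @return A data frame of class `cohort_table` with typed helper
#'   columns: `rrt` (logical), `rrt_age`, `egfr_value`, `up_value`
#'   (numeric urinary protein, NA when non-numeric), `biopsy`, `mckd`.
#' @export
read_cohort_table <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("id", "age_at_diagnosis", "sex", "family_history", "pathology",
            "hypertension", "hyperuricemia", "egfr", "urinary_protein",
            "potassium")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(tbl$age_at_diagnosis)) ||
      any(tbl$age_at_diagnosis <= 0)) {
    stop("age_at_diagnosis must be positive", call. = FALSE)
  }
  rrt <- grepl("^RRT", tbl$egfr, ignore.case = TRUE)
  rrt_age <- rep(NA_real_, nrow(tbl))
  num <- suppressWarnings(
    as.numeric(sub(".*?([0-9]+\\.?[0-9]*).*", "\\1", tbl$egfr)))
  rrt_age[rrt] <- num[rrt]
  if (any(rrt & !is.finite(rrt_age))) {
    stop("RRT rows must carry an RRT age, e.g. 'RRT (32 y)'",
         call. = FALSE)
  }
  tbl$rrt <- rrt
  tbl$rrt_age <- rrt_age
  tbl$egfr_value <- ifelse(rrt, NA_real_, num)
  tbl$up_value <- suppressWarnings(as.numeric(tbl$urinary_protein))
  tbl$biopsy <- !(trimws(tbl$pathology) %in% c("-", "–", ""))
  tbl$mckd <- grepl("MCKD", tbl$pathology, ignore.case = TRUE)
  class(tbl) <- c("cohort_table", "data.frame")
  tbl
}

#' Path of the packaged example cohort table
#'
#' Tab-separated transcription of the published clinical characteristics
#' of the 19 long-read-confirmed cases (age at diagnosis, sex, family
#' history, pathology, hypertension, hyperuricemia, eGFR/RRT status,
#' urinary protein, serum potassium).
#'
#' @return File path.
#' @export
example_cohort_path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "vntrscreen",
              mustWork = TRUE)
}

plus_status <- function(x) {
  x <- trimws(x)
  ifelse(grepl("^\\+", x), "positive",
         ifelse(x %in% c("-", "–"), "negative", "ND"))
}

#' Summarise a clinical cohort
#'
#' Descriptive statistics: median and IQR of age at diagnosis (linear
#' interpolation of order statistics, R quantile type 7), sex counts,
#' family-history count, biopsy and MCKD-finding counts, hypertension
#' and hyperuricemia positives (ND excluded from numerators), the count
#' already on renal replacement therapy at diagnosis, and proteinuria
#' among the non-RRT patients (numeric urinary protein >= 0.15 g/gCr;
#' `negative`/`ND`/`auria` and values below threshold count as
#' non-proteinuric).
#'
#' @param tbl A `cohort_table` from [read_cohort_table()].
#' @param proteinuria_threshold g/gCr threshold (default 0.15).
#' @return A named list of class `cohort_summary`.
#' @export
summarize_cohort <- function(tbl, proteinuria_threshold = 0.15) {
  stopifnot(inherits(tbl, "cohort_table"))
  if (nrow(tbl) == 0L) stop("empty cohort", call. = FALSE)
  q <- stats::quantile(tbl$age_at_diagnosis, c(0.25, 0.5, 0.75), type = 7)
  non_rrt <- !tbl$rrt
  structure(
    list(n = nrow(tbl),
         age_median = unname(q[2L]),
         age_iqr = unname(q[c(1L, 3L)]),
         n_male = sum(tbl$sex == "M"),
         n_female = sum(tbl$sex == "F"),
         n_family_history = sum(plus_status(tbl$family_history) ==
                                  "positive"),
         n_biopsy = sum(tbl$biopsy),
         n_mckd = sum(tbl$mckd),
         n_hypertension = sum(plus_status(tbl$hypertension) == "positive"),
         n_hyperuricemia = sum(plus_status(tbl$hyperuricemia) ==
                                 "positive"),
         n_rrt_at_diagnosis = sum(tbl$rrt),
         n_non_rrt = sum(non_rrt),
         n_proteinuria_non_rrt = sum(
           non_rrt & !is.na(tbl$up_value) &
             tbl$up_value >= proteinuria_threshold)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Cohort of %d patients\n",
           "  age at diagnosis: median %g (IQR %g-%g)\n",
           "  sex: %d M / %d F; family history: %d\n",
           "  biopsies: %d (MCKD findings: %d)\n",
           "  hypertension: %d; hyperuricemia: %d\n",
           "  on RRT at diagnosis: %d; proteinuria among %d non-RRT: %d\n"),
    x$n, x$age_median, x$age_iqr[1L], x$age_iqr[2L], x$n_male, x$n_female,
    x$n_family_history, x$n_biopsy, x$n_mckd, x$n_hypertension,
    x$n_hyperuricemia, x$n_rrt_at_diagnosis, x$n_non_rrt,
    x$n_proteinuria_non_rrt))
  invisible(x)
}

#' Convert a cohort to renal-survival records
#'
#' The endpoint is ESKD: patients on renal replacement therapy
#' contribute an event at their RRT age (the event time takes precedence
#' over the diagnosis age); all others are censored at their age at
#' diagnosis.
#'
#' @param tbl A `cohort_table`.
#' @return Data frame with columns `id`, `time` (years), `event`
#'   (logical).
#' @export
to_survival <- function(tbl) {
  stopifnot(inherits(tbl, "cohort_table"))
  if (any(tbl$rrt & !is.finite(tbl$rrt_age))) {
    stop("RRT row without RRT age", call. = FALSE)
  }
  data.frame(
    id = tbl$id,
    time = ifelse(tbl$rrt, tbl$rrt_age, tbl$age_at_diagnosis),
    event = tbl$rrt,
    stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier renal survival
#'
#' Product-limit estimator of renal survival as a function of age, with
#' Greenwood standard errors and a log-scale 95% confidence interval
#' (the interval construction that matches published cohort estimates of
#' this locus). At tied times events precede censorings. The median is
#' the smallest time at which the estimated survival drops to 0.5 or
#' below; a CI bound is `NA` when the corresponding CI curve never
#' crosses 0.5 (limited events late in follow-up).
#'
#' @param surv Data frame with `time` and logical/0-1 `event` (from
#'   [to_survival()]).
#' @param conf_type Confidence-interval transform passed to
#'   [survival::survfit()] (default `"log"`).
#' @return An object of class `km_fit`: list with `table` (time, n_risk,
#'   n_event, n_censor, survival, lower, upper), `median`,
#'   `median_lower`, `median_upper`, and the underlying `survfit`
#'   object as `fit`.
#' @export
kaplan_meier <- function(surv, conf_type = "log") {
  stopifnot(nrow(surv) >= 1L)
  if (any(surv$time <= 0)) stop("survival times must be positive",
                                call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(surv$time, as.integer(surv$event)) ~ 1,
    conf.type = conf_type)
  q <- stats::quantile(fit, probs = 0.5)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv, lower = fit$lower,
                    upper = fit$upper)
  structure(
    list(table = tab,
         median = unname(q$quantile),
         median_lower = unname(q$lower),
         median_upper = unname(q$upper),
         fit = fit),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier renal survival: median %s years (95%% CI %s-%s)\n",
    format(x$median), format(x$median_lower), format(x$median_upper)))
  invisible(x)
}

#' Number-at-risk table at given ages
#'
#' @param x A `km_fit`.
#' @param times Ages (years) at which to report the number at risk.
#' @return Data frame with `time` and `n_risk`.
#' @export
number_at_risk <- function(x, times) {
  stopifnot(inherits(x, "km_fit"))
  s <- summary(x$fit, times = times, extend = TRUE)
  data.frame(time = s$time, n_risk = s$n.risk)
}

#' Plot a Kaplan-Meier renal survival curve
#'
#' Step curve with censoring ticks and the 95% confidence band, renal
#' survival probability against age. Requires ggplot2.
#'
#' @param x A `km_fit`.
#' @return A ggplot object.
#' @export
plot_renal_survival <- function(x) {
  stopifnot(inherits(x, "km_fit"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_renal_survival requires ggplot2", call. = FALSE)
  }
  tab <- x$table
  # expand the step function so the CI ribbon follows the steps
  t0 <- c(0, tab$time)
  stepify <- function(col) utils::head(rep(c(1, col), each = 2L), -1L)
  step <- data.frame(
    time = rep(t0, each = 2L)[-1L],
    survival = stepify(tab$survival),
    lower = stepify(tab$lower),
    upper = stepify(tab$upper))
  cens <- tab[tab$n_censor > 0L, , drop = FALSE]
  ggplot2::ggplot(step, ggplot2::aes(x = time, y = survival)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = cens,
                        ggplot2::aes(x = time, y = survival), shape = 3) +
    ggplot2::labs(x = "Age (years)", y = "Renal survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
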