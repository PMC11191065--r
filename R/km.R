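#' Kaplan-Meier comparator penetrance by sex and carrier status
#'
#' Product-limit estimate of the age-at-first-cancer penetrance `1 - S(t)` in
#' each of the four (sex x carrier status) strata, the nonparametric
#' comparator to the model-based penetrances. Right-censoring at age at last
#' contact; evaluation between step times uses the value of the latest step at
#' or before `t`.
#'
#' @param cohort A data frame with columns `sex` (`"male"`/`"female"`),
#'   `carrier` (0/1), `age` (age at first cancer or censoring, years) and
#'   `event` (1 = first cancer observed, 0 = censored).
#' @return A `km_penetrance` object: per-stratum step functions with numbers
#'   at risk retained. Empty strata are flagged and evaluate to `NA`.
#' @export
fit_km_penetrance <- function(cohort) {
  cohort <- as_tibble(cohort)
  stopifnot(all(c("sex", "carrier", "age", "event") %in% names(cohort)))
  cohort <- cohort[!is.na(cohort$age), ]
  strata <- expand.grid(sex = c("male", "female"), carrier = c(0, 1),
                        stringsAsFactors = FALSE)
  fits <- pmap(strata, function(sex, carrier) {
    d <- cohort[cohort$sex == sex & cohort$carrier == carrier, ]
    if (nrow(d) == 0) {
      return(list(empty = TRUE, times = numeric(), pen = numeric(),
                  n_risk = numeric(), n = 0L))
    }
    sf <- survival::survfit(survival::Surv(age, event) ~ 1, data = d)
    list(empty = FALSE, times = sf$time, pen = 1 - sf$surv,
         n_risk = sf$n.risk, n = nrow(d))
  })
  names(fits) <- paste(strata$sex, strata$carrier, sep = ".")
  structure(list(fits = fits), class = "km_penetrance")
}

km_eval <- function(km, t, sex, carrier) {
  f <- km$fits[[paste(sex, carrier, sep = ".")]]
  if (is.null(f) || f$empty) return(rep(NA_real_, length(t)))
  vapply(t, function(tt) {
    i <- findInterval(tt, f$times)
    if (i == 0) 0 else f$pen[i]
  }, numeric(1))
}

#' Weighted Kaplan-Meier risk
#'
#' Carrier-probability-weighted mixture of the stratified KM penetrances:
#' `p * KM(t | sex, carrier) + (1 - p) * KM(t | sex, wildtype)`. A missing
#' (empty) stratum propagates `NA`.
#'
#' @param t Age(s) in years.
#' @param carrier_prob Probability of carrying the deleterious variant.
#' @param sex `"male"` or `"female"`.
#' @param km A [fit_km_penetrance()] object.
#' @return Numeric vector of risk probabilities.
#' @export
km_risk <- function(t, carrier_prob, sex, km) {
  stopifnot(carrier_prob >= 0, carrier_prob <= 1)
  if (carrier_prob == 1) return(km_eval(km, t, sex, 1))
  if (carrier_prob == 0) return(km_eval(km, t, sex, 0))
  carrier_prob * km_eval(km, t, sex, 1) +
    (1 - carrier_prob) * km_eval(km, t, sex, 0)
}

#' @export
print.km_penetrance <- function(x, ...) {
  cat("<km_penetrance> strata (n):",
      paste0(names(x$fits), " (", map_dbl(x$fits, "n"), ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
autoplot.km_penetrance <- function(object, ...) {
  df <- bind_rows(imap(object$fits, function(f, nm) {
    if (f$empty) return(NULL)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble(age = c(0, f$times), pen = c(0, f$pen),
           sex = parts[1], carrier = parts[2])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$pen,
                                   colour = .data$sex,
                                   linetype = .data$carrier)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)", y = "KM penetrance",
                  colour = "Sex", linetype = "Carrier") +
    ggplot2::theme_minimal()
}
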