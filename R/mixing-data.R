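#' Standardize a covariate
#'
#' Centre and scale a continuous covariate, `x_std = (x - mean(x)) / SD(x)`,
#' keeping the original mean and standard deviation for back-transforming
#' predictions.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @return A list of class `standardized_covariate`: `values`,
#'   `original_mean`, `original_sd`.
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("non-finite values")
  s <- stats::sd(x)
  if (s == 0) stop("constant covariate cannot be standardized")
  m <- mean(x)
  structure(list(values = (x - m) / s, original_mean = m, original_sd = s),
            class = "standardized_covariate")
}

#' Derive a life stage from length and maturity
#'
#' Juveniles are identified by maturity staging when available; otherwise any
#' fish smaller than 20 cm is treated as a juvenile.
#'
#' @param length_cm Numeric vector of fish lengths (cm); `NA` allowed.
#' @param maturity Optional character vector; values `"juvenile"`/`"immature"`
#'   force juvenile, `"adult"`/`"mature"`/`"spawning"` force adult, `NA` or
#'   `"unknown"` fall back to the length rule.
#' @param juvenile_max_cm Length threshold (default 20).
#' @return Character vector `"juvenile"`/`"adult"`.
#' @export
infer_life_stage <- function(length_cm, maturity = NULL,
                             juvenile_max_cm = 20) {
  n <- length(length_cm)
  stage <- rep(NA_character_, n)
  if (!is.null(maturity)) {
    stage[maturity %in% c("juvenile", "immature")] <- "juvenile"
    stage[maturity %in% c("adult", "mature", "spawning")] <- "adult"
  }
  use_len <- is.na(stage)
  stage[use_len] <- ifelse(!is.na(length_cm[use_len]) &
                             length_cm[use_len] < juvenile_max_cm,
                           "juvenile", "adult")
  stage
}

#' Aggregate individual assignments into haul-level observations
#'
#' Builds the binomial response of the mixing models: per trawl haul and life
#' stage, the number of fish assigned to the eastern baseline (`east_count`)
#' out of all usable assigned fish (`n_fish`). Ambiguous and unusable
#' assignments are excluded; hauls with zero usable fish are dropped (and
#' reported in the `dropped_hauls` attribute).
#'
#' @param assignments An [assign_individuals()] result.
#' @param metadata `data.frame` with one row per individual: `individual_id`,
#'   `haul_id`, `period_id`, `utm_x`, environmental columns `salinity`,
#'   `oxygen`, `temperature` (constant within haul), and either `life_stage`
#'   or `length_cm` (+ optional `maturity`) from which the stage is inferred.
#' @param east_label Baseline label counted as "eastern" (default `"east"`).
#' @param area_split Longitude (same units as `utm_x`) splitting the western
#'   and eastern assessment areas (default 13).
#' @return A `data.frame` of haul observations: `haul_id`, `period_id`,
#'   `utm_x`, `area` (`west_of_13E`/`east_of_13E`), `life_stage`,
#'   `east_count`, `n_fish`, `salinity`, `oxygen`, `temperature`.
#' @export
aggregate_hauls <- function(assignments, metadata, east_label = "east",
                            area_split = 13) {
  stopifnot(inherits(assignments, "assignment_result"))
  need <- c("individual_id", "haul_id", "period_id", "utm_x",
            "salinity", "oxygen", "temperature")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  m <- merge(assignments[, c("individual_id", "assigned")], metadata,
             by = "individual_id")
  if (nrow(m) < nrow(assignments)) {
    stop("metadata missing for some assigned individuals")
  }
  if (!("life_stage" %in% names(m))) {
    m$life_stage <- infer_life_stage(m$length_cm,
                                     if ("maturity" %in% names(m)) m$maturity)
  }
  usable <- !(m$assigned %in% c("ambiguous", "unusable"))
  m <- m[usable, , drop = FALSE]
  key <- interaction(m$haul_id, m$life_stage, drop = TRUE)
  agg <- do.call(rbind, lapply(split(m, key), function(g) {
    data.frame(haul_id = g$haul_id[1], period_id = g$period_id[1],
               utm_x = g$utm_x[1],
               life_stage = g$life_stage[1],
               east_count = sum(g$assigned == east_label),
               n_fish = nrow(g),
               salinity = g$salinity[1], oxygen = g$oxygen[1],
               temperature = g$temperature[1], stringsAsFactors = FALSE)
  }))
  agg$area <- ifelse(agg$utm_x >= area_split, "east_of_13E", "west_of_13E")
  agg <- agg[order(agg$haul_id, agg$life_stage),
             c("haul_id", "period_id", "utm_x", "area", "life_stage",
               "east_count", "n_fish", "salinity", "oxygen", "temperature")]
  rownames(agg) <- NULL
  all_hauls <- unique(metadata$haul_id)
  attr(agg, "dropped_hauls") <- setdiff(all_hauls, agg$haul_id)
  agg
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes, @param n Trials, @param conf Confidence level.
#' @return Matrix with columns `prop`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(prop = p, lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' Compare pooled mixing proportions before and after a date
#'
#' Descriptive comparison of eastern proportions around an environmental event
#' (e.g. a Major Baltic Inflow): pools the fish counts on each side of
#' `split_period`, overall and per assessment area, with Wilson 95% intervals.
#'
#' @param data Haul observations (see [aggregate_hauls()]).
#' @param split_period Period id (sortable string, e.g. `"2014-Q4"`): hauls
#'   with `period_id <= split_period` count as "before", later ones "after".
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` with `period` (`before`/`after`), `area` (including
#'   `"all"`), `n_fish`, `east_count`, `prop_east`, `ci_low`, `ci_high`.
#' @export
before_after_comparison <- function(data, split_period, conf = 0.95) {
  grp <- ifelse(data$period_id <= split_period, "before", "after")
  if (!all(c("before", "after") %in% grp)) {
    stop("both periods must be non-empty")
  }
  rows <- list()
  for (g in c("before", "after")) {
    sub <- data[grp == g, , drop = FALSE]
    for (a in c("all", unique(sub$area))) {
      s2 <- if (a == "all") sub else sub[sub$area == a, , drop = FALSE]
      if (nrow(s2) == 0L) next
      n <- sum(s2$n_fish); x <- sum(s2$east_count)
      ci <- wilson_ci(x, n, conf)
      rows[[length(rows) + 1L]] <-
        data.frame(period = g, area = a, n_fish = n, east_count = x,
                   prop_east = ci[, "prop"], ci_low = ci[, "lower"],
                   ci_high = ci[, "upper"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
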