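# Behaviour classification. Categories follow the three outcomes the assay
# distinguishes -- rapid complete disintegration, slow disintegration,
# swelling -- split by the pharmacopoeial time limits (FDA 30 s, Ph. Eur.
# 3 min) plus an "instant" band for freeze-dried formulations, and "partial"
# for tablets that leave a residue without ever completing.

#' Classification thresholds
#'
#' @param completion_threshold_pct Profile level (% remaining) at or below
#'   which disintegration counts as complete. Default 10: formulations that
#'   plateau just above this are reported as partial disintegration.
#' @param instant_limit_s Endpoint bound for "instant" (default 10 s).
#' @param fast_limit_s Endpoint bound for "fast" (default 30 s, the FDA limit).
#' @param prolonged_limit_s Endpoint bound for "prolonged" (default 180 s,
#'   the European Pharmacopoeia limit).
#' @param swelling_threshold_pct Sustained level above which the profile is
#'   read as swelling (default 105, i.e. 5 points above the intact tablet,
#'   clear of the noise floor yet far below typical swelling recoveries of
#'   120-135%).
#' @param sustain_s Minimum duration the profile must hold above the swelling
#'   threshold (default 5 s).
#' @param burn_in_s Initial span ignored by the swelling detector (default
#'   5 s), covering medium addition and settling.
#' @return A named list of thresholds.
#' @export
dida_thresholds <- function(completion_threshold_pct = 10,
                            instant_limit_s = 10,
                            fast_limit_s = 30,
                            prolonged_limit_s = 180,
                            swelling_threshold_pct = 105,
                            sustain_s = 5,
                            burn_in_s = 5) {
  th <- list(completion_threshold_pct = completion_threshold_pct,
             instant_limit_s = instant_limit_s,
             fast_limit_s = fast_limit_s,
             prolonged_limit_s = prolonged_limit_s,
             swelling_threshold_pct = swelling_threshold_pct,
             sustain_s = sustain_s,
             burn_in_s = burn_in_s)
  if (!(instant_limit_s < fast_limit_s && fast_limit_s < prolonged_limit_s))
    stop_config("category limits must satisfy instant < fast < prolonged")
  if (swelling_threshold_pct <= 100)
    stop_config("swelling threshold must exceed 100%")
  th
}

#' Classify a disintegration profile
#'
#' Decision order: (1) *swelling* if the profile holds at or above the
#' swelling threshold for at least `sustain_s` seconds after the burn-in;
#' otherwise (2) the disintegration endpoint is the first time the profile
#' drops to the completion threshold and never rises above it again, giving
#' *instant*, *fast* or *prolonged* by the endpoint bounds (endpoints beyond
#' the prolonged bound are still reported as prolonged); otherwise (3)
#' *partial* -- material remains at the end of the recording.
#'
#' @param profile A `dida_profile`.
#' @param thresholds A [dida_thresholds()] list.
#' @return A `dida_classification`: `category`, `endpoint_time_s` (NA when no
#'   endpoint), `max_percent` (post burn-in), `final_percent`,
#'   `thresholds_used`.
#' @export
classify_profile <- function(profile, thresholds = dida_thresholds()) {
  stopifnot(inherits(profile, "dida_profile"))
  th <- do.call(dida_thresholds, thresholds)  # re-validate orderings
  t <- profile$times_s
  v <- profile$percent_remaining
  n <- length(v)
  post <- t >= th$burn_in_s
  if (!any(post)) post <- rep(TRUE, n)  # very short recording: use all of it
  max_percent <- max(v[post])
  final_percent <- v[n]

  category <- NULL
  if (sustained_above(t, v, th$swelling_threshold_pct, th$burn_in_s, th$sustain_s))
    category <- "swelling"

  endpoint <- NA_real_
  if (is.null(category)) {
    above <- which(v > th$completion_threshold_pct)
    if (length(above) == 0L) {
      endpoint <- t[1L]
    } else if (above[length(above)] < n) {
      endpoint <- t[above[length(above)] + 1L]
    }
    if (!is.na(endpoint)) {
      category <- if (endpoint <= th$instant_limit_s) "instant"
                  else if (endpoint <= th$fast_limit_s) "fast"
                  else "prolonged"
    } else {
      category <- "partial"
    }
  }

  structure(list(category = category,
                 endpoint_time_s = endpoint,
                 max_percent = max_percent,
                 final_percent = final_percent,
                 thresholds_used = th),
            class = "dida_classification")
}

# TRUE when some full window of length sustain_s, starting at or after
# burn_in_s and contained in the recording, stays entirely at/above `level`.
sustained_above <- function(t, v, level, burn_in_s, sustain_s) {
  n <- length(t)
  tmax <- t[n]
  ge <- v >= level
  starts <- which(t >= burn_in_s & t + sustain_s <= tmax & ge)
  for (i in starts) {
    j <- i
    ok <- TRUE
    end_t <- t[i] + sustain_s
    while (j <= n && t[j] <= end_t) {
      if (!ge[j]) { ok <- FALSE; break }
      j <- j + 1L
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' @export
print.dida_classification <- function(x, ...) {
  cat(sprintf("<dida_classification> %s (endpoint %s s, max %.1f%%, final %.1f%%)\n",
              x$category,
              if (is.na(x$endpoint_time_s)) "none" else format(x$endpoint_time_s),
              x$max_percent, x$final_percent))
  invisible(x)
}

classification_to_list <- function(x) {
  list(category = x$category,
       endpoint_time_s = if (is.na(x$endpoint_time_s)) NULL else x$endpoint_time_s,
       max_percent = x$max_percent,
       final_percent = x$final_percent,
       thresholds = x$thresholds_used)
}
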