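# Behavioral indices (partner-recognition test), exclusion rules,
# chance-level tests, and the ROUT robust outlier screen.

#' Sociability and preference indices
#'
#' Percentage interaction-time indices from the partner-recognition test.
#' In trial 1, `sociability = Tp / (Tp + Tc) * 100` where `Tp` is the time
#' interacting with the caged partner mouse and `Tc` with the object. In
#' trial 2, `preference = Tn / (Tf + Tn) * 100` where `Tn` is the time with
#' the novel and `Tf` with the familiar partner. 50% is the chance level;
#' values above 50% indicate social preference / social memory.
#'
#' @param tp,tc,tn,tf interaction times in seconds (>= 0), vectorized.
#' @return percent in `[0, 100]`; `NA` with a warning where the pair of
#'   times sums to zero (unscored mouse).
#' @export
sociability <- function(tp, tc) {
  stopifnot(all(tp >= 0, na.rm = TRUE), all(tc >= 0, na.rm = TRUE))
  tot <- tp + tc
  if (any(tot == 0, na.rm = TRUE))
    warning("zero total interaction time: sociability undefined for some mice")
  ifelse(tot > 0, tp / tot * 100, NA_real_)
}

#' @rdname sociability
#' @export
preference <- function(tn, tf) {
  stopifnot(all(tn >= 0, na.rm = TRUE), all(tf >= 0, na.rm = TRUE))
  tot <- tn + tf
  if (any(tot == 0, na.rm = TRUE))
    warning("zero total interaction time: preference undefined for some mice")
  ifelse(tot > 0, tn / tot * 100, NA_real_)
}

#' Score a table of interaction records
#'
#' Adds `sociability` and `preference` columns to a data.frame with columns
#' `Tp`, `Tc` (trial 1) and `Tn`, `Tf` (trial 2), in seconds.
#'
#' @param records data.frame of interaction times, one row per mouse.
#' @return the records with `sociability` and `preference` columns appended.
#' @export
score_interactions <- function(records) {
  stopifnot(all(c("Tp", "Tc", "Tn", "Tf") %in% names(records)))
  records$sociability <- sociability(records$Tp, records$Tc)
  records$preference <- preference(records$Tn, records$Tf)
  records
}

#' Apply the pre-registered exclusion rules
#'
#' Removes mice with sociability at or below the cutoff (inclusive, `<= 55%`
#' in the reproduced protocol: such mice did not engage with the partner)
#' and mice whose partners were flagged for aggression (logical column
#' `aggression`, if present). Removals are returned in an exclusion log,
#' never silently dropped.
#'
#' @param records scored data.frame (see [score_interactions()]).
#' @param sociability_cutoff inclusive sociability cutoff in percent.
#' @return the retained rows, with attribute `exclusion_log`: a data.frame
#'   of excluded rows and the reason for each.
#' @export
apply_exclusions <- function(records, sociability_cutoff = 55) {
  if (nrow(records) == 0) {
    attr(records, "exclusion_log") <- data.frame(row = integer(),
                                                 reason = character())
    return(records)
  }
  reason <- rep(NA_character_, nrow(records))
  soc <- if ("sociability" %in% names(records)) records$sociability
         else sociability(records$Tp, records$Tc)
  # inclusive cutoff with a float-safe margin: Tp/(Tp+Tc)*100 can land a
  # hair above an exactly-representable boundary (55/100*100 > 55)
  low <- !is.na(soc) & soc <= sociability_cutoff + 1e-9
  reason[low] <- sprintf("sociability %.1f%% <= %.1f%%", soc[low], sociability_cutoff)
  if ("aggression" %in% names(records)) {
    agg <- isTRUE_vec(records$aggression) & is.na(reason)
    reason[agg] <- "partner aggression"
  }
  keep <- is.na(reason)
  log <- data.frame(row = which(!keep), reason = reason[!keep],
                    stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' One-sample t-test against a chance level
#'
#' Standard two-sided one-sample t-test of index values against a
#' hypothetical mean — 50% for sociability/preference, 22.5 s for the
#' water-maze probe-trial quadrant time.
#'
#' @param values numeric vector (n >= 2, non-zero variance).
#' @param hypothetical hypothesized mean under chance behaviour.
#' @return one-row `data.frame`: `n`, `mean`, `t`, `df`, `p`,
#'   `hypothetical`.
#' @export
chance_test <- function(values, hypothetical = 50) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    mg_stop("chance test needs at least two values", "mgmorph_bad_sample")
  if (sd(values) == 0) {
    if (values[1] == hypothetical)
      return(data.frame(n = length(values), mean = hypothetical, t = 0,
                        df = length(values) - 1, p = 1,
                        hypothetical = hypothetical))
    mg_stop("zero variance: t-test undefined", "mgmorph_bad_sample")
  }
  tt <- t.test(values, mu = hypothetical)
  data.frame(n = length(values), mean = unname(tt$estimate),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, hypothetical = hypothetical)
}

#' ROUT outlier screen for a univariate sample
#'
#' The ROUT procedure (robust fit followed by a false-discovery-rate outlier
#' decision) specialized to a constant-only model. The robust location is
#' the median; the robust scale is the RSDR, the 68.27th percentile of the
#' absolute residuals with the small-sample correction `n / (n - K)`
#' (K = 1 parameter). Each point gets a two-tailed t probability of its
#' standardized residual (df = n - K); points are then tested from the
#' largest residual inward with the step-down thresholds
#' `alpha_i = Q (n - i + 1) / n`, stopping at the first non-outlier, so at
#' most a fraction ~Q of clean data is flagged. Flagged points are returned,
#' never silently dropped.
#'
#' @param values numeric vector, n >= 3.
#' @param Q maximum desired false-discovery rate, percent (5 for single-cell
#'   metrics, 10 for expression-style tables in the reproduced analysis).
#' @return logical vector flagging outliers, with attributes `rsdr`,
#'   `center` and `p` (per-point tail probabilities).
#' @export
rout_outliers <- function(values, Q = 5) {
  stopifnot(Q > 0, Q < 50)
  x <- values
  ok <- !is.na(x)
  if (sum(ok) < 3)
    mg_stop("ROUT needs at least three values", "mgmorph_bad_sample")
  n <- sum(ok)
  K <- 1
  center <- median(x[ok])
  res <- abs(x - center)
  rsdr <- unname(quantile(res[ok], 0.6827, type = 7)) * n / (n - K)
  flags <- rep(FALSE, length(x))
  p <- rep(NA_real_, length(x))
  if (rsdr == 0) {                       # constant data: nothing to flag
    p[ok] <- 1
  } else {
    p[ok] <- 2 * pt(-res[ok] / rsdr, df = n - K)
    ord <- order(res, decreasing = TRUE, na.last = NA)
    q <- Q / 100
    for (i in seq_along(ord)) {
      alpha_i <- q * (n - i + 1) / n
      if (p[ord[i]] < alpha_i) flags[ord[i]] <- TRUE else break
    }
  }
  attr(flags, "rsdr") <- rsdr
  attr(flags, "center") <- center
  attr(flags, "p") <- p
  flags
}
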