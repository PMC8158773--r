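# ---- helpers ----------------------------------------------------------------

#' Half-up rounding
#'
#' Presentation rounding used for zone boundaries: exact halves round away
#' from zero (base \code{round()} rounds to even).
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Default zone deviation fractions
#'
#' The five clinical-risk zones of the error grid are bounded at relative
#' deviations of 1/12, 2/12, 4/12 and 5/12 of the reference value. These
#' are exact rationals, not the rounded percentages (8.3, 16.6, 33.3,
#' 41.6\%) used when quoting them: for a reference of 140 mmHg the zone-A
#' band is 140 * (1 +/- 1/12) = 128.33/151.67, which prints as 128.3/151.7.
#' @export
zone_fractions <- c(A = 1, B = 2, C = 4, D = 5) / 12

get_pairs_cols <- function(pairs, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  ref <- pairs[[paste0(target, "_ref")]]
  pred <- pairs[[paste0(target, "_pred")]]
  if (is.null(ref) || is.null(pred))
    stop("pairs must contain columns ", target, "_ref and ", target, "_pred")
  if (anyNA(ref) || anyNA(pred)) stop("missing values in paired measurements")
  list(ref = ref, pred = pred)
}

# ---- Bland-Altman -----------------------------------------------------------

#' Bland-Altman agreement analysis
#'
#' Differences are oriented predicted - reference (cuffless minus cuff).
#' Reports the bias (mean difference), the sample sd of the differences, the
#' 95\% CI of the bias and its one-sample t-test against zero, the 95\%
#' limits of agreement (bias +/- 1.96 sd), and the per-pair (mean,
#' difference) coordinates for plotting. With fewer than 3 pairs, or
#' zero-variance differences, the t-based quantities degenerate: p is NA
#' and the CI collapses onto the bias.
#'
#' @param pairs data.frame with \code{<target>_ref} and \code{<target>_pred}
#'   columns (mmHg).
#' @param target \code{"sbp"} or \code{"dbp"}.
#' @return List: \code{n}, \code{bias}, \code{sd}, \code{ci} (length 2),
#'   \code{p}, \code{loa} (length 2), \code{means}, \code{diffs}.
#' @export
bland_altman <- function(pairs, target = "sbp") {
  pc <- get_pairs_cols(pairs, target)
  d <- pc$pred - pc$ref
  n <- length(d)
  bias <- mean(d)
  sdd <- if (n > 1) stats::sd(d) else 0
  if (n >= 3 && sdd > 0) {
    tt <- stats::t.test(d)
    ci <- as.numeric(tt$conf.int); p <- tt$p.value
  } else {
    ci <- c(bias, bias); p <- NA_real_
  }
  list(n = n, bias = bias, sd = sdd, ci = ci, p = p,
       loa = c(lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd),
       means = (pc$pred + pc$ref) / 2, diffs = d)
}

#' Spearman rank correlation between reference and predicted BP
#'
#' Mid-rank handling of ties; two-sided p. A constant vector has no defined
#' rank correlation: r and p are returned as NA.
#'
#' @inheritParams bland_altman
#' @return List with \code{r} and \code{p}.
#' @export
spearman_corr <- function(pairs, target = "sbp") {
  pc <- get_pairs_cols(pairs, target)
  if (length(pc$ref) < 3 || stats::sd(pc$ref) == 0 || stats::sd(pc$pred) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(pc$ref, pc$pred,
                                         method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value)
}

# ---- zonal error grid -------------------------------------------------------

#' Zone label of one reference/predicted pair
#'
#' Clarke-style zone from the relative deviation d = |predicted -
#' reference| / reference: zone A for d <= 1/12 (clinically accurate), B
#' for d <= 2/12 (no significant clinical importance), C for d <= 4/12
#' (may influence decisions, not life-threatening), D for d <= 5/12
#' (potentially dangerous), E beyond (extreme error). Upper edges are
#' inclusive; the grid is symmetric in the sign of the deviation.
#'
#' @param reference Reference (cuff) value, mmHg, positive. Vectorized.
#' @param predicted Predicted (cuffless) value, mmHg. Vectorized.
#' @param fractions Deviation fractions, increasing, defaults
#'   \code{\link{zone_fractions}}.
#' @return Character vector of zone labels in \code{c("A","B","C","D","E")}.
#' @export
zone_of <- function(reference, predicted, fractions = zone_fractions) {
  if (any(reference <= 0)) stop("reference must be positive")
  stopifnot(length(fractions) == 4, !is.unsorted(fractions))
  d <- abs(predicted - reference) / reference
  eps <- 1e-12
  zones <- rep("E", length(d))
  zones[d <= fractions[4] + eps] <- "D"
  zones[d <= fractions[3] + eps] <- "C"
  zones[d <= fractions[2] + eps] <- "B"
  zones[d <= fractions[1] + eps] <- "A"
  zones
}

#' Zone boundary values for a reference pressure
#'
#' The eight boundary pressures reference * (1 +/- f) for the four deviation
#' fractions, rounded half-up to one decimal. For a cuff value of 140 mmHg
#' the zone-A band is (128.3, 151.7), B extends to (116.7, 163.3), C to
#' (93.3, 186.7) and D to (81.7, 198.3); beyond lies zone E.
#'
#' @inheritParams zone_of
#' @return data.frame with columns \code{zone}, \code{fraction},
#'   \code{lower}, \code{upper} (mmHg, one decimal).
#' @export
zone_boundaries <- function(reference, fractions = zone_fractions) {
  if (length(reference) != 1 || reference <= 0)
    stop("reference must be a single positive value")
  nm <- names(fractions) %||% LETTERS[seq_along(fractions)]
  data.frame(zone = nm, fraction = as.numeric(fractions),
             lower = round_half_up(reference * (1 - fractions), 1),
             upper = round_half_up(reference * (1 + fractions), 1),
             row.names = NULL)
}

#' Zonal error grid over a set of pairs
#'
#' @inheritParams bland_altman
#' @param fractions Deviation fractions (see \code{\link{zone_of}}).
#' @return List: \code{zones} (per pair), \code{counts}, \code{percent}
#'   (named A-E, summing to 100), \code{scatter} (data.frame reference,
#'   predicted, zone; reference on X by convention).
#' @export
error_grid <- function(pairs, target = "sbp", fractions = zone_fractions) {
  pc <- get_pairs_cols(pairs, target)
  z <- zone_of(pc$ref, pc$pred, fractions)
  counts <- table(factor(z, levels = c("A", "B", "C", "D", "E")))
  list(zones = z,
       counts = as.list(as.integer(counts) |> stats::setNames(names(counts))),
       percent = as.list((100 * as.integer(counts) / length(z)) |>
                           stats::setNames(names(counts))),
       scatter = data.frame(reference = pc$ref, predicted = pc$pred,
                            zone = z))
}

# ---- subgroup error analysis ------------------------------------------------

#' Per-subgroup error summaries
#'
#' Subjects are grouped by their reference cuff values: "low" when SBP <
#' 110 and DBP < 70 mmHg, "high" when SBP > 140 or DBP > 90, otherwise
#' "middle". For each subgroup and target the predicted - reference error is
#' summarized (mean, sd, median, quartiles) with a one-sample Wilcoxon
#' signed-rank test of zero median error. Empty subgroups yield a row of
#' NAs with a warning; degenerate tests (all errors zero) report p = NA.
#'
#' @param pairs data.frame with \code{sbp_ref}, \code{dbp_ref},
#'   \code{sbp_pred}, \code{dbp_pred}.
#' @return data.frame: subgroup, target, n, mean, sd, median, q25, q75, p.
#' @export
subgroup_errors <- function(pairs) {
  s <- get_pairs_cols(pairs, "sbp"); d <- get_pairs_cols(pairs, "dbp")
  grp <- ifelse(s$ref < 110 & d$ref < 70, "low",
                ifelse(s$ref > 140 | d$ref > 90, "high", "middle"))
  out <- list()
  for (g in c("low", "middle", "high")) {
    for (tg in c("sbp", "dbp")) {
      pc <- if (tg == "sbp") s else d
      e <- (pc$pred - pc$ref)[grp == g]
      if (!length(e)) {
        warning("empty subgroup: ", g, " (", tg, ")", call. = FALSE)
        out[[length(out) + 1]] <- data.frame(
          subgroup = g, target = tg, n = 0L, mean = NA_real_, sd = NA_real_,
          median = NA_real_, q25 = NA_real_, q75 = NA_real_, p = NA_real_)
        next
      }
      p <- if (all(e == 0) || length(e) < 2) NA_real_ else
        suppressWarnings(stats::wilcox.test(e)$p.value)
      q <- stats::quantile(e, c(0.25, 0.75))
      out[[length(out) + 1]] <- data.frame(
        subgroup = g, target = tg, n = length(e), mean = mean(e),
        sd = if (length(e) > 1) stats::sd(e) else NA_real_,
        median = stats::median(e), q25 = unname(q[1]), q75 = unname(q[2]),
        p = p)
    }
  }
  do.call(rbind, out)
}

# ---- hypertension classification --------------------------------------------

#' Hypertension / prehypertension classification metrics
#'
#' A subject is labelled positive when SBP exceeds the systolic threshold OR
#' DBP exceeds the diastolic one (hypertension: > 140/90 mmHg;
#' prehypertension: > 130/85 mmHg), applied identically to reference and
#' predicted values. Sensitivity, specificity and accuracy come from the
#' confusion table. The AUC uses a continuous exceedance score - the larger
#' of the two threshold-scaled exceedances max((SBP-s)/s, (DBP-d)/d) of the
#' predicted values - with DeLong variance for its 95\% CI, since a binary
#' label alone carries no ROC curve.
#'
#' @param pairs data.frame with \code{sbp_ref}, \code{dbp_ref},
#'   \code{sbp_pred}, \code{dbp_pred}.
#' @param condition \code{"hypertension"} (140/90) or
#'   \code{"prehypertension"} (130/85).
#' @return List: condition, thresholds, confusion counts (tp, fp, tn, fn),
#'   sensitivity/specificity/accuracy (\%), auc, auc_ci (DeLong 95\%).
#' @export
classify_hypertension <- function(pairs,
                                  condition = c("hypertension",
                                                "prehypertension")) {
  condition <- match.arg(condition)
  thr <- if (condition == "hypertension") c(sbp = 140, dbp = 90)
         else c(sbp = 130, dbp = 85)
  s <- get_pairs_cols(pairs, "sbp"); d <- get_pairs_cols(pairs, "dbp")
  lab_ref <- s$ref > thr["sbp"] | d$ref > thr["dbp"]
  lab_pred <- s$pred > thr["sbp"] | d$pred > thr["dbp"]
  tp <- sum(lab_ref & lab_pred); fn <- sum(lab_ref & !lab_pred)
  tn <- sum(!lab_ref & !lab_pred); fp <- sum(!lab_ref & lab_pred)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  if (!(tp + fn) || !(tn + fp))
    warning("single-class reference: sensitivity or specificity undefined",
            call. = FALSE)
  acc <- 100 * (tp + tn) / length(lab_ref)
  score <- pmax((s$pred - thr["sbp"]) / thr["sbp"],
                (d$pred - thr["dbp"]) / thr["dbp"])
  auc <- NA_real_; auc_ci <- c(NA_real_, NA_real_)
  if ((tp + fn) > 0 && (tn + fp) > 0) {
    roc <- pROC::roc(response = lab_ref, predictor = score,
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
    # ci.auc warns that a degenerate CI of a perfect AUC is uninformative;
    # the collapsed interval is still the correct DeLong limit here
    ci <- tryCatch(
      suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong"))),
      error = function(e) c(NA_real_, auc, NA_real_))
    auc_ci <- ci[c(1, 3)]
  }
  list(condition = condition, thresholds = as.list(thr),
       confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = sens, specificity = spec, accuracy = acc,
       auc = auc, auc_ci = auc_ci)
}

# ---- full evaluation --------------------------------------------------------

#' Evaluate predicted against reference blood pressures
#'
#' Runs the whole agreement layer on paired cuff-reference and cuffless
#' predictions: Bland-Altman and Spearman for both pressures, the zonal
#' error grid, subgroup error analysis, and hypertension /
#' prehypertension classification with DeLong AUC intervals.
#'
#' @param pairs data.frame with columns \code{sbp_ref}, \code{dbp_ref},
#'   \code{sbp_pred}, \code{dbp_pred} (one row per subject).
#' @param fractions Zone deviation fractions.
#' @return Nested report list (serializable with \code{\link{write_report}}).
#' @export
evaluate_predictions <- function(pairs, fractions = zone_fractions) {
  stopifnot(nrow(pairs) >= 1)
  strip_plot <- function(ba) ba[setdiff(names(ba), c("means", "diffs"))]
  eg <- function(tg) {
    g <- error_grid(pairs, tg, fractions)
    g[c("counts", "percent")]
  }
  list(
    schema_version = report_schema_version,
    n = nrow(pairs),
    bland_altman = list(sbp = strip_plot(bland_altman(pairs, "sbp")),
                        dbp = strip_plot(bland_altman(pairs, "dbp"))),
    spearman = list(sbp = spearman_corr(pairs, "sbp"),
                    dbp = spearman_corr(pairs, "dbp")),
    error_grid = list(sbp = eg("sbp"), dbp = eg("dbp")),
    subgroups = subgroup_errors(pairs),
    classification = list(
      hypertension = classify_hypertension(pairs, "hypertension"),
      prehypertension = classify_hypertension(pairs, "prehypertension")))
}

# ---- plots ------------------------------------------------------------------

#' Bland-Altman plot
#' @param pairs,target See \code{\link{bland_altman}}.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, target = "sbp") {
  ba <- bland_altman(pairs, target)
  df <- data.frame(m = ba$means, d = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = 2) +
    ggplot2::labs(x = sprintf("Mean of methods, %s (mmHg)", toupper(target)),
                  y = "Cuffless - cuff (mmHg)",
                  title = sprintf("Bland-Altman, %s: bias %.2f, sd %.2f",
                                  toupper(target), ba$bias, ba$sd))
}

#' Zonal error-grid scatterplot
#'
#' Reference (cuff) on X, predicted (cuffless) on Y, with the zone bands
#' drawn as deviation envelopes around the identity line.
#' @param pairs,target,fractions See \code{\link{error_grid}}.
#' @return A ggplot object.
#' @export
plot_error_grid <- function(pairs, target = "sbp",
                            fractions = zone_fractions) {
  g <- error_grid(pairs, target, fractions)
  sc <- g$scatter
  rng <- range(c(sc$reference, sc$predicted))
  xx <- seq(rng[1] * 0.9, rng[2] * 1.1, length.out = 100)
  bands <- do.call(rbind, lapply(seq_along(fractions), function(k)
    data.frame(x = xx, lo = xx * (1 - fractions[k]),
               hi = xx * (1 + fractions[k]),
               zone = names(fractions)[k])))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(x = .data$x, y = .data$lo,
                                    group = .data$zone),
                       linetype = 3, color = "grey40") +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(x = .data$x, y = .data$hi,
                                    group = .data$zone),
                       linetype = 3, color = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(data = sc,
                        ggplot2::aes(x = .data$reference, y = .data$predicted,
                                     color = .data$zone), alpha = 0.7) +
    ggplot2::labs(x = sprintf("Cuff %s (mmHg)", toupper(target)),
                  y = sprintf("Cuffless %s (mmHg)", toupper(target)),
                  color = "Zone",
                  title = sprintf("Zonal error grid, %s: %.1f%% in zone A",
                                  toupper(target),
                                  g$percent$A))
}
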