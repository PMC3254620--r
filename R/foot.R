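# Pedal-proportion analyses: inter-element ratios, geometric-mean
# standardization of element lengths, discriminant classification with
# jackknife cross-validation, and single-specimen comparisons of fossils
# to extant group distributions.

FOOT_ELEMENTS <- c("mt1", "mt2", "mt3", "mt4", "mt5",
                   "pp1", "pp2", "pp3", "pp4", "pp5",
                   "ip2", "ip3", "ip5")
FOOT_RATIOS <- c("pp4_mt4", "mt1_mt2", "mt3_mt4", "mt4_mt5",
                 "pp2_pp5", "pp3_pp4")
# DFA-2 drops the metatarsals; of the 8 phalangeal lengths the hallucal
# proximal phalanx is excluded to make the seven-variable set.
PHALANGES7 <- c("pp2", "pp3", "pp4", "pp5", "ip2", "ip3", "ip5")

#' Six pedal inter-element ratios
#'
#' pp4/mt4 (prehensility), mt1/mt2 (hallux hypertrophy), mt3/mt4 (foot
#' axis), mt4/mt5, pp2/pp5 (digit II reduction, grooming-claw linked) and
#' pp3/pp4. Ratios whose elements are missing come back \code{NA}.
#'
#' @param records data.frame with (a subset of) the element-length columns
#'   \code{mt1..mt5, pp1..pp5, ip2, ip3, ip5} in mm.
#' @return data.frame of the six ratios, plus \code{individual_id} if
#'   present.
#' @export
compute_foot_ratios <- function(records) {
  stopifnot(is.data.frame(records))
  gv <- function(v) if (v %in% names(records)) records[[v]] else
    rep(NA_real_, nrow(records))
  div <- function(num, den) {
    bad <- which(!is.na(den) & den == 0)
    if (length(bad))
      stop(sprintf("invalid measurement: zero denominator (row %d)", bad[1]))
    num / den
  }
  out <- data.frame(pp4_mt4 = div(gv("pp4"), gv("mt4")),
                    mt1_mt2 = div(gv("mt1"), gv("mt2")),
                    mt3_mt4 = div(gv("mt3"), gv("mt4")),
                    mt4_mt5 = div(gv("mt4"), gv("mt5")),
                    pp2_pp5 = div(gv("pp2"), gv("pp5")),
                    pp3_pp4 = div(gv("pp3"), gv("pp4")))
  if ("individual_id" %in% names(records))
    out <- cbind(records["individual_id"], out)
  out
}

#' Geometric-mean standardization of foot element lengths
#'
#' Divides each element length by the geometric mean of the chosen
#' variable set: all 13 elements for the full discriminant analysis, or
#' the 7 phalangeal elements (pp2-pp5, ip2, ip3, ip5) for the
#' phalanx-only analysis, for which a new geometric mean is computed.
#'
#' @param records data.frame of element lengths.
#' @param variable_set \code{"all13"} or \code{"phalanges7"}.
#' @return data.frame of standardized lengths (columns suffixed
#'   \code{_GM}) plus \code{GM}.
#' @export
gm_standardize_foot <- function(records,
                                variable_set = c("all13", "phalanges7")) {
  variable_set <- match.arg(variable_set)
  vars <- if (variable_set == "all13") FOOT_ELEMENTS else PHALANGES7
  if (variable_set == "phalanges7")
    message("phalanx-only variable set: using ", paste(PHALANGES7,
            collapse = ", "), " (pp1 excluded)")
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("insufficient data: missing element column(s) ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(records[vars])
  if (anyNA(x)) {
    i <- which(rowSums(is.na(x)) > 0)[1]
    stop("insufficient data: missing ",
         vars[which(is.na(x[i, ]))[1]], " in row ", i)
  }
  if (any(x <= 0)) stop("invalid measurement: non-positive length")
  gm <- exp(rowMeans(log(x)))
  out <- as.data.frame(x / gm)
  names(out) <- paste0(vars, "_GM")
  out$GM <- gm
  if ("individual_id" %in% names(records))
    out <- cbind(records["individual_id"], out)
  out
}

#' Fit a linear discriminant model with equal priors
#'
#' Thin wrapper over \code{MASS::lda} with equal priors (collection
#' sample sizes are artifacts, so no group is favoured a priori).
#'
#' @param x data.frame/matrix of predictors.
#' @param groups group labels (>= 2 groups).
#' @return object of class \code{"unguis_lda"} wrapping the fit.
#' @export
lda_fit <- function(x, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  x <- as.data.frame(x)
  fit <- MASS::lda(x, grouping = groups,
                   prior = rep(1 / nlevels(groups), nlevels(groups)))
  structure(list(fit = fit, levels = levels(groups)),
            class = "unguis_lda")
}

#' Classify records with a fitted discriminant model
#'
#' @param model an \code{\link{lda_fit}} result.
#' @param newdata data.frame of predictors.
#' @return data.frame with \code{group} (assigned class) and one posterior
#'   column per group; posteriors sum to 1.
#' @export
lda_classify <- function(model, newdata) {
  stopifnot(inherits(model, "unguis_lda"))
  pr <- stats::predict(model$fit, as.data.frame(newdata))
  out <- data.frame(group = as.character(pr$class),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pr$posterior))
}

#' Leave-one-out (jackknife) cross-validated classification success
#'
#' Refits the discriminant model once per record with that record held
#' out, classifies it, and reports overall and per-group success rates.
#'
#' @param x predictors.
#' @param groups labels; every group needs >= 2 records.
#' @return list with \code{success} (overall), \code{per_group},
#'   \code{assignments} (per-record predicted group) and \code{refits}
#'   (the number of model refits, equal to the number of records).
#' @export
loo_cv <- function(x, groups) {
  x <- as.data.frame(x)
  groups <- factor(groups)
  if (any(table(groups) < 2))
    stop("insufficient data: every group needs >= 2 records")
  n <- nrow(x)
  pred <- character(n)
  refits <- 0L
  for (i in seq_len(n)) {
    fit <- lda_fit(x[-i, , drop = FALSE], droplevels(groups[-i]))
    refits <- refits + 1L
    pred[i] <- lda_classify(fit, x[i, , drop = FALSE])$group
  }
  ok <- pred == as.character(groups)
  list(success = mean(ok),
       per_group = tapply(ok, groups, mean),
       assignments = data.frame(observed = as.character(groups),
                                predicted = pred,
                                stringsAsFactors = FALSE),
       refits = refits)
}

#' Conservative estimate of a fossil's fourth metatarsal length
#'
#' When a published mt4 length is implausible, predict it from the
#' fossil's mt3 and mt5 via the extant distributions of mt4/mt3 and
#' mt4/mt5. The conservative point estimate is the smaller of
#' \code{mt3 * min(mt4/mt3)} and \code{mt5 * min(mt4/mt5)} over the extant
#' sample (the shortest mt4 any sampled primate's proportions would
#' imply); the full predictive interval from both ratio distributions is
#' returned alongside.
#'
#' @param mt3,mt5 fossil element lengths (mm).
#' @param extant data.frame with columns \code{mt3}, \code{mt4},
#'   \code{mt5} for the extant sample (complete cases used).
#' @return list with \code{estimate}, \code{interval} (range over both
#'   prediction sets) and the per-ratio prediction vectors.
#' @export
estimate_mt4 <- function(mt3, mt5, extant) {
  keep <- stats::complete.cases(extant[c("mt3", "mt4", "mt5")])
  extant <- extant[keep, , drop = FALSE]
  if (!nrow(extant)) stop("insufficient data: no complete extant records")
  r3 <- extant$mt4 / extant$mt3
  r5 <- extant$mt4 / extant$mt5
  pred3 <- mt3 * r3
  pred5 <- mt5 * r5
  list(estimate = min(mt3 * min(r3), mt5 * min(r5)),
       interval = range(c(pred3, pred5)),
       pred_from_mt3 = pred3, pred_from_mt5 = pred5)
}

#' Group-comparison test battery for a pedal ratio
#'
#' Two-group design (prosimian vs anthropoid): Welch two-sample t (the
#' unequal-variance adjustment) and Mann-Whitney U. Five-group design:
#' one-way ANOVA F, Kruskal-Wallis H, post hoc Tukey HSD and pairwise
#' Mann-Whitney tests assessed at a Bonferroni-adjusted alpha.
#'
#' @param values numeric ratio values.
#' @param groups group labels (2 or 5 levels to match \code{design}).
#' @param design \code{"two_group"} or \code{"five_group"}.
#' @param alpha family-wise level for the post hoc flag.
#' @return list of test results; see details of each component.
#' @export
group_tests <- function(values, groups, design = c("two_group",
                                                   "five_group"),
                        alpha = 0.05) {
  design <- match.arg(design)
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (any(table(groups) < 2))
    stop("insufficient data: every group needs >= 2 observations")
  if (design == "two_group") {
    if (nlevels(groups) != 2) stop("two_group design needs 2 groups")
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    wt <- stats::t.test(a, b, var.equal = FALSE)
    mw <- stats::wilcox.test(a, b, exact = FALSE)
    list(design = design,
         welch = list(t = unname(wt$statistic), df = unname(wt$parameter),
                      p = wt$p.value),
         mann_whitney = list(U = unname(mw$statistic), p = mw$p.value))
  } else {
    av <- stats::aov(values ~ groups)
    atab <- summary(av)[[1]]
    kw <- stats::kruskal.test(values, groups)
    m <- nlevels(groups) * (nlevels(groups) - 1) / 2
    thr <- bonferroni_alpha(alpha, m)
    pw <- stats::pairwise.wilcox.test(values, groups, p.adjust.method =
                                        "none", exact = FALSE)
    list(design = design,
         anova = list(F = atab$`F value`[1], p = atab$`Pr(>F)`[1]),
         kruskal = list(H = unname(kw$statistic), p = kw$p.value),
         tukey = stats::TukeyHSD(av)$groups,
         pairwise_mw = pw$p.value,
         bonferroni_alpha = thr)
  }
}

#' Compare a fossil ratio value to extant group summaries
#'
#' Runs the single-specimen t-test against each group summary and reports
#' the nearest group by minimum absolute t. Exact ties are broken towards
#' the first group in input order and flagged.
#'
#' @param x fossil ratio value.
#' @param summaries data.frame with columns \code{group}, \code{mean},
#'   \code{variance}, \code{n}.
#' @param alpha significance threshold applied to each comparison (the
#'   design's Bonferroni-adjusted level, e.g. 0.0125 or 0.025).
#' @return list with the per-group \code{tests} table, \code{nearest} and
#'   \code{tie}.
#' @export
fossil_vs_groups <- function(x, summaries, alpha = 0.0125) {
  stopifnot(all(c("group", "mean", "variance", "n") %in% names(summaries)))
  tests <- do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    st <- single_specimen_t(x, summaries$mean[i], summaries$variance[i],
                            summaries$n[i])
    data.frame(group = summaries$group[i], t = st$t, df = st$df, p = st$p,
               significant = st$p < alpha, stringsAsFactors = FALSE)
  }))
  best <- which.min(abs(tests$t))
  tie <- sum(abs(abs(tests$t) - abs(tests$t[best])) < 1e-12) > 1
  list(tests = tests, nearest = tests$group[best], tie = tie,
       alpha = alpha)
}
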