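# Analysis layer: log D from per-phase free energies, deviation summary
# statistics, significance-filtered sign accuracy, and BEDROC
# chemical-group diagnostics with bootstrap uncertainties.

.logd_denom <- function(temperature) 2.3 * .const$R_J * temperature / 1000

#' Distribution coefficient from solvation free energies
#'
#' log D is approximated by the partition coefficient of the neutral
#' species:
#' log D = (Delta G_solv(water) - Delta G_solv(cyclohexane)) / (2.3 R T),
#' with R = 8.314 J/mol/K and the literal factor 2.3.  Antisymmetric
#' under swapping the two phases.
#'
#' @param dg_water,dg_cyclohexane Solvation free energies in kJ/mol
#'   (vectorised).
#' @param temperature Absolute temperature in K.
#' @return log D value(s).
#' @examples
#' log_d(-55.2, -63.8)  # 1.51
#' @export
log_d <- function(dg_water, dg_cyclohexane, temperature = 298) {
  (dg_water - dg_cyclohexane) / .logd_denom(temperature)
}

#' Propagated standard error of log D
#'
#' Quadrature sum of the two independent per-phase standard errors,
#' divided by the same 2.3 R T denominator.
#'
#' @param se_water,se_cyclohexane Per-phase standard errors in kJ/mol.
#' @param temperature Absolute temperature in K.
#' @return Standard error(s) of log D.
#' @export
propagate_se <- function(se_water, se_cyclohexane, temperature = 298) {
  stopifnot(all(se_water >= 0), all(se_cyclohexane >= 0))
  sqrt(se_water^2 + se_cyclohexane^2) / .logd_denom(temperature)
}

#' Deviation summary statistics
#'
#' Mean absolute deviation, mean signed deviation (mean of pred - exp),
#' root-mean-squared deviation and Pearson's correlation coefficient.
#' With zero variance on either side R is undefined and reported as an
#' explicit error state (the `r` field is `NA` and `r_state` explains),
#' never silently 1.
#'
#' @param pred,exp Equal-length numeric vectors (length >= 2).
#' @return List with `mad`, `msd`, `rmsd`, `r`, `r_state`.
#' @export
summary_metrics <- function(pred, exp) {
  stopifnot(length(pred) == length(exp), length(pred) >= 2)
  dev <- pred - exp
  r_state <- "ok"
  r <- NA_real_
  if (var(pred) == 0 || var(exp) == 0) {
    r_state <- "undefined: zero variance"
  } else {
    r <- cor(pred, exp)
  }
  list(mad = mean(abs(dev)), msd = mean(dev), rmsd = sqrt(mean(dev^2)),
       r = r, r_state = r_state)
}

#' Percentage of correctly predicted signs
#'
#' A pair counts as correct when sign(pred) == sign(exp); an exact zero
#' on one side only is a mismatch (both zero matches).
#'
#' @param pred,exp Numeric vectors.
#' @return Percentage in `[0, 100]`.
#' @export
sign_accuracy <- function(pred, exp) {
  stopifnot(length(pred) == length(exp), length(pred) >= 1)
  100 * mean(sign(pred) == sign(exp))
}

#' Sign accuracy restricted to significant values
#'
#' Excludes records where either the prediction or the experiment is not
#' significantly different from zero at the given confidence, judged by
#' |value| / uncertainty against the normal quantile.  The default
#' one-sided variant uses the 95 % one-sided critical value (1.645); the
#' two-sided variant uses 1.96.  An empty remainder is an explicit
#' undefined result (`NA` with attribute `n_used = 0`).
#'
#' @param records A prediction table ([read_prediction_table()]) or data
#'   frame with columns `logd_pred`, `se_pred`, `logd_exp`, `err_exp`.
#' @param confidence Confidence level of the significance test.
#' @param alternative `"one.sided"` or `"two.sided"` test variant.
#' @return Percentage with attributes `n_used` and `excluded`
#'   (compound ids if present).
#' @export
sign_accuracy_filtered <- function(records, confidence = 0.95,
                                   alternative = c("one.sided",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  crit <- if (alternative == "one.sided") qnorm(confidence)
          else qnorm((1 + confidence) / 2)
  tp <- ifelse(records$se_pred > 0, abs(records$logd_pred) / records$se_pred,
               ifelse(records$logd_pred != 0, Inf, 0))
  te <- ifelse(records$err_exp > 0, abs(records$logd_exp) / records$err_exp,
               ifelse(records$logd_exp != 0, Inf, 0))
  keep <- tp > crit & te > crit
  ids <- if (!is.null(records$compound_id)) records$compound_id
         else seq_len(nrow(records))
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "n_used") <- 0L
    attr(out, "excluded") <- ids
    return(out)
  }
  out <- sign_accuracy(records$logd_pred[keep], records$logd_exp[keep])
  attr(out, "n_used") <- sum(keep)
  attr(out, "excluded") <- ids[!keep]
  out
}

#' Largest and second-largest absolute deviations
#'
#' Ties are broken by first occurrence in input order.
#'
#' @param pred,exp Numeric vectors.
#' @param ids Identifiers (defaults to indices).
#' @return List with `max`, `max_id`, `second`, `second_id`.
#' @export
deviation_extremes <- function(pred, exp, ids = seq_along(pred)) {
  stopifnot(length(pred) == length(exp), length(pred) >= 2)
  dev <- abs(pred - exp)
  o <- order(-dev)  # stable: earlier index wins ties
  list(max = dev[o[1]], max_id = ids[o[1]],
       second = dev[o[2]], second_id = ids[o[2]])
}

# BEDROC from the ranks of the members among N ranked items
.bedroc_from_ranks <- function(ranks, n_total, alpha) {
  n <- length(ranks)
  N <- n_total
  Ra <- n / N
  s <- sum(exp(-alpha * ranks / N))
  rie <- (s / n) / ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of ROC: items are ranked by `scores`
#' in decreasing order (highest score = rank 1, "worst first" when
#' scoring by absolute deviation) and the members' ranks are summed with
#' exponential weights exp(-alpha rank / N), normalised to `[0, 1]`.
#' Invariant under strictly monotone transformations of the scores; ties
#' are broken by first occurrence in input order.
#'
#' @param scores Ranking statistic per item (e.g. absolute deviation).
#' @param membership Logical vector: does the item carry the group label?
#' @param alpha Early-recognition parameter (> 0); 20 by default, the
#'   conventional early-recognition setting.
#' @return BEDROC value in `[0, 1]`.
#' @export
bedroc <- function(scores, membership, alpha = 20) {
  stopifnot(length(scores) == length(membership), alpha > 0)
  membership <- as.logical(membership)
  if (all(membership) || !any(membership))
    stop("BEDROC needs at least one member and one non-member")
  o <- order(-scores)
  ranks <- match(which(membership), o)
  .bedroc_from_ranks(ranks, length(scores), alpha)
}

#' Expected BEDROC under a uniform (random) ranking
#'
#' Monte-Carlo average of the BEDROC metric over seeded random
#' placements of the members among N ranks.
#'
#' @param n_members Number of members (1 <= n_members < N).
#' @param n_total Total number of ranked items N.
#' @param alpha Early-recognition parameter.
#' @param n_mc Number of Monte-Carlo permutations.
#' @param seed RNG seed.
#' @return List with `value` (MC mean) and `se` (MC standard error).
#' @export
uniform_bedroc <- function(n_members, n_total, alpha = 20, n_mc = 2000,
                           seed = 1) {
  stopifnot(n_members >= 1, n_members < n_total)
  set.seed(seed)
  vals <- vapply(seq_len(n_mc), function(i)
    .bedroc_from_ranks(sample.int(n_total, n_members), n_total, alpha), 0)
  list(value = mean(vals), se = sd(vals) / sqrt(n_mc))
}

#' Bootstrap standard error of a statistic
#'
#' Resamples the records with replacement `n_boot` times, recomputes the
#' statistic, and reports the standard deviation across iterations.
#' Iterations where the statistic is undefined (e.g. a resample without
#' both members and non-members) are dropped.
#'
#' @param statistic Function taking a resampled data frame (or vector)
#'   and returning a scalar.
#' @param records Data frame (resampled by row) or vector.
#' @param n_boot Number of bootstrap iterations.
#' @param seed RNG seed (deterministic results under a fixed seed).
#' @return Standard error (scalar), with attribute `n_effective`.
#' @export
bootstrap_se <- function(statistic, records, n_boot = 500, seed = 1) {
  set.seed(seed)
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- if (is.data.frame(records)) records[idx, , drop = FALSE]
           else records[idx]
    tryCatch(as.numeric(statistic(sub)), error = function(e) NA_real_)
  }, 0)
  vals <- vals[is.finite(vals)]
  out <- if (length(vals) > 1) sd(vals) else NA_real_
  attr(out, "n_effective") <- length(vals)
  out
}

#' t-test of a group's absolute deviations against the population
#'
#' Two-sided Student's t-test of the group's absolute deviations against
#' the entire population of absolute deviations (group included), with
#' pooled variance by default; a Welch variant is available.
#'
#' @param group_absdevs Absolute deviations of the group members.
#' @param all_absdevs Absolute deviations of the whole population.
#' @param variant `"pooled"` (classic two-sample) or `"welch"`.
#' @return Two-sided p-value.
#' @export
group_ttest <- function(group_absdevs, all_absdevs,
                        variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  t.test(group_absdevs, all_absdevs,
         var.equal = (variant == "pooled"))$p.value
}

#' Chemical-group diagnostics report
#'
#' For every group label with at least `min_members` members, computes
#' the observed BEDROC of the group when compounds are ranked worst-first
#' by absolute deviation, its bootstrap standard error, the expected
#' BEDROC under a uniform ranking, the t-test p-value of the group's
#' absolute deviations against the whole population, and the group's
#' mean signed deviation.
#'
#' @param records Prediction table with columns `logd_pred`, `logd_exp`
#'   and `groups` (semicolon-separated labels per compound).
#' @param alpha BEDROC early-recognition parameter (logged in the output).
#' @param n_boot Bootstrap iterations for the BEDROC uncertainty.
#' @param seed RNG seed.
#' @param min_members Smallest group size reported.
#' @param n_mc Monte-Carlo iterations for the uniform baseline.
#' @return Data frame with one row per group: `group`, `n`, `uniform`,
#'   `observed`, `observed_se`, `p_value`, `msd`; attribute `alpha`.
#' @export
group_report <- function(records, alpha = 20, n_boot = 500, seed = 1,
                         min_members = 5, n_mc = 2000) {
  stopifnot(!is.null(records$groups))
  labels <- strsplit(ifelse(is.na(records$groups), "", records$groups), ";")
  labels <- lapply(labels, trimws)
  all_labels <- sort(unique(unlist(labels)))
  all_labels <- all_labels[all_labels != ""]
  absdev <- abs(records$logd_pred - records$logd_exp)
  sgndev <- records$logd_pred - records$logd_exp
  N <- nrow(records)
  rows <- list()
  for (g in all_labels) {
    member <- vapply(labels, function(l) g %in% l, TRUE)
    n <- sum(member)
    if (n < min_members || n == N) next
    obs <- bedroc(absdev, member, alpha)
    se <- bootstrap_se(function(sub)
      bedroc(abs(sub$logd_pred - sub$logd_exp),
             vapply(strsplit(ifelse(is.na(sub$groups), "", sub$groups), ";"),
                    function(l) g %in% trimws(l), TRUE),
             alpha),
      records, n_boot = n_boot, seed = seed)
    unif <- uniform_bedroc(n, N, alpha, n_mc = n_mc, seed = seed)
    p <- group_ttest(absdev[member], absdev)
    rows[[g]] <- data.frame(group = g, n = n, uniform = unif$value,
                            observed = obs, observed_se = as.numeric(se),
                            p_value = p, msd = mean(sgndev[member]),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), n = integer(), uniform = numeric(),
               observed = numeric(), observed_se = numeric(),
               p_value = numeric(), msd = numeric())
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
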