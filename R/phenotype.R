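# Growth/yield phenotype statistics: per-trait effect size,
# assumption-guided test selection (two-sample t vs
# Mann-Whitney-Wilcoxon), Benjamini-Hochberg correction across traits
# within each biological replicate, and significance-star assignment on
# the replicate-averaged adjusted p.

#' Inoculation effect on a trait, in percent
#'
#' `100 * (mean_treated - mean_control) / mean_control`.
#'
#' @param mean_treated,mean_control group means (`mean_control` non-zero).
#' @return percent effect (vectorised).
#' @export
si_effect <- function(mean_treated, mean_control) {
  if (any(mean_control == 0)) {
    stop("control mean of zero: effect undefined", call. = FALSE)
  }
  100 * (mean_treated - mean_control) / mean_control
}

#' Choose and run the two-group test for one trait repetition
#'
#' Shapiro-Wilk normality checks on both groups and an F-ratio variance
#' check, all at `alpha_assumption`, route the comparison: both groups
#' normal with homogeneous variances gives a pooled two-sample t test;
#' normal with heterogeneous variances gives Welch's t; anything else
#' gives the two-sided Mann-Whitney-Wilcoxon test (exact for group sizes
#' of 8 or fewer, where ties permit). Constant (zero-variance) groups
#' fail the normality gate.
#'
#' @param control,treated numeric vectors (each of length at least 3).
#' @param alpha_assumption significance level for the assumption checks.
#' @return list with `test_used` (`"t"` or `"mww"`), `variant`
#'   (`"pooled"`, `"welch"` or `"exact"`/`"approx"`), and `p_value`.
#' @export
choose_and_run_test <- function(control, treated, alpha_assumption = 0.05) {
  if (length(control) < 3L || length(treated) < 3L) {
    stop("each group needs at least 3 values for normality checking",
         call. = FALSE)
  }
  is_normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha_assumption
  }
  if (is_normal(control) && is_normal(treated)) {
    homo <- stats::var.test(control, treated)$p.value > alpha_assumption
    fit <- stats::t.test(treated, control, var.equal = homo)
    return(list(test_used = "t",
                variant = if (homo) "pooled" else "welch",
                p_value = fit$p.value))
  }
  if (stats::sd(c(control, treated)) == 0) {
    # fully degenerate data: no evidence of any difference
    return(list(test_used = "mww", variant = "degenerate", p_value = 1))
  }
  exact <- length(control) <= 8L && length(treated) <= 8L
  fit <- suppressWarnings(
    stats::wilcox.test(treated, control, exact = exact, correct = TRUE))
  list(test_used = "mww",
       variant = if (exact) "exact" else "approx",
       p_value = fit$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate correction with monotonicity
#' enforcement; output order matches input order.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return adjusted p values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values outside [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Significance stars for an (averaged) adjusted p value
#'
#' `***` for p <= 0.0001, `**` for p <= 0.001, `*` for p <= 0.05,
#' otherwise `ns`. Averaging over experiment repetitions happens before
#' assignment.
#'
#' @param p adjusted p value(s) in \[0, 1\].
#' @return character vector of star labels.
#' @export
assign_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values outside [0, 1]", call. = FALSE)
  }
  ifelse(p <= 0.0001, "***",
    ifelse(p <= 0.001, "**",
      ifelse(p <= 0.05, "*", "ns")))
}

#' Full phenotype analysis of a replicated two-group trait table
#'
#' For every biological replicate, each trait is tested with
#' [choose_and_run_test()] and the resulting p values are
#' Benjamini-Hochberg corrected across the traits of that replicate (the
#' correction family). Adjusted p values are then averaged over
#' replicates per trait, stars assigned to the average, and the percent
#' effect computed from the pooled group means.
#'
#' @param traits data frame with columns `trait`, `group` (two levels,
#'   one named `control_label`), `replicate`, `value`.
#' @param alpha_assumption significance level for assumption checks.
#' @param control_label name of the control group.
#' @return data frame with one row per trait: `trait`, `mean_control`,
#'   `mean_treated`, `si_effect_percent`, `test_used`,
#'   `mean_adjusted_p`, `stars`; the per-replicate detail table is
#'   attached as attribute `"per_replicate"`.
#' @export
phenotype_stats <- function(traits, alpha_assumption = 0.05,
                            control_label = "control") {
  need <- c("trait", "group", "replicate", "value")
  stopifnot(all(need %in% names(traits)))
  groups <- unique(traits$group)
  if (length(groups) != 2L || !(control_label %in% groups)) {
    stop("trait table must have exactly two groups, one named '",
         control_label, "'", call. = FALSE)
  }
  treated_label <- setdiff(groups, control_label)

  detail <- list()
  for (rep_id in unique(traits$replicate)) {
    tr <- traits[traits$replicate == rep_id, , drop = FALSE]
    trait_ids <- unique(tr$trait)
    res <- lapply(trait_ids, function(tn) {
      tt <- tr[tr$trait == tn, , drop = FALSE]
      choose_and_run_test(tt$value[tt$group == control_label],
                          tt$value[tt$group == treated_label],
                          alpha_assumption)
    })
    detail[[length(detail) + 1L]] <- data.frame(
      trait = trait_ids, replicate = rep_id,
      test_used = vapply(res, `[[`, character(1), "test_used"),
      variant = vapply(res, `[[`, character(1), "variant"),
      p_value = vapply(res, `[[`, numeric(1), "p_value"),
      adjusted_p = bh_adjust(vapply(res, `[[`, numeric(1), "p_value")))
  }
  detail <- do.call(rbind, detail)

  out <- lapply(unique(traits$trait), function(tn) {
    tt <- traits[traits$trait == tn, , drop = FALSE]
    d <- detail[detail$trait == tn, , drop = FALSE]
    mc <- mean(tt$value[tt$group == control_label])
    mt <- mean(tt$value[tt$group == treated_label])
    mean_adj <- mean(d$adjusted_p)
    data.frame(trait = tn, mean_control = mc, mean_treated = mt,
               si_effect_percent = si_effect(mt, mc),
               test_used = paste(sort(unique(d$test_used)), collapse = "+"),
               mean_adjusted_p = mean_adj, stars = assign_stars(mean_adj))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "per_replicate") <- detail
  out
}
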