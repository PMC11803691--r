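#' Default analysis plan
#'
#' Metrics that correlate with gestational age (T2* of both organs, volume)
#' are compared between groups by ANCOVA with GA as covariate; the shape and
#' texture metrics, which show no GA trend, by plain ANOVA. FDR correction
#' is applied within each named family.
#'
#' @param alpha Significance level (default 0.05).
#' @return Plan list consumed by [run_statistics()].
#' @export
stats_plan <- function(alpha = 0.05) {
  list(
    covariate = "ga_weeks",
    adjusted_metrics = c("brain_t2", "placenta_t2", "volume_mm3"),
    anova_metrics = c("texture", "thickness_mm", "morphology"),
    correlation_metrics = c("placenta_t2", "brain_t2", "volume_mm3",
                            "texture", "thickness_mm", "morphology"),
    fdr_families = list(
      group_comparisons = TRUE,
      partial_correlations = TRUE
    ),
    alpha = alpha
  )
}

subset_rows <- function(table, subset) {
  if (subset == "all") table else table[table$group == subset, , drop = FALSE]
}

#' Run the full cohort statistics stage
#'
#' Reproduces the analysis plan of the pipeline on a cohort table:
#' demographic comparisons (Mann-Whitney on GA and maternal age), per-metric
#' GA correlations for the pooled cohort and each group, GA-adjusted
#' (ANCOVA) or plain (ANOVA) between-group comparisons with estimated
#' marginal means, the brain-placenta and texture-T2* partial Spearman
#' panels with group-interaction tests, and Benjamini-Hochberg FDR within
#' each configured family.
#'
#' @param table Cohort data.frame (see [subject_record()]).
#' @param plan Analysis plan from [stats_plan()].
#' @return List of data.frames: `demographics`, `ga_correlations`,
#'   `group_comparisons`, `partial_correlations`, `group_summaries`, plus
#'   `meta` (plan echo, group sizes, notes). Group comparisons are skipped
#'   with a notice when a group has fewer than 2 subjects.
#' @export
run_statistics <- function(table, plan = stats_plan()) {
  validate_cohort(table)
  notes <- character()
  counts <- table(factor(table$group, levels = c("control", "CHD")))
  has_groups <- all(counts >= 2)
  cov <- plan$covariate

  ## demographics
  demographics <- NULL
  if (has_groups) {
    ctrl <- table[table$group == "control", ]
    chd <- table[table$group == "CHD", ]
    demo <- lapply(c("ga_weeks", "maternal_age_years"), function(v) {
      mw <- mann_whitney(ctrl[[v]], chd[[v]])
      data.frame(variable = v, method = mw$method, statistic = mw$estimate,
                 p_value = mw$p_value, n = mw$n)
    })
    demographics <- do.call(rbind, demo)
  } else {
    notes <- c(notes, "single-group cohort: demographic and group comparisons skipped")
  }

  ## GA correlations, pooled and per group
  subsets <- c("all", "control", "CHD")
  ga_rows <- list()
  for (m in plan$correlation_metrics) {
    for (s in subsets) {
      sub <- subset_rows(table, s)
      if (nrow(sub) >= 4) {
        r <- tryCatch(spearman(sub[[m]], sub[[cov]]),
                      error = function(e) NULL)
        if (!is.null(r)) {
          ga_rows[[length(ga_rows) + 1]] <- data.frame(
            metric = m, subset = s, rho = r$estimate, p_value = r$p_value,
            n = r$n)
        }
      }
    }
  }
  ga_correlations <- do.call(rbind, ga_rows)

  ## between-group comparisons
  group_comparisons <- NULL
  if (has_groups) {
    rows <- list()
    for (m in plan$adjusted_metrics) {
      a <- ancova_group(table, m, cov)
      rows[[m]] <- data.frame(
        metric = m, method = "ancova", estimate = a$stat$estimate,
        p_value = a$stat$p_value, n = a$stat$n,
        emm_control = a$emm$group_means["control"],
        emm_chd = a$emm$group_means["CHD"],
        emm_diff_se = a$emm$diff_se, covariate_at = a$emm$covariate_at)
    }
    for (m in plan$anova_metrics) {
      a <- anova_group(table, m)
      rows[[m]] <- data.frame(
        metric = m, method = "anova", estimate = a$estimate,
        p_value = a$p_value, n = a$n,
        emm_control = NA_real_, emm_chd = NA_real_,
        emm_diff_se = NA_real_, covariate_at = NA_real_)
    }
    group_comparisons <- do.call(rbind, rows)
    rownames(group_comparisons) <- NULL
    if (isTRUE(plan$fdr_families$group_comparisons)) {
      group_comparisons$p_fdr <- bh_fdr(group_comparisons$p_value)
    }
  }

  ## partial-correlation panels (GA-adjusted) + interaction tests
  panels <- list(
    brain_vs_placenta = c(y = "brain_t2", x = "placenta_t2"),
    texture_vs_placenta_t2 = c(y = "texture", x = "placenta_t2")
  )
  pc_rows <- list()
  for (pn in names(panels)) {
    y <- panels[[pn]][["y"]]; x <- panels[[pn]][["x"]]
    for (s in subsets) {
      sub <- subset_rows(table, s)
      if (nrow(sub) >= 5) {
        r <- partial_spearman(sub[[x]], sub[[y]], sub[[cov]])
        pc_rows[[length(pc_rows) + 1]] <- data.frame(
          panel = pn, subset = s, test = "partial_spearman",
          estimate = r$estimate, p_value = r$p_value, n = r$n)
      }
    }
    if (has_groups) {
      it <- interaction_test(table, y, x)
      pc_rows[[length(pc_rows) + 1]] <- data.frame(
        panel = pn, subset = "all", test = "interaction",
        estimate = it$estimate, p_value = it$p_value, n = it$n)
    }
  }
  partial_correlations <- do.call(rbind, pc_rows)
  if (isTRUE(plan$fdr_families$partial_correlations)) {
    ps <- partial_correlations$test == "partial_spearman"
    partial_correlations$p_fdr <- NA_real_
    partial_correlations$p_fdr[ps] <-
      bh_fdr(partial_correlations$p_value[ps])
  }

  ## per-group descriptive summaries with Shapiro-Wilk gatekeeping
  sum_rows <- list()
  metrics_all <- unique(c(plan$adjusted_metrics, plan$anova_metrics))
  for (m in metrics_all) {
    for (g in c("control", "CHD")) {
      v <- table[[m]][table$group == g]
      v <- v[is.finite(v)]
      if (!length(v)) next
      style <- shapiro_gate(v, plan$alpha)
      if (style == "parametric") {
        center <- mean(v); lo <- sd(v); hi <- NA_real_
      } else {
        qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        center <- qs[2]; lo <- qs[1]; hi <- qs[3]
      }
      sum_rows[[length(sum_rows) + 1]] <- data.frame(
        metric = m, group = g, style = style, center = center,
        spread_lo = lo, spread_hi = hi, n = length(v))
    }
  }
  group_summaries <- do.call(rbind, sum_rows)

  list(
    demographics = demographics,
    ga_correlations = ga_correlations,
    group_comparisons = group_comparisons,
    partial_correlations = partial_correlations,
    group_summaries = group_summaries,
    meta = list(plan = plan, n_control = unname(counts["control"]),
                n_chd = unname(counts["CHD"]), notes = notes)
  )
}

#' Write a statistics report to JSON and CSV tables
#'
#' @param report Output of [run_statistics()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `stats_report.json` plus one CSV per
#'   table.
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  for (nm in c("demographics", "ga_correlations", "group_comparisons",
               "partial_correlations", "group_summaries")) {
    if (!is.null(report[[nm]])) {
      write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(dir)
}
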