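#' Per-group Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test within each group of a per-cell metric before
#' any parametric comparison. The pipeline proceeds parametric when every
#' group passes (p > alpha); otherwise a warning is raised (the comparisons
#' still run, the gate never silently switches tests).
#'
#' @param records data.frame of per-cell records.
#' @param metric name of the metric column.
#' @param group name of the grouping column (default `"line"`).
#' @param alpha gate level (default 0.05).
#' @return data.frame with one row per group: `group`, `n`, `W`, `p_value`,
#'   `normal`; attribute `all_normal`.
#' @export
normality_gate <- function(records, metric, group = "line", alpha = 0.05) {
  check_columns(records, c(metric, group))
  sp <- split(records[[metric]], records[[group]])
  rows <- lapply(names(sp), function(g) {
    x <- sp[[g]][is.finite(sp[[g]])]
    if (length(x) < 3)
      stop("group `", g, "` has fewer than 3 values; Shapiro-Wilk undefined")
    if (stats::sd(x) == 0)
      stop("group `", g, "` is degenerate (identical values); ",
           "Shapiro-Wilk undefined")
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), W = unname(sw$statistic),
               p_value = sw$p.value, normal = sw$p.value > alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_normal") <- all(out$normal)
  if (!all(out$normal))
    warning("normality gate failed for group(s): ",
            paste(out$group[!out$normal], collapse = ", "),
            "; parametric comparisons may be unreliable")
  out
}

#' Group comparison: ANOVA omnibus plus Tukey pairwise tests
#'
#' One-way (`metric ~ line`) or two-way (`metric ~ line * condition`)
#' analysis of variance followed by Tukey honest-significant-difference
#' pairwise comparisons on the line factor. Significance of each pairwise
#' comparison is declared against a Bonferroni-adjusted alpha,
#' 0.05 / (number of pairwise comparisons) — a deliberately conservative
#' double control (Tukey-adjusted p-values compared to a Bonferroni
#' threshold) matching how the original workflow captions its figures.
#' The comparison family size defaults to the number of line pairs but can
#' be set explicitly via `family_size` (it is never inferred from anything
#' else).
#'
#' @param records per-cell data.frame.
#' @param metric metric column name.
#' @param design `"one_way"` or `"two_way"`.
#' @param line grouping column (default `"line"`).
#' @param condition second factor for the two-way design
#'   (default `"condition"`).
#' @param alpha base significance level (default 0.05).
#' @param family_size number of comparisons the Bonferroni adjustment
#'   divides alpha by; default `choose(k, 2)` for `k` lines.
#' @return An object of class `comparison_report`: list with `metric`,
#'   `design`, `anova` (data.frame of omnibus terms), `pairwise`
#'   (data.frame: comparison, diff, p_adj, significant), `adjusted_alpha`.
#' @export
compare_groups <- function(records, metric, design = c("one_way", "two_way"),
                           line = "line", condition = "condition",
                           alpha = 0.05, family_size = NULL) {
  design <- match.arg(design)
  need <- c(metric, line, if (design == "two_way") condition)
  check_columns(records, need)
  d <- records[stats::complete.cases(records[, need, drop = FALSE]), ,
               drop = FALSE]
  d$.line <- factor(d[[line]])
  k <- nlevels(d$.line)
  if (k < 2) stop("need at least 2 groups to compare")
  tab <- table(d$.line)
  if (any(tab < 2))
    stop("group(s) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (design == "two_way") {
    d$.cond <- factor(d[[condition]])
    cells <- table(d$.line, d$.cond)
    if (any(cells == 0))
      stop("two-way design has empty line x condition cells; ",
           "cannot estimate the interaction")
    fit <- stats::aov(d[[metric]] ~ .line * .cond, data = d)
  } else {
    fit <- stats::aov(d[[metric]] ~ .line, data = d)
  }
  an <- summary(fit)[[1]]
  anova_df <- data.frame(term = trimws(rownames(an)), df = an$Df,
                         statistic = an$`F value`, p_value = an$`Pr(>F)`,
                         stringsAsFactors = FALSE)
  if (is.null(family_size)) family_size <- choose(k, 2)
  adj_alpha <- alpha / family_size
  tk <- stats::TukeyHSD(fit, which = ".line")$.line
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < adj_alpha,
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  structure(list(metric = metric, design = design, anova = anova_df,
                 pairwise = pairwise, adjusted_alpha = adj_alpha,
                 n_groups = k, family_size = family_size),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%s), %d groups\n",
              x$metric, x$design, x$n_groups))
  cat(sprintf("  adjusted alpha = %.4g (0.05 / %d comparisons)\n",
              x$adjusted_alpha, x$family_size))
  print(x$anova, row.names = FALSE)
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  cat(sprintf("  %d / %d pairwise comparisons significant\n",
              nrow(sig), nrow(x$pairwise)))
  invisible(x)
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' alpha / C(k, 2) for all pairwise comparisons among k groups (0.005 for
#' five groups), or alpha / family_size for an explicit comparison family.
#'
#' @param k number of groups (ignored when `family_size` given).
#' @param alpha base level (default 0.05).
#' @param family_size explicit number of comparisons.
#' @return The adjusted per-comparison alpha.
#' @export
adjusted_alpha <- function(k, alpha = 0.05, family_size = NULL) {
  if (is.null(family_size)) {
    stopifnot(k >= 2)
    family_size <- choose(k, 2)
  }
  alpha / family_size
}

#' Before/after-stress comparison within a line
#'
#' Unpaired two-sided Student's t-test (equal variances) between the two
#' conditions of one cell line, at alpha 0.05.
#'
#' @param records per-cell data.frame.
#' @param metric metric column name.
#' @param line_value which line to test.
#' @param line,condition column names.
#' @param conditions the two condition labels compared
#'   (default `c("normal", "H2O2")`).
#' @param alpha significance level.
#' @return One-row data.frame: `line`, `metric`, `statistic`, `df`,
#'   `p_value`, `significant`, `mean_a`, `mean_b`.
#' @export
paired_condition_test <- function(records, metric, line_value,
                                  line = "line", condition = "condition",
                                  conditions = c("normal", "H2O2"),
                                  alpha = 0.05) {
  check_columns(records, c(metric, line, condition))
  d <- records[records[[line]] == line_value, , drop = FALSE]
  a <- d[[metric]][d[[condition]] == conditions[1]]
  b <- d[[metric]][d[[condition]] == conditions[2]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop(sprintf("line `%s` lacks condition `%s` (n=%d) or `%s` (n=%d)",
                 line_value, conditions[1], length(a), conditions[2],
                 length(b)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  data.frame(line = line_value, metric = metric,
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, significant = tt$p.value < alpha,
             mean_a = mean(a), mean_b = mean(b), stringsAsFactors = FALSE)
}

#' ANCOVA with donor age and sex as covariates
#'
#' Linear model `metric ~ line + age + sex`, with the age x sex interaction
#' fitted and reported in a second model. With one donor per line, age and
#' sex are perfectly confounded with the line factor; this is detected
#' (aliased coefficients) and reported with a warning — the covariate
#' effects are then not identifiable and their rows are `NA`.
#'
#' @param records per-cell data.frame with `age` and `sex` columns.
#' @param metric metric column name.
#' @param line line column name.
#' @return An object of class `ancova_report`: list with `terms`
#'   (data.frame: term, df, statistic, p_value), `interaction_p` (p-value of
#'   age:sex), `confounded` flag, and the fitted `model`.
#' @export
ancova_covariates <- function(records, metric, line = "line") {
  check_columns(records, c(metric, line, "age", "sex"))
  if (anyNA(records$age) || anyNA(records$sex))
    stop("age and sex must be present for every record")
  d <- data.frame(y = records[[metric]], line = factor(records[[line]]),
                  age = as.numeric(records$age), sex = factor(records$sex))
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(y ~ line + age + sex, data = d)
  confounded <- anyNA(stats::coef(fit))
  if (confounded)
    warning("age/sex are confounded with the line factor (rank-deficient ",
            "design, e.g. one donor per line); covariate effects are not ",
            "identifiable")
  an <- stats::anova(fit)
  terms_df <- data.frame(term = rownames(an), df = an$Df,
                         statistic = an$`F value`, p_value = an$`Pr(>F)`,
                         stringsAsFactors = FALSE)
  interaction_p <- NA_real_
  if (!confounded && nlevels(d$sex) > 1) {
    fit2 <- stats::lm(y ~ line + age * sex, data = d)
    an2 <- stats::anova(fit2)
    if ("age:sex" %in% rownames(an2))
      interaction_p <- an2["age:sex", "Pr(>F)"]
  }
  structure(list(metric = metric, terms = terms_df,
                 interaction_p = interaction_p, confounded = confounded,
                 model = fit),
            class = "ancova_report")
}

#' @export
print.ancova_report <- function(x, ...) {
  cat(sprintf("<ancova_report> %s ~ line + age + sex%s\n", x$metric,
              if (x$confounded) "  [CONFOUNDED: one donor per line]" else ""))
  print(x$terms, row.names = FALSE)
  if (!is.na(x$interaction_p))
    cat(sprintf("  age:sex interaction p = %.3g\n", x$interaction_p))
  invisible(x)
}

#' Fold changes of group means against a reference group
#'
#' mean(group) / mean(reference), rounded half-up to `decimals` decimal
#' places (so 2.05 reports as 2.1 at one decimal).
#'
#' @param means named numeric vector of group means, or a data.frame with
#'   `group` and `mean` columns.
#' @param reference name of the reference group (its mean must be > 0).
#' @param decimals decimals for half-up rounding (default 1).
#' @return data.frame: `group`, `mean`, `fold_change`.
#' @export
fold_change <- function(means, reference, decimals = 1) {
  if (is.data.frame(means)) {
    check_columns(means, c("group", "mean"))
    v <- stats::setNames(means$mean, means$group)
  } else {
    v <- means
  }
  if (is.null(names(v)) || !reference %in% names(v))
    stop("`means` must be named and contain the reference group `",
         reference, "`")
  ref <- v[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf("reference mean must be positive (got %.4g)", ref))
  data.frame(group = names(v), mean = unname(v),
             fold_change = round_half_up(unname(v) / ref, decimals),
             stringsAsFactors = FALSE)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

check_columns <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
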