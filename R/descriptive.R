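#' Counts and percentage shares of a categorical variable
#'
#' @param data A data frame.
#' @param var Column name (string) of the categorical variable.
#' @param by Optional grouping column name.
#' @param drop_na Drop missing values before computing shares?
#' @return Tibble with `level`, `n`, `pct` (percent of non-missing rows,
#'   unrounded), optionally per `by` group.
#' @examples
#' tab_shares(data.frame(x = rep(c("yes", "no"), c(175, 40))), "x")
#' @export
tab_shares <- function(data, var, by = NULL, drop_na = TRUE) {
  require_columns(data, c(var, by), "data")
  x <- data
  if (drop_na) x <- x[!is.na(x[[var]]), , drop = FALSE]
  grouping <- c(by, var)
  out <- x |>
    dplyr::count(dplyr::across(dplyr::all_of(grouping)), name = "n")
  if (!is.null(by)) {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  } else {
    out$pct <- 100 * out$n / sum(out$n)
  }
  names(out)[names(out) == var] <- "level"
  out
}

#' Dunn's rank-based post-hoc test
#'
#' All pairwise comparisons following a Kruskal--Wallis test, using the
#' standard large-sample z statistic on mean ranks with tie correction.
#'
#' @param value Numeric vector.
#' @param group Grouping vector (>= 2 levels).
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`; use `"none"` for raw p-values).
#' @return Tibble with `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_test <- function(value, group, p_adjust = "holm") {
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]
  group <- factor(group[ok])
  if (nlevels(group) < 2) stop_contract("dunn_test needs >= 2 groups")
  n <- length(value)
  r <- rank(value)
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  levs <- levels(group)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
    (mean_rank[p[1]] - mean_rank[p[2]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = unname(z), p_raw = unname(p_raw),
    p_adjusted = p.adjust(p_raw, method = p_adjust)
  )
}

#' Dunnett's many-to-one comparisons against the control group
#'
#' One-way ANOVA followed by Dunnett contrasts of every subtype against the
#' control group (via `multcomp`).
#'
#' @param value Numeric vector.
#' @param group Grouping vector; must contain `control_level`.
#' @param control_level Reference level (default `"control"`).
#' @return Tibble with `group`, `estimate`, `se`, `statistic`, `p_adjusted`.
#' @export
dunnett_test <- function(value, group, control_level = "control") {
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]
  group <- factor(group[ok])
  if (!control_level %in% levels(group)) {
    stop_contract(sprintf("control level '%s' not present", control_level))
  }
  group <- stats::relevel(group, ref = control_level)
  fit <- aov(value ~ group)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  comp <- sub(sprintf(" - %s$", control_level), "", names(sm$test$coefficients))
  tibble::tibble(
    group = comp,
    estimate = unname(sm$test$coefficients),
    se = unname(sm$test$sigma),
    statistic = unname(sm$test$tstat),
    p_adjusted = unname(as.numeric(sm$test$pvalues))
  )
}

summarise_numeric <- function(x, normal = FALSE) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return("")
  }
  if (normal) {
    sprintf("%.3g ± %.3g", mean(x), sd(x))
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.3g [%.3g, %.3g]", q[2], q[1], q[3])
  }
}

#' Baseline characteristics table with group comparisons
#'
#' Summarises variables by group the way cohort baseline tables are usually
#' presented: median \[Q1, Q3\] for continuous biomarkers (mean ± SD for
#' variables declared normal), n (%) per level for categoricals. Tests:
#' with two groups, Mann--Whitney U (or Student/Welch t for normal
#' variables, by an F-test of equal variances) and chi-square (Fisher's
#' exact when any expected cell count is below 5); with more than two
#' groups, Kruskal--Wallis (Dunn's post-hoc available via [dunn_test()])
#' and, when a control group is present, ANOVA with Dunnett contrasts via
#' [dunnett_test()].
#'
#' @param data A data frame of one row per participant.
#' @param group_col Name of the grouping column.
#' @param vars Variables to summarise (default: all except the group).
#' @param normal_vars Variables summarised/tested under normality.
#' @return Tibble with `variable`, `level`, one formatted column per group,
#'   `test`, `p_value`.
#' @export
descriptive_table <- function(data, group_col = "group", vars = NULL,
                              normal_vars = character()) {
  require_columns(data, group_col, "data")
  g <- factor(data[[group_col]])
  if (is.null(vars)) vars <- setdiff(names(data), group_col)
  two_groups <- nlevels(g) == 2
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      normal <- v %in% normal_vars
      cells <- vapply(levels(g), function(l) {
        summarise_numeric(x[g == l], normal)
      }, character(1))
      p <- tryCatch(
        {
          if (two_groups) {
            if (normal) {
              equal_var <- var.test(x ~ g)$p.value > 0.05
              t.test(x ~ g, var.equal = equal_var)$p.value
            } else {
              wilcox.test(x ~ g, exact = FALSE)$p.value
            }
          } else {
            kruskal.test(x, g)$p.value
          }
        },
        error = function(e) NA_real_
      )
      test <- if (two_groups) {
        if (normal) "t/Welch" else "Mann-Whitney U"
      } else {
        "Kruskal-Wallis"
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = v, level = NA_character_,
        !!!as.list(cells), test = test, p_value = p
      )
    } else {
      tab <- table(g, factor(x))
      p <- tryCatch(
        {
          expected <- chisq.test(tab)$expected
          if (any(expected < 5)) {
            fisher.test(tab, simulate.p.value = TRUE, B = 2000)$p.value
          } else {
            chisq.test(tab)$p.value
          }
        },
        error = function(e) NA_real_
      )
      shares <- tab_shares(
        data.frame(g = g, x = x)[!is.na(x), ], "x",
        by = "g"
      )
      for (lev in colnames(tab)) {
        cells <- vapply(levels(g), function(l) {
          row <- shares[shares$g == l & shares$level == lev, ]
          if (nrow(row) == 0) {
            "0 (0.0%)"
          } else {
            sprintf("%d (%.1f%%)", row$n, row$pct)
          }
        }, character(1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, level = lev,
          !!!as.list(cells),
          test = "chi-square/Fisher",
          p_value = p
        )
        p <- NA_real_ # report the test once per variable
      }
    }
  }
  dplyr::bind_rows(rows)
}
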