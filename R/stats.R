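#' Kernel density evaluated at the data points
#'
#' Gaussian-kernel 2D density for coloring scatter maps (distance versus
#' angle and friends). Because the two axes are incommensurate (nm versus
#' degrees), both are standardized to unit variance before evaluation;
#' densities are reported on that standardized scale, with the bandwidth
#' recorded. Bandwidth defaults to Scott's rule, `n^(-1/6)` on the
#' standardized scale.
#'
#' @param data a data frame.
#' @param x,y column names (strings) of the two axes.
#' @param bandwidth bandwidth override on the standardized scale.
#' @param probe optional data frame of extra points (same columns) at
#'   which to evaluate the density as well; returned in attribute
#'   `"probe_density"`.
#' @return `data` with a `density` column; attributes `"bandwidth"` and
#'   axis scaling parameters.
#' @export
kde_at_points <- function(data, x, y, bandwidth = NULL, probe = NULL) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) < 2) abort("need at least 2 points")
  sx <- sd(xv)
  sy <- sd(yv)
  if (sx == 0 && sy == 0) abort("all points identical: degenerate covariance")
  if (sx == 0 || sy == 0) abort("zero variance on one axis: degenerate covariance")
  xs <- (xv - mean(xv)) / sx
  ys <- (yv - mean(yv)) / sy
  h <- bandwidth %||% length(xv)^(-1 / 6)
  dens <- cpp_kde2d_at(xs, ys, xs, ys, h)
  out <- data
  out$density <- dens
  attr(out, "bandwidth") <- h
  attr(out, "scaling") <- list(x_mean = mean(xv), x_sd = sx,
                               y_mean = mean(yv), y_sd = sy)
  if (!is.null(probe)) {
    ps <- (probe[[x]] - mean(xv)) / sx
    qs <- (probe[[y]] - mean(yv)) / sy
    attr(out, "probe_density") <- cpp_kde2d_at(xs, ys, ps, qs, h)
  }
  out
}

#' Group comparison statistics
#'
#' The statistics wiring used for condition summaries: one-way ANOVA with
#' Tukey's multiple comparisons for three or more groups, or an F-test
#' (variance ratio) plus two-sample t-test for two groups. Group means and
#' standard errors of the mean are always reported alongside.
#'
#' @param data a data frame.
#' @param value,group column names (strings) of the measurement and the
#'   grouping factor.
#' @param design `"anova_tukey"`, `"ttest"`, or `"ftest"`.
#' @return object of class `filarch_comparison` with [generics::tidy()]
#'   and [generics::glance()] methods.
#' @export
group_compare <- function(data, value, group,
                          design = c("anova_tukey", "ttest", "ftest")) {
  design <- match.arg(design)
  v <- data[[value]]
  g <- factor(data[[group]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group(s) with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  k <- nlevels(g)
  if (design == "anova_tukey" && k < 2) abort("anova needs at least 2 groups")
  if (design %in% c("ttest", "ftest") && k != 2) {
    abort(paste0(design, " needs exactly 2 groups"))
  }
  groups <- tibble(
    group = levels(g),
    n = as.integer(sizes),
    mean = as.numeric(tapply(v, g, mean)),
    sem = as.numeric(tapply(v, g, sd) / sqrt(sizes))
  )
  tests <- switch(design,
    anova_tukey = {
      fit <- aov(v ~ g)
      an <- summary(fit)[[1]]
      overall <- tibble(
        comparison = "overall", test = "anova_F",
        statistic = unname(an$`F value`[1]), df1 = an$Df[1], df2 = an$Df[2],
        p_value = unname(an$`Pr(>F)`[1]), p_adjusted = NA_real_
      )
      tk <- TukeyHSD(fit)$g
      pairs <- tibble(
        comparison = rownames(tk), test = "tukey_hsd",
        statistic = unname(tk[, "diff"]), df1 = NA_real_, df2 = NA_real_,
        p_value = NA_real_, p_adjusted = unname(tk[, "p adj"])
      )
      bind_rows(overall, pairs)
    },
    ttest = {
      tt <- t.test(v ~ g, var.equal = TRUE)
      tibble(comparison = paste(levels(g), collapse = " vs "),
             test = "t_test", statistic = unname(tt$statistic),
             df1 = unname(tt$parameter), df2 = NA_real_,
             p_value = tt$p.value, p_adjusted = NA_real_)
    },
    ftest = {
      ft <- var.test(v ~ g)
      tibble(comparison = paste(levels(g), collapse = " vs "),
             test = "F_variance", statistic = unname(ft$statistic),
             df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
             p_value = ft$p.value, p_adjusted = NA_real_)
    }
  )
  structure(list(design = design, tests = tests, groups = groups,
                 value = value, group = group, n_total = length(v)),
            class = "filarch_comparison")
}

#' @export
print.filarch_comparison <- function(x, ...) {
  cat(sprintf("<filarch_comparison (%s) on '%s' by '%s'>\n",
              x$design, x$value, x$group))
  print(x$groups)
  print(x$tests)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the test table of a group comparison
#' @param x a `filarch_comparison`. @param ... unused.
#' @export
tidy.filarch_comparison <- function(x, ...) x$tests

#' One-row summary of a group comparison
#' @param x a `filarch_comparison`. @param ... unused.
#' @export
glance.filarch_comparison <- function(x, ...) {
  tibble(design = x$design, n_groups = nrow(x$groups), n_total = x$n_total,
         p_value = x$tests$p_value[1])
}
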