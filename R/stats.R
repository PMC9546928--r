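#' Group means and standard errors
#'
#' @param values numeric vector.
#' @param group group id per value.
#' @return data frame: group, n, mean, se (`se = sd / sqrt(n)` with the
#'   n - 1 denominator; `NA` for singleton groups rather than zero).
#' @export
summarize_groups <- function(values, group) {
  group <- as.factor(group)
  if (any(tabulate(group) == 0L)) group <- droplevels(group)
  if (!length(values)) stop("no values")
  if (anyNA(values)) stop("missing values in input")
  n <- as.vector(table(group))
  if (any(n < 1)) stop("empty group")
  m <- tapply(values, group, mean)
  s <- tapply(values, group, sd)
  data.frame(group = levels(group), n = n, mean = as.vector(m),
             se = ifelse(n >= 2, as.vector(s) / sqrt(n), NA_real_),
             stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' @param values numeric vector.
#' @param group group id per value (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df1`, `df2`. Zero within-group variance
#'   with unequal means reports the underflow floor rather than exactly 0.
#' @export
anova_oneway <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  # a perfect fit triggers an unreliability warning; that case is handled
  # explicitly below
  a <- suppressWarnings(anova(lm(values ~ group)))
  Fv <- a$`F value`[1]
  p <- a$`Pr(>F)`[1]
  if (!is.finite(Fv) || all(tapply(values, group, var) == 0)) {
    # zero within-group variance: F is 0/0 or dominated by rounding noise
    means <- tapply(values, group, mean)
    if (max(means) - min(means) > 0) {
      Fv <- Inf; p <- .Machine$double.xmin
    } else {
      Fv <- 0; p <- 1
    }
  }
  list(F = Fv, p = max(p, .Machine$double.xmin),
       df1 = a$Df[1], df2 = a$Df[2])
}

# equicorrelation-structured correlation matrix of many-to-one contrasts
dunnett_corr <- function(n_control, n_treat) {
  k <- length(n_treat)
  lam <- sqrt(n_treat / (n_treat + n_control))
  R <- outer(lam, lam)
  diag(R) <- 1
  R
}

#' Critical value of the many-to-one (Dunnett) test
#'
#' Two-sided equicoordinate quantile of the multivariate t distribution of
#' the treatment-vs-control contrasts.
#'
#' @param n_control,n_treat group sizes (`n_treat` one per treatment).
#' @param alpha family-wise error rate.
#' @param df error degrees of freedom (pooled; default from group sizes).
#' @param seed seed for the quantile integration.
#' @return scalar critical value for `max |t|`.
#' @export
dunnett_critical <- function(n_control, n_treat, alpha = 0.05, df = NULL,
                             seed = 1L) {
  R <- dunnett_corr(n_control, n_treat)
  if (is.null(df)) df <- sum(c(n_control, n_treat)) - length(n_treat) - 1L
  set.seed(seed)
  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = R,
                algorithm = mvtnorm::GenzBretz(abseps = 1e-5))$quantile
}

#' Many-to-one Dunnett comparison against a control group
#'
#' Classical equal-variance many-to-one comparisons: pooled-variance t
#' statistics for each treatment group against the shared control, with
#' two-sided family-wise adjustment through the multivariate-t dependence
#' of the contrasts (the procedure used with a p < 0.05 criterion in the
#' reference workflow). Reduces to the pooled two-sample t test when a
#' single treatment group is present.
#'
#' @param values numeric vector.
#' @param group group id per value.
#' @param control control group id.
#' @param alpha significance level for flags.
#' @param seed seed for the multivariate-t integration.
#' @return object of class `dunnett_result`: per-treatment data frame
#'   (mean difference, t, unadjusted and adjusted p, significance flag),
#'   plus the one-way ANOVA F and p.
#' @export
dunnett_many_to_one <- function(values, group, control, alpha = 0.05,
                                seed = 1L) {
  group <- droplevels(as.factor(group))
  if (!control %in% levels(group)) stop("control group not present")
  treats <- setdiff(levels(group), control)
  if (!length(treats)) stop("need at least one treatment group")
  n <- table(group)
  if (n[[control]] < 2) stop("control group needs n >= 2")
  if (any(n < 2)) stop("each group needs n >= 2 for the pooled variance")
  means <- tapply(values, group, mean)
  vars <- tapply(values, group, var)
  N <- length(values); k <- nlevels(group)
  df <- N - k
  s2 <- sum((n - 1) * vars) / df
  n0 <- n[[control]]
  nt <- as.numeric(n[treats])
  diffs <- as.numeric(means[treats] - means[[control]])
  sed <- sqrt(s2 * (1 / nt + 1 / n0))
  tstat <- ifelse(sed > 0, diffs / sed,
                  ifelse(diffs == 0, 0, Inf * sign(diffs)))
  R <- dunnett_corr(n0, nt)
  set.seed(seed)
  p_adj <- vapply(tstat, function(ti) {
    if (!is.finite(ti)) return(if (is.na(ti)) NA_real_ else 0)
    1 - mvtnorm::pmvt(lower = rep(-abs(ti), length(nt)),
                      upper = rep(abs(ti), length(nt)),
                      df = df, corr = R,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
  }, numeric(1))
  p_unadj <- 2 * pt(-abs(tstat), df)
  p_adj <- pmin(1, pmax(p_adj, p_unadj))  # adjusted p never below unadjusted
  an <- anova_oneway(values, group)
  structure(list(
    comparisons = data.frame(group = treats, n = nt,
                             diff = diffs, se = sed, t = tstat,
                             p = p_unadj, p_adj = p_adj,
                             significant = p_adj < alpha,
                             stringsAsFactors = FALSE),
    control = control, n_control = n0, df = df, s2 = s2,
    anova_F = an$F, anova_p = an$p, alpha = alpha),
    class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("<dunnett_result> vs control '%s' (ANOVA F = %.3g, p = %.3g)\n",
              x$control, x$anova_F, x$anova_p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Dunnett tests for every parameter of a tidy morphometry table
#'
#' Aggregates object-level rows to per-specimen means (specimens are the
#' experimental units), then runs [dunnett_many_to_one()] per parameter
#' (and per layer when a `layer` column is present).
#'
#' @param data tidy data frame: `specimen`, `group`, optional `layer`,
#'   `parameter`, `value` — or a wide data frame plus `parameters`.
#' @param control control group id.
#' @param alpha significance level.
#' @param parameters for wide input, the value columns to test.
#' @param aggregate_specimens average object rows per specimen first
#'   (default TRUE).
#' @param seed seed for the adjustment integrations.
#' @return data frame of per-parameter (x layer) comparisons with adjusted
#'   p values and significance flags.
#' @export
dunnett_table <- function(data, control, alpha = 0.05, parameters = NULL,
                          aggregate_specimens = TRUE, seed = 1L) {
  if (!is.null(parameters)) {
    long <- do.call(rbind, lapply(parameters, function(p) {
      out <- data[, intersect(c("specimen", "group", "layer"), names(data)),
                  drop = FALSE]
      out$parameter <- p
      out$value <- data[[p]]
      out
    }))
  } else long <- data
  keys <- intersect(c("parameter", "layer"), names(long))
  split_keys <- interaction(long[keys], drop = TRUE)
  res <- lapply(split(long, split_keys), function(dd) {
    key_row <- dd[1, keys, drop = FALSE]
    if (aggregate_specimens) {
      dd <- aggregate(value ~ specimen + group, dd, mean)
    }
    if (length(unique(dd$group)) < 2 || !control %in% dd$group) return(NULL)
    dr <- dunnett_many_to_one(dd$value, dd$group, control, alpha, seed = seed)
    cbind(key_row, dr$comparisons,
          anova_F = dr$anova_F, anova_p = dr$anova_p, row.names = NULL)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  do.call(rbind, c(res, make.row.names = FALSE))
}
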