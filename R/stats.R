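#' Rank-based effect size r from a two-group comparison
#'
#' r = |z| / sqrt(N), with z the standardized rank-sum statistic
#' (normal approximation with tie correction and continuity
#' correction).
#'
#' @param x,y Numeric samples for the two groups.
#' @return List with `z` (signed; positive when `x` tends larger), `r`,
#'   `n`.
#' @export
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(ranks)
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(list(z = 0, r = 0, n = nt))
  cc <- sign(W - mu) * 0.5  # continuity correction
  z <- (W - mu - cc) / sqrt(sig2)
  list(z = z, r = abs(z) / sqrt(nt), n = nt)
}

#' Per-day nonparametric group comparisons with Bonferroni correction
#'
#' For each day (or other stratum) of one measure: two groups are
#' compared by the Wilcoxon rank-sum test, three or more by
#' Kruskal-Wallis; p values are Bonferroni-corrected within the family
#' of days. When a day's Kruskal-Wallis test is significant after
#' correction, pairwise rank-sum post hocs (Bonferroni over pairs within
#' the day) are appended. The rank effect size r = |z|/sqrt(N)
#' accompanies every rank-sum comparison. Exact rank-sum p values are
#' used when both groups have at most `exact_max` observations and no
#' ties; the normal approximation with continuity correction otherwise.
#'
#' @param values Numeric feature values, one per observation (mouse x
#'   day).
#' @param group Group label per observation.
#' @param day Day (stratum) per observation.
#' @param alpha Significance level before correction (default 0.05).
#' @param exact_max Largest per-group n for exact rank-sum p.
#' @return Data frame of comparison rows: `day`, `test`, `groups`,
#'   `statistic`, `z`, `p_raw`, `p_adjusted`, `effect_kind`,
#'   `effect_size`, `m` (family size).
#' @export
per_day_ranksum <- function(values, group, day, alpha = 0.05,
                            exact_max = 10L) {
  stopifnot(length(values) == length(group),
            length(values) == length(day))
  group <- as.character(group)
  days <- sort(unique(day))
  glev <- sort(unique(group))
  out <- list()
  skipped <- character(0)
  for (d in days) {
    sel <- day == d & is.finite(values)
    v <- values[sel]; g <- group[sel]
    ns <- table(factor(g, levels = glev))
    if (any(ns < 2)) {
      skipped <- c(skipped, as.character(d))
      next
    }
    if (length(glev) == 2L) {
      x <- v[g == glev[1]]; y <- v[g == glev[2]]
      exact <- max(length(x), length(y)) <= exact_max &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
      zz <- ranksum_z(x, y)
      out[[length(out) + 1L]] <- data.frame(
        day = d, test = "wilcoxon_ranksum",
        groups = paste(glev, collapse = " vs "),
        statistic = unname(wt$statistic), z = zz$z,
        p_raw = wt$p.value, p_adjusted = NA_real_,
        effect_kind = "r", effect_size = zz$r,
        m = NA_integer_)
    } else {
      kw <- stats::kruskal.test(v, factor(g))
      out[[length(out) + 1L]] <- data.frame(
        day = d, test = "kruskal_wallis", groups = "all",
        statistic = unname(kw$statistic), z = NA_real_,
        p_raw = kw$p.value, p_adjusted = NA_real_,
        effect_kind = NA_character_, effect_size = NA_real_,
        m = NA_integer_)
    }
  }
  if (length(skipped))
    warning("per_day_ranksum: day(s) skipped for n < 2 in a group: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(out)) return(empty_comparison_table())
  res <- do.call(rbind, out)
  m <- nrow(res)  # family = days within this measure
  res$p_adjusted <- pmin(1, res$p_raw * m)
  res$m <- m
  # post hoc pairwise rank-sums for significant Kruskal-Wallis days
  if (length(glev) > 2L) {
    post <- list()
    pairs <- utils::combn(glev, 2, simplify = FALSE)
    for (k in which(res$test == "kruskal_wallis" &
                    res$p_adjusted < alpha)) {
      d <- res$day[k]
      sel <- day == d & is.finite(values)
      v <- values[sel]; g <- group[sel]
      for (pr in pairs) {
        x <- v[g == pr[1]]; y <- v[g == pr[2]]
        exact <- max(length(x), length(y)) <= exact_max &&
          !any(duplicated(c(x, y)))
        wt <- suppressWarnings(
          stats::wilcox.test(x, y, exact = exact, correct = TRUE))
        zz <- ranksum_z(x, y)
        post[[length(post) + 1L]] <- data.frame(
          day = d, test = "posthoc_ranksum",
          groups = paste(pr, collapse = " vs "),
          statistic = unname(wt$statistic), z = zz$z,
          p_raw = wt$p.value,
          p_adjusted = min(1, wt$p.value * length(pairs)),
          effect_kind = "r", effect_size = zz$r,
          m = length(pairs))
      }
    }
    if (length(post)) res <- rbind(res, do.call(rbind, post))
  }
  rownames(res) <- NULL
  res
}

empty_comparison_table <- function() {
  data.frame(day = numeric(0), test = character(0),
             groups = character(0), statistic = numeric(0),
             z = numeric(0), p_raw = numeric(0),
             p_adjusted = numeric(0), effect_kind = character(0),
             effect_size = numeric(0), m = integer(0))
}

#' Mixed-design two-way ANOVA with partial eta squared
#'
#' Between-subject factor `group`, within-subject factor `within` (day
#' or hole), subjects identified by `subject`. Fits the classical
#' mixed-model ANOVA (subjects nested in group; the within factor and
#' the interaction tested against the subject-by-within error stratum)
#' and reports partial eta squared for each effect,
#' eta_p^2 = SS_effect / (SS_effect + SS_error-of-its-stratum).
#' When an effect involving `group` is significant, Tukey's HSD post hoc
#' on the group factor (over subject means) is attached as attribute
#' `tukey`.
#'
#' @param values Numeric response per observation.
#' @param subject Subject (mouse) id per observation.
#' @param group Between-subject group per observation.
#' @param within Within-subject level (day or hole) per observation.
#' @param alpha Gate for the post hoc (default 0.05).
#' @return Data frame with one row per effect (`group`, `within`,
#'   `group:within`): `df1`, `df2`, `F`, `p`, `eta_p_sq`.
#' @export
mixed_anova_eta <- function(values, subject, group, within,
                            alpha = 0.05) {
  df <- data.frame(y = values, subject = factor(subject),
                   group = factor(group), within = factor(within))
  if (any(is.na(df$y)))
    stop("mixed_anova_eta: missing responses", call. = FALSE)
  cells <- table(df$group, df$within)
  if (any(cells == 0))
    stop("mixed_anova_eta: empty design cell: ",
         paste(which(cells == 0, arr.ind = TRUE), collapse = ","),
         call. = FALSE)
  fit <- stats::aov(y ~ group * within + Error(subject/within),
                    data = df)
  sm <- summary(fit)
  # between stratum: group vs subject-within-group residuals
  bt <- sm[["Error: subject"]][[1]]
  wt <- sm[["Error: subject:within"]][[1]]
  if (is.null(bt) || is.null(wt))
    stop("mixed_anova_eta: singular design (no error stratum)",
         call. = FALSE)
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    if (is.na(i)) NULL else tab[i, ]
  }
  eta <- function(tab, name) {
    r <- row_of(tab, name)
    e <- row_of(tab, "Residuals")
    r[["Sum Sq"]] / (r[["Sum Sq"]] + e[["Sum Sq"]])
  }
  mk <- function(tab, name) {
    r <- row_of(tab, name)
    e <- row_of(tab, "Residuals")
    data.frame(effect = name, df1 = r[["Df"]], df2 = e[["Df"]],
               F = r[["F value"]], p = r[["Pr(>F)"]],
               eta_p_sq = eta(tab, name))
  }
  res <- rbind(mk(bt, "group"), mk(wt, "within"),
               mk(wt, "group:within"))
  rownames(res) <- NULL
  sig <- res$p[res$effect %in% c("group", "group:within")] < alpha
  if (any(sig, na.rm = TRUE) && nlevels(df$group) >= 2L) {
    means <- stats::aggregate(y ~ subject + group, data = df, FUN = mean)
    tk <- stats::TukeyHSD(stats::aov(y ~ group, data = means))
    attr(res, "tukey") <- tk$group
  }
  res
}
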