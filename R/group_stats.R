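#' D'Agostino-Pearson omnibus normality test
#'
#' Omnibus K^2 statistic combining the standardized sample skewness
#' (D'Agostino's transformation) and kurtosis (Anscombe-Glynn
#' transformation); under normality K^2 is approximately chi-squared with
#' 2 degrees of freedom. Used as the normality screen before the
#' nonparametric battery: the pipeline proceeds with rank-based tests
#' regardless, and this test documents why.
#'
#' @param x Numeric vector. Requires `n >= 8` for the kurtosis
#'   transformation to be defined.
#' @return A list with `statistic` (K^2), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`, and `applicable`. For `n < 8` or a zero-variance
#'   sample the result is flagged not applicable (`statistic` and `p_value`
#'   are `NA`) and callers proceed nonparametrically.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  na_result <- list(statistic = NA_real_, p_value = NA_real_,
                    z_skewness = NA_real_, z_kurtosis = NA_real_,
                    n = n, applicable = FALSE)
  if (n < 8) return(na_result)
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 <= 0) return(na_result)
  g1 <- mean(m^3) / m2^1.5
  g2 <- mean(m^4) / m2^2

  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  list(statistic = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n, applicable = TRUE)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and a chi-squared reference
#' with k - 1 degrees of freedom, via [stats::kruskal.test()]. A degenerate
#' input with all values identical returns H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, total
#'   n >= 3).
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 1) || sum(lengths(groups)) < 3)
    stop("need >= 2 non-empty groups with total n >= 3")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(H = 0, p_value = 1, df = k - 1))
  g <- factor(rep(seq_len(k), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc comparisons versus the control group
#'
#' Dunn z statistics on the pooled ranks with tie correction, comparing each
#' non-control group against the control. Two-sided p values are multiplied
#' by the number of comparisons (k - 1, the vs-control family) and capped at
#' 1. The sign of each comparison is the sign of the difference in group
#' mean ranks (treated minus control).
#'
#' @param groups Named list of numeric vectors, control identified by
#'   `control_index`.
#' @param control_index Index of the control group in `groups` (default 1).
#' @return Data frame with one row per non-control group: `group`, `z`,
#'   `p_value`, `p_adjusted`, `sign`, `mean_rank_diff`.
#' @export
dunn_vs_control <- function(groups, control_index = 1L) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (lengths(groups)[control_index] == 0) stop("control group is empty")
  labs <- names(groups) %||% as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  others <- setdiff(seq_len(k), control_index)
  n <- lengths(groups)
  z <- (mean_ranks[others] - mean_ranks[control_index]) /
    sqrt(var_base * (1 / n[others] + 1 / n[control_index]))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = labs[others],
             z = as.numeric(z),
             p_value = as.numeric(p),
             p_adjusted = pmin(1, as.numeric(p) * (k - 1)),
             sign = sign(as.numeric(z)),
             mean_rank_diff = as.numeric(mean_ranks[others] - mean_ranks[control_index]),
             row.names = NULL)
}

#' Signed change calls for one endpoint across groups
#'
#' The full inference chain for one endpoint: Kruskal-Wallis omnibus across
#' all groups, then (only when the omnibus is significant) Dunn's test of
#' each treated group against the control with Bonferroni adjustment over
#' the k - 1 vs-control comparisons. A group is called `up` when its
#' adjusted p is below alpha and its mean exceeds the control mean, `down`
#' when below, and `no_change` otherwise; a non-significant omnibus makes
#' every call `no_change`.
#'
#' @param measurements Cell-measurement data frame.
#' @param endpoint Endpoint column name.
#' @param control_label Control group label.
#' @param alpha Significance level (default 0.05).
#' @param group_col,region_col Column names for group and region.
#' @return A list of class `endpoint_comparison`: `endpoint`, `region`,
#'   `normality` (per-group D'Agostino-Pearson p), `kw_H`, `kw_p`,
#'   `comparisons` (per treated group: Dunn statistics, group means, call).
#' @export
compare_endpoint <- function(measurements, endpoint, control_label,
                             alpha = 0.05, group_col = "group",
                             region_col = "region") {
  v <- measurements[[endpoint]]
  if (is.null(v)) stop("unknown endpoint: ", endpoint)
  grp <- measurements[[group_col]]
  region <- unique(measurements[[region_col]])
  if (length(region) > 1)
    stop("compare_endpoint expects a single region; split first")
  glabs <- unique(grp)
  if (!control_label %in% glabs) stop("control group absent: ", control_label)
  glabs <- c(control_label, setdiff(glabs, control_label))
  groups <- lapply(stats::setNames(glabs, glabs),
                   function(g) v[grp == g & !is.na(v)])
  norm_p <- vapply(groups, function(g) dagostino_pearson(g)$p_value, numeric(1))
  kw <- kruskal_wallis(groups)
  dn <- dunn_vs_control(groups, control_index = 1L)
  means <- vapply(groups, mean, numeric(1))
  dn$mean <- means[dn$group]
  dn$control_mean <- means[[control_label]]
  dn$call <- "no_change"
  if (is.finite(kw$p_value) && kw$p_value < alpha) {
    sig <- dn$p_adjusted < alpha
    dn$call[sig & dn$mean > dn$control_mean] <- "up"
    dn$call[sig & dn$mean < dn$control_mean] <- "down"
  }
  structure(list(endpoint = endpoint, region = region,
                 alpha = alpha, n = lengths(groups),
                 normality_p = norm_p, kw_H = kw$H, kw_p = kw$p_value,
                 comparisons = dn),
            class = "endpoint_comparison")
}

# canonical endpoint set for the autophagy battery, with the measurement
# column and whether group statistics run on the control-relative scale
endpoint_table <- function() {
  data.frame(
    endpoint = c("expression_autophagosome", "expression_adaptor",
                 "puncta_autophagosome", "puncta_adaptor", "puncta_coloc",
                 "pct_coloc_autophagosome", "pct_coloc_adaptor"),
    column = c("expr_autophagosome", "expr_adaptor",
               "n_autophagosome", "n_adaptor", "n_coloc",
               "pct_autophagosome_coloc", "pct_adaptor_coloc"),
    stringsAsFactors = FALSE
  )
}

#' Run the statistical battery over all endpoints of one region
#'
#' Applies [compare_endpoint()] to the seven autophagy endpoints
#' (two expression, three puncta-count, two percent-colocalized) and collects
#' per-group change calls.
#'
#' @param measurements Cell-measurement data frame for one region.
#' @param control_label Control group label.
#' @param alpha Significance level.
#' @return A list with `comparisons` (named list of `endpoint_comparison`)
#'   and `calls`, a data frame (`region`, `endpoint`, `group`, `call`,
#'   `p_adjusted`, `mean`, `control_mean`).
#' @export
endpoint_battery <- function(measurements, control_label, alpha = 0.05) {
  tab <- endpoint_table()
  comps <- list()
  calls <- list()
  for (i in seq_len(nrow(tab))) {
    cmp <- compare_endpoint(measurements, tab$column[i], control_label, alpha)
    cmp$endpoint <- tab$endpoint[i]
    comps[[tab$endpoint[i]]] <- cmp
    cc <- cmp$comparisons
    calls[[i]] <- data.frame(region = cmp$region, endpoint = tab$endpoint[i],
                             group = cc$group, call = cc$call,
                             p_adjusted = cc$p_adjusted, mean = cc$mean,
                             control_mean = cc$control_mean,
                             kw_H = cmp$kw_H, kw_p = cmp$kw_p)
  }
  list(comparisons = comps, calls = do.call(rbind, calls))
}
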