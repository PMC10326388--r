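# Dose-response statistics on per-region volume-of-activation counts:
# Kruskal-Wallis across dose groups (exact small-sample permutation path),
# exact Wilcoxon rank-sum post-hoc contrasts, the rank-based FDR boundary
# across regions, and the time-course repeated-measures ANOVA.

# Kruskal-Wallis H with tie correction (midranks)
kw_h_statistic <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n_g <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(n_g * rbar^2) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0) # all values identical
  H / corr
}

# all distinct assignments of indices 1..N into groups of the given sizes;
# calls fn(assignment factor) for each
.for_each_partition <- function(sizes, fn) {
  N <- sum(sizes)
  assign_rec <- function(remaining, g, lab) {
    if (g > length(sizes)) {
      fn(lab)
      return(invisible(NULL))
    }
    if (g == length(sizes)) {
      lab[remaining] <- g
      fn(lab)
      return(invisible(NULL))
    }
    picks <- combn(length(remaining), sizes[g])
    for (j in seq_len(ncol(picks))) {
      lab2 <- lab
      lab2[remaining[picks[, j]]] <- g
      assign_rec(remaining[-picks[, j]], g + 1L, lab2)
    }
  }
  assign_rec(seq_len(N), 1L, integer(N))
}

n_partitions <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Kruskal-Wallis test with an exact small-sample path
#'
#' Computes the tie-corrected H statistic. For small samples (number of
#' distinct group assignments at most `max_perm`) the p-value is the exact
#' permutation probability `P(H* >= H)`; otherwise the chi-square
#' approximation with `k - 1` degrees of freedom is used and the result is
#' flagged `approximate`.
#'
#' @param values Numeric responses.
#' @param groups Group labels (>= 2 groups, >= 2 per group).
#' @param exact `"auto"` (default), `"never"` or `"always"`.
#' @param max_perm Enumeration budget for the exact path.
#' @return List: `H`, `p_value`, `method` (`"exact"`/`"approximate"`), `df`.
#' @export
kw_test <- function(values, groups, exact = c("auto", "never", "always"),
                    max_perm = 20000) {
  exact <- match.arg(exact)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 groups.")
  n_g <- tabulate(groups)
  if (any(n_g < 2)) abort("need at least 2 observations per group.")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1, method = "degenerate", df = k - 1))
  }
  H <- kw_h_statistic(values, groups)
  np <- n_partitions(n_g)
  use_exact <- switch(exact,
    auto = np <= max_perm,
    always = TRUE,
    never = FALSE
  )
  if (use_exact) {
    if (np > 5e6) abort("exact enumeration infeasible for this design.")
    # order observations so assignment sizes follow the factor levels
    count <- 0L
    hits <- 0L
    .for_each_partition(n_g, function(lab) {
      count <<- count + 1L
      if (kw_h_statistic(values, lab) >= H - 1e-12) hits <<- hits + 1L
    })
    list(H = H, p_value = hits / count, method = "exact", df = k - 1)
  } else {
    list(
      H = H, p_value = pchisq(H, df = k - 1, lower.tail = FALSE),
      method = "approximate", df = k - 1
    )
  }
}

#' Wilcoxon rank-sum test, exact by enumeration for small samples
#'
#' Two-sided rank-sum test of `a` vs `b`. When `min(n_a, n_b) <= 10` (and
#' the enumeration is affordable) the p-value is exact: every assignment of
#' the pooled midranks to a group of size `n_a` is enumerated and the
#' two-sided p is twice the smaller tail of the rank-sum distribution
#' (capped at 1). Ties are handled naturally by the midranks. Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric samples.
#' @param max_enum Enumeration budget (`choose(n, n_a)`).
#' @return List: `W` (rank sum of `a`), `z` (normal-scale statistic used for
#'   the effect size), `p_value`, `method`, `direction` (`"<"`, `">"` or
#'   `"="` comparing medians of `a` and `b`), `omega_sq`.
#' @export
rank_sum_test <- function(a, b, max_enum = 4e5) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty.")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- table(pooled)
  sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (W - mu - sign(W - mu) * 0.5) / sqrt(sig2) else 0
  med_a <- median(a); med_b <- median(b)
  direction <- if (med_a < med_b) "<" else if (med_a > med_b) ">" else "="
  if (length(unique(pooled)) == 1L) {
    return(list(
      W = W, z = 0, p_value = 1, method = "degenerate",
      direction = "=", omega_sq = 0
    ))
  }
  if (min(na, nb) <= 10 && choose(N, na) <= max_enum) {
    sums <- combn(N, na, function(i) sum(r[i]))
    p_lo <- mean(sums <= W + 1e-9)
    p_hi <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- if (sig2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(
    W = W, z = z, p_value = p, method = method, direction = direction,
    omega_sq = (z^2 - 1) / N
  )
}

#' Kruskal-Wallis dose-response scan over regions
#'
#' For every region, compares the per-subject values (typically
#' volume-of-activation voxel counts) across the dose groups, reports the
#' per-group medians and the tie-corrected H test, and ranks the output by
#' ascending p-value (ties broken by region id) — the layout of a
#' dose-response table.
#'
#' @param table Tibble with one row per (region, subject): columns
#'   `region_id`, `region_name` (optional), a group column and a value
#'   column.
#' @param value,group Column names (strings) of the response and the group
#'   label.
#' @param exact Passed to [kw_test()].
#' @return Tibble: `region_id`, `region_name`, one `med_<group>` column per
#'   group, `H`, `p_value`, `method`, sorted by `p_value`.
#' @export
kruskal_wallis_by_region <- function(table, value = "n_voxels",
                                     group = "dose", exact = "auto") {
  table <- as_tibble(table)
  if (!"region_name" %in% names(table)) {
    table$region_name <- paste0("region_", table$region_id)
  }
  lvls <- if (is.factor(table[[group]])) {
    levels(table[[group]])
  } else {
    unique(table[[group]])
  }
  res <- table |>
    dplyr::group_by(.data$region_id, .data$region_name) |>
    dplyr::group_modify(function(d, key) {
      meds <- tapply(d[[value]], factor(d[[group]], levels = lvls), median)
      kt <- kw_test(d[[value]], d[[group]], exact = exact)
      out <- as_tibble(as.list(setNames(meds, paste0("med_", lvls))))
      out$H <- kt$H
      out$p_value <- kt$p_value
      out$method <- kt$method
      out
    }) |>
    dplyr::ungroup()
  dplyr::arrange(res, .data$p_value, .data$region_id)
}

#' Post-hoc rank-sum contrasts between two dose groups, per region
#'
#' Runs [rank_sum_test()] region by region for one pair of groups, reports
#' the group medians, direction, p-value and the `(z^2 - 1)/N` variance
#' explained effect size, and flags the regions surviving the rank-based FDR
#' boundary across regions (see [region_fdr_cutoff()]).
#'
#' @inheritParams kruskal_wallis_by_region
#' @param group_a,group_b The two group labels to contrast.
#' @param fdr_q FDR filter value applied across regions (default 0.05).
#' @return Tibble: `region_id`, `region_name`, `med_a`, `direction`,
#'   `med_b`, `W`, `z`, `p_value`, `omega_sq`, `method`, `fdr_significant`;
#'   sorted by `p_value`. The FDR boundary p is attached as attribute
#'   `fdr_cutoff`.
#' @export
wilcoxon_posthoc <- function(table, group_a, group_b, value = "n_voxels",
                             group = "dose", fdr_q = 0.05) {
  table <- as_tibble(table)
  if (!"region_name" %in% names(table)) {
    table$region_name <- paste0("region_", table$region_id)
  }
  have <- unique(table[[group]])
  if (!all(c(group_a, group_b) %in% have)) {
    abort("both groups must be present in the table.")
  }
  res <- table |>
    dplyr::group_by(.data$region_id, .data$region_name) |>
    dplyr::group_modify(function(d, key) {
      a <- d[[value]][d[[group]] == group_a]
      b <- d[[value]][d[[group]] == group_b]
      rt <- rank_sum_test(a, b)
      tibble(
        med_a = median(a), direction = rt$direction, med_b = median(b),
        W = rt$W, z = rt$z, p_value = rt$p_value, omega_sq = rt$omega_sq,
        method = rt$method
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_value, .data$region_id)
  fc <- region_fdr_cutoff(res$p_value, q = fdr_q)
  res$fdr_significant <- fc$keep
  attr(res, "fdr_cutoff") <- fc$cutoff
  res
}

#' Rank-based FDR boundary across regions
#'
#' Applies the same step-up rule as the voxel filter (see [fdr_filter()]) to
#' a vector of per-region p-values and returns the largest p-value declared
#' significant — the "FDR boundary" annotation of a ranked post-hoc table.
#'
#' @param p_values Per-region p-values.
#' @param q Filter value (default 0.05).
#' @return List: `cutoff` (largest kept p, `NA` if none kept) and `keep`
#'   (logical, aligned with `p_values`).
#' @export
region_fdr_cutoff <- function(p_values, q = 0.05) {
  keep <- fdr_filter(p_values, q = q, c_V = 1)
  cutoff <- if (any(keep)) max(p_values[keep]) else NA_real_
  list(cutoff = cutoff, keep = keep)
}

#' Two-way repeated-measures ANOVA on time courses
#'
#' Classical mixed two-factor decomposition: group (between subjects) by
#' acquisition (repeated within subject), with the subject stratum handled
#' by an `Error(subject)` term. Reports the group-by-time interaction and
#' per-timepoint group contrasts at the Sidak-adjusted level
#' `alpha_sidak = 1 - (1 - alpha)^(1/m)` where `m` is the number of
#' timepoints in the comparison family.
#'
#' @param data Tibble with columns `subject`, `group`, `time`, `value` (one
#'   row per subject x acquisition).
#' @param alpha Familywise level for the Sidak contrasts (default 0.05).
#' @param family Optional integer vector of timepoints forming the
#'   multiple-comparison family (default: all timepoints present).
#' @return List: `anova` (tibble of the within-stratum terms with F and p),
#'   `interaction_p`, `per_time` (tibble `time`, `statistic`, `p_value`,
#'   `significant`), `alpha_sidak`, `m`.
#' @export
rm_anova_interaction <- function(data, alpha = 0.05, family = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("subject", "group", "time", "value") %in% names(data)))
  if (length(unique(data$time)) < 2) abort("need at least 2 timepoints.")
  if (any(tapply(data$subject, data$group, function(s) length(unique(s))) < 2)) {
    abort("need at least 2 subjects per group.")
  }
  d <- data
  d$subject <- factor(d$subject)
  d$group <- factor(d$group)
  d$timef <- factor(d$time)
  fit <- aov(value ~ group * timef + Error(subject), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  between <- summary(fit)[["Error: subject"]][[1]]
  rn <- trimws(rownames(within))
  anova_tbl <- tibble(
    term = sub("timef", "time", rn),
    df = within[["Df"]],
    statistic = within[["F value"]],
    p_value = within[["Pr(>F)"]]
  )
  anova_tbl <- dplyr::bind_rows(
    tibble(
      term = trimws(rownames(between)),
      df = between[["Df"]],
      statistic = between[["F value"]],
      p_value = between[["Pr(>F)"]]
    ),
    anova_tbl
  )
  interaction_p <- anova_tbl$p_value[anova_tbl$term == "group:time"]
  fam <- family %||% sort(unique(d$time))
  m <- length(fam)
  alpha_sidak <- 1 - (1 - alpha)^(1 / m)
  glev <- levels(d$group)
  per_time <- purrr::map_dfr(fam, function(tp) {
    dt <- d[d$time == tp, ]
    if (length(glev) == 2) {
      a <- dt$value[dt$group == glev[1]]
      b <- dt$value[dt$group == glev[2]]
      ht <- t.test(a, b)
      tibble(time = tp, statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      ht <- stats::oneway.test(value ~ group, data = dt)
      tibble(time = tp, statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  })
  per_time$significant <- per_time$p_value <= alpha_sidak
  list(
    anova = anova_tbl, interaction_p = interaction_p, per_time = per_time,
    alpha_sidak = alpha_sidak, m = m
  )
}
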