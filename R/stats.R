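#' Define a sample group
#'
#' A labelled set of replicate-level metric values for one crystallization
#' treatment cell: base fat (cocoa butter `CB` or trilaurin `TL`), with or
#' without emulsifier, random (`RS`) or laminar (`LS`) shear at a given
#' shear rate. Inferential comparisons require at least two replicates per
#' group.
#'
#' @param base_fat `"CB"` or `"TL"`.
#' @param emulsifier logical; emulsifier added.
#' @param shear_type `"RS"` or `"LS"`.
#' @param shear_rate_s1 shear rate in 1/s (metadata only).
#' @param replicate_values numeric vector, one value per replicate.
#' @return A `sample_group`.
#' @export
sample_group <- function(base_fat = c("CB", "TL"), emulsifier = FALSE,
                         shear_type = c("RS", "LS"), shear_rate_s1 = 500,
                         replicate_values = numeric()) {
  base_fat <- match.arg(base_fat)
  shear_type <- match.arg(shear_type)
  structure(list(base_fat = base_fat, emulsifier = isTRUE(emulsifier),
                 shear_type = shear_type, shear_rate_s1 = shear_rate_s1,
                 replicate_values = as.numeric(replicate_values),
                 label = paste0(base_fat, if (isTRUE(emulsifier)) "/M" else "",
                                " ", shear_type)),
            class = "sample_group")
}

.groups_to_df <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    stopifnot(inherits(g, "sample_group"))
    data.frame(group = g$label, base_fat = g$base_fat,
               emulsifier = g$emulsifier, shear_type = g$shear_type,
               value = g$replicate_values)
  }))
}

#' Brown-Forsythe homoscedasticity check
#'
#' Levene-type test on absolute deviations from the group medians. Groups
#' are called homoscedastic when `p > alpha`; that gate selects the ordinary
#' ANOVA branch in [compare_groups()].
#'
#' With the handful of replicates typical of crystallization experiments
#' the classical F reference distribution for this statistic is severely
#' conservative (the group median zeroes one deviation per group), so by
#' default the statistic is calibrated by a label-permutation null (group
#' medians recomputed per permutation; a fixed internal substream keeps the
#' result deterministic), which holds the nominal level at any group size.
#' `calibration = "parametric"` gives the textbook F p-value.
#'
#' All-constant groups (no variance anywhere) are degenerate: no variance
#' difference is detectable and the test returns `p = 1` by convention,
#' flagged.
#'
#' @param groups list of [sample_group()] objects.
#' @param alpha gate level (default 0.05).
#' @param calibration `"permutation"` (default) or `"parametric"`.
#' @param n_perm permutations for the permutation null (default 199).
#' @return List with `statistic`, `p`, `homoscedastic`, `degenerate`,
#'   `calibration`.
#' @export
check_homoscedasticity <- function(groups, alpha = 0.05,
                                   calibration = c("permutation",
                                                   "parametric"),
                                   n_perm = 199) {
  calibration <- match.arg(calibration)
  df <- .groups_to_df(groups)
  if (length(unique(df$group)) < 2)
    stop("need at least two groups")
  n_per <- table(df$group)
  if (any(n_per < 2))
    stop("every group needs >= 2 replicates: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  dev <- abs(df$value - stats::ave(df$value, df$group,
                                   FUN = stats::median))
  if (all(dev == 0))
    return(list(statistic = NA_real_, p = 1, homoscedastic = TRUE,
                degenerate = TRUE, calibration = calibration))
  g <- factor(df$group)
  n <- length(df$value)
  idx <- split(seq_len(n), g)
  k <- length(idx)
  bf_stat <- function(v) {
    ssb <- 0; ssw <- 0; tot <- 0
    devs <- vector("list", k)
    for (j in seq_len(k)) {
      d <- abs(v[idx[[j]]] - stats::median(v[idx[[j]]]))
      devs[[j]] <- d
      tot <- tot + sum(d)
    }
    grand <- tot / n
    for (j in seq_len(k)) {
      m <- mean(devs[[j]])
      ssb <- ssb + length(devs[[j]]) * (m - grand)^2
      ssw <- ssw + sum((devs[[j]] - m)^2)
    }
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- bf_stat(df$value)
  if (calibration == "parametric") {
    lt <- car::leveneTest(df$value ~ g, center = median)
    p <- lt[1, "Pr(>F)"]
  } else {
    exceed <- .with_seed(104729, {
      sum(vapply(seq_len(n_perm), function(b) {
        bf_stat(df$value[sample.int(n)]) >= f_obs
      }, logical(1)))
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(statistic = f_obs, p = p, homoscedastic = p > alpha,
       degenerate = FALSE, calibration = calibration)
}

# Dunnett T3 all-pairs comparisons: pairwise Welch t statistics judged
# against Sidak-style studentized-maximum-modulus tails with
# Welch-Satterthwaite degrees of freedom.
.dunnett_t3 <- function(stats_df) {
  k <- nrow(stats_df)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(g1 = stats_df$group[pairs[1, ]],
                    g2 = stats_df$group[pairs[2, ]],
                    p = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- stats_df$var[i1] / stats_df$n[i1] + stats_df$var[i2] /
      stats_df$n[i2]
    if (se2 == 0) {
      out$p[j] <- if (stats_df$mean[i1] == stats_df$mean[i2]) 1 else 0
      next
    }
    tstat <- (stats_df$mean[i1] - stats_df$mean[i2]) / sqrt(se2)
    df_w <- se2^2 / (stats_df$var[i1]^2 / (stats_df$n[i1]^2 *
                                             (stats_df$n[i1] - 1)) +
                       stats_df$var[i2]^2 / (stats_df$n[i2]^2 *
                                               (stats_df$n[i2] - 1)))
    p2 <- 2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE)
    out$p[j] <- 1 - (1 - p2)^m # SMM tail, Sidak form over m moduli
  }
  out$p <- pmin(out$p, 1)
  out
}

# compact letter display, insert-and-absorb: groups sharing a letter are
# exactly those whose pairwise p > alpha
.compact_letters <- function(group_names, pw, alpha) {
  cols <- list(group_names) # each column = a set of mutually similar groups
  sig <- pw[pw$p <= alpha, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- sig$g1[j]; b <- sig$g2[j]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else newcols <- c(newcols, list(col))
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols))
      for (k in seq_along(newcols))
        if (i != k && keep[i] && keep[k] &&
            all(newcols[[i]] %in% newcols[[k]]) &&
            !(all(newcols[[k]] %in% newcols[[i]]) && i < k))
          keep[i] <- FALSE
    cols <- newcols[keep]
  }
  letters_out <- stats::setNames(rep("", length(group_names)), group_names)
  for (j in seq_along(cols))
    for (g in cols[[j]])
      letters_out[g] <- paste0(letters_out[g], LETTERS[j])
  letters_out
}

#' Compare treatment groups of one base fat
#'
#' The assumption-gated comparison workflow: a Brown-Forsythe check decides
#' the branch. Homoscedastic data take an ordinary two-way ANOVA (factors
#' emulsifier and shear type with interaction) for the factor p-values, with
#' Tukey HSD pairwise tests across the four treatment cells. Heteroscedastic
#' data take a Welch one-way ANOVA across cells with Dunnett T3 pairwise
#' tests. Pairwise results are rendered as a compact letter display at
#' `alpha`; letters are assigned within one base fat only, matching how the
#' groups are compared in practice.
#'
#' @param groups list of [sample_group()] objects of a single base fat.
#' @param alpha significance level (default 0.05).
#' @param metric_name label carried into the result.
#' @return A `comparison_result`: `branch`, `factor_p_values`,
#'   `pairwise_p_values` (data frame `g1`, `g2`, `p`), `letters`,
#'   `group_summary` (mean, sd, n per group), `alpha`, `homoscedasticity`.
#' @export
compare_groups <- function(groups, alpha = 0.05, metric_name = "") {
  df <- .groups_to_df(groups)
  if (length(unique(df$base_fat)) != 1)
    stop("letters are compared within one base fat; split the groups")
  df$group <- factor(df$group, levels = unique(df$group))
  gn <- levels(df$group)
  n_per <- table(df$group)

  # zero-variance degenerate case: no difference detectable
  grp_var <- tapply(df$value, df$group, stats::var)
  if (!anyNA(grp_var) && all(grp_var == 0)) {
    pw <- data.frame(g1 = character(0), g2 = character(0), p = numeric(0))
    return(structure(list(metric_name = metric_name, branch = "degenerate",
                          factor_p_values = c(emulsifier = NA_real_,
                                              shear_type = NA_real_,
                                              interaction = NA_real_),
                          pairwise_p_values = pw,
                          letters = stats::setNames(rep("A", length(gn)), gn),
                          group_summary = .group_summary(df),
                          alpha = alpha,
                          homoscedasticity = list(p = 1, degenerate = TRUE),
                          notes = "all groups have zero variance"),
                     class = "comparison_result"))
  }

  hom <- check_homoscedasticity(groups, alpha)
  notes <- character(0)
  forced_welch <- FALSE
  if (max(n_per) - min(n_per) > 1) {
    notes <- c(notes, "unbalanced design beyond one missing replicate; Welch branch forced")
    warning(notes[length(notes)])
    forced_welch <- TRUE
  }

  fac_p <- c(emulsifier = NA_real_, shear_type = NA_real_,
             interaction = NA_real_)
  use_ordinary <- hom$homoscedastic && !forced_welch
  if (use_ordinary) {
    branch <- "ordinary_two_way"
    n_em <- length(unique(df$emulsifier)); n_sh <-
      length(unique(df$shear_type))
    if (n_em > 1 && n_sh > 1) {
      fit <- stats::aov(value ~ factor(emulsifier) * factor(shear_type),
                        data = df)
      tb <- summary(fit)[[1]]
      fac_p <- c(emulsifier = tb[1, "Pr(>F)"], shear_type = tb[2, "Pr(>F)"],
                 interaction = tb[3, "Pr(>F)"])
    } else {
      fit1 <- stats::aov(value ~ group, data = df)
      fac_p["interaction"] <- summary(fit1)[[1]][1, "Pr(>F)"]
    }
    cellfit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(cellfit)$group
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(g1 = vapply(parts, `[`, "", 2),
                     g2 = vapply(parts, `[`, "", 1),
                     p = tk[, "p adj"], row.names = NULL)
  } else {
    branch <- "welch"
    wt <- stats::oneway.test(value ~ group, data = df, var.equal = FALSE)
    fac_p["interaction"] <- wt$p.value # omnibus across cells
    st <- .group_summary(df)
    pw <- .dunnett_t3(data.frame(group = st$group, mean = st$mean,
                                 var = st$sd^2, n = st$n))
  }
  letters_out <- .compact_letters(gn, pw, alpha)
  structure(list(metric_name = metric_name, branch = branch,
                 factor_p_values = fac_p, pairwise_p_values = pw,
                 letters = letters_out, group_summary = .group_summary(df),
                 alpha = alpha, homoscedasticity = hom, notes = notes),
            class = "comparison_result")
}

.group_summary <- function(df) {
  agg <- do.call(rbind, lapply(split(df$value, df$group), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  data.frame(group = rownames(agg), agg, row.names = NULL)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s branch=%s alpha=%.2f\n",
              x$metric_name, x$branch, x$alpha))
  gs <- x$group_summary
  gs$letter <- x$letters[gs$group]
  print(gs, row.names = FALSE)
  invisible(x)
}
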