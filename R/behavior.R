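#' Per-subject behavioral summary
#'
#' Collapses trial-level task records into the per-subject measures the
#' behavioral analysis uses: accuracy over all 10 trials (non-responses
#' count as errors), and the mean and standard deviation of reaction time
#' over responded trials only.
#'
#' @param records data.frame of \code{\link{sampleBehavior}}-shaped rows
#'   (possibly several subjects).
#' @param groups named vector mapping subject_id to group, or a cohort
#'   data.frame.
#' @return data.frame with \code{subject_id}, \code{group},
#'   \code{accuracy}, \code{mean_rt_ms}, \code{std_rt_ms},
#'   \code{n_responded}; subjects with no responded trials get NA RT fields
#'   and \code{flagged = TRUE}.
#' @export
summarizeBehavior <- function(records, groups) {
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$subject_id)
  ids <- unique(records$subject_id)
  rows <- lapply(ids, function(id) {
    r <- records[records$subject_id == id, ]
    if (nrow(r) != 10L)
      stop("subject ", id, " has ", nrow(r), " trials; expected 10")
    rts <- r$rt_ms[!is.na(r$rt_ms)]
    data.frame(subject_id = id, group = unname(groups[id]),
               accuracy = sum(r$correct) / 10,
               mean_rt_ms = if (length(rts)) mean(rts) else NA_real_,
               std_rt_ms = if (length(rts) > 1) sd(rts) else
                 if (length(rts) == 1) 0 else NA_real_,
               n_responded = length(rts),
               flagged = length(rts) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality gate
#'
#' Tests each group's values for normality; the decision is
#' \code{"nonparametric"} as soon as any group rejects at
#' \code{alpha} (or is degenerate), mirroring the analysis plan that routes
#' non-normal measures to rank-based tests.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param alpha rejection level (0.05).
#' @return list with a per-group data.frame (\code{W}, \code{p},
#'   \code{degenerate}) and the \code{decision}.
#' @export
normalityGate <- function(values, groups, alpha = 0.05) {
  sp <- split(values, groups)
  if (any(vapply(sp, length, 1L) < 3L))
    stop("each group needs at least 3 values for the normality test")
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    if (length(unique(v)) == 1L)
      return(data.frame(group = g, W = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    t <- shapiro.test(v)
    data.frame(group = g, W = unname(t$statistic), p = t$p.value,
               degenerate = FALSE)
  })
  tab <- do.call(rbind, rows)
  nonNormal <- any(tab$degenerate) || any(tab$p < alpha, na.rm = TRUE)
  list(table = tab, decision = if (nonNormal) "nonparametric" else "parametric")
}

#' Kruskal-Wallis omnibus comparison
#'
#' Rank-based H test with tie correction (delegated to
#' \code{stats::kruskal.test}); p-value from the chi-square approximation
#' with k-1 degrees of freedom. An all-identical input is degenerate and
#' reported as H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return list with \code{H}, \code{df}, \code{p}, \code{degenerate}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1, degenerate = TRUE))
  t <- kruskal.test(values, groups)
  list(H = unname(t$statistic), df = unname(t$parameter), p = t$p.value,
       degenerate = FALSE)
}

#' Dunn-type post hoc pairwise comparisons
#'
#' Pairwise z tests on pooled-rank means with the Kruskal-Wallis tie
#' correction, Bonferroni-adjusted over the pairs (adjusted p =
#' min(1, m x raw p)).
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param method multiplicity adjustment (\code{p.adjust} method).
#' @return data.frame with one row per pair: \code{z}, \code{p},
#'   \code{p_adj}; pairs involving a group with fewer than 2 values are
#'   flagged with NA statistics.
#' @export
posthocPairwise <- function(values, groups, method = "bonferroni") {
  groups <- factor(groups)
  lev <- levels(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  sig2 <- n * (n + 1) / 12 - tieCorr
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    if (n1 < 2L || n2 < 2L)
      return(data.frame(group1 = g1, group2 = g2, z = NA_real_,
                        p = NA_real_, flagged = TRUE))
    z <- (mean(r[groups == g1]) - mean(r[groups == g2])) /
      sqrt(sig2 * (1 / n1 + 1 / n2))
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * pnorm(-abs(z)), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = method, n = nrow(out))
  out
}

#' Group-level behavioral comparison for one measure
#'
#' Runs the full analysis chain on a per-subject measure: Shapiro-Wilk per
#' group, Kruskal-Wallis omnibus, Dunn-type Bonferroni post hocs.
#'
#' @param behTable a \code{\link{summarizeBehavior}} data.frame.
#' @param measure column to analyse (\code{"accuracy"}, \code{"mean_rt_ms"}
#'   or \code{"std_rt_ms"}).
#' @return list with \code{normality}, \code{omnibus}, \code{pairwise} and
#'   the group \code{summary} (mean and SD per group).
#' @export
compareBehavior <- function(behTable, measure = "accuracy") {
  ok <- !is.na(behTable[[measure]])
  v <- behTable[[measure]][ok]
  g <- behTable$group[ok]
  summary <- do.call(rbind, lapply(split(v, g), function(x)
    data.frame(mean = mean(x), sd = sd(x))))
  summary$group <- rownames(summary)
  list(summary = summary[, c("group", "mean", "sd")],
       normality = normalityGate(v, g),
       omnibus = kruskalWallis(v, g),
       pairwise = posthocPairwise(v, g))
}
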