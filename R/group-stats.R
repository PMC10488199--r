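.check_groups <- function(groups) {
  if (length(groups) < 2) stop_config("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2)) stop_config("every group needs n >= 2 for inference")
  v <- unlist(groups)
  if (!all(is.finite(v))) stop_config("non-finite values in groups")
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within_ss <= 0) stop_config("degenerate data: zero within-group variance")
  invisible(n)
}

.stack_groups <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way analysis of variance across conditions
#'
#' Classical between/within sum-of-squares decomposition via [stats::aov()].
#'
#' @param groups Named list of numeric vectors (one per condition; active
#'   pumping rates).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  .check_groups(groups)
  fit <- stats::aov(value ~ group, data = .stack_groups(groups))
  s <- summary(fit)[[1]]
  list(F = s[1, "F value"], p = s[1, "Pr(>F)"],
       df_between = s[1, "Df"], df_within = s[2, "Df"])
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean comparisons with the studentized-range (Tukey-Kramer)
#' adjustment, which handles unequal replication. Significance tiers are
#' reported at 0.05 / 0.01 / 0.001.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A `tukey_result` data frame: `group1`, `group2`, `diff`
#'   (mean of group2 minus group1), `q`, `p_adj`, `significant`, `stars`;
#'   attribute `alpha`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  df <- .stack_groups(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  # studentized range statistic per pair (Tukey-Kramer standard error)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  n <- lengths(groups)
  g2 <- vapply(pair, `[`, "", 1)   # TukeyHSD rows are "later-earlier"
  g1 <- vapply(pair, `[`, "", 2)
  se <- sqrt(mse / 2 * (1 / n[g1] + 1 / n[g2]))
  q <- abs(tk[, "diff"]) / se
  p <- tk[, "p adj"]
  stars <- cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", "ns"))
  out <- data.frame(group1 = unname(g1), group2 = unname(g2),
                    diff = unname(tk[, "diff"]), q = unname(q),
                    p_adj = unname(p),
                    significant = unname(p < alpha),
                    stars = as.character(stars),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Compact letter display from pairwise comparisons
#'
#' Letters are assigned so that two groups share a letter if and only if
#' their adjusted p value exceeds `alpha`: each letter corresponds to a
#' maximal clique of the non-significance graph, ordered by the first
#' group it covers.
#'
#' @param result A [tukey_hsd()] result (or any data frame with `group1`,
#'   `group2`, `p_adj`).
#' @param alpha Significance level; defaults to the result's alpha.
#' @param group_order Optional character vector fixing the group order.
#' @return Named character vector: condition -> letter string.
#' @export
letter_display <- function(result, alpha = NULL,
                           group_order = NULL) {
  alpha <- alpha %||% attr(result, "alpha") %||% 0.05
  groups <- group_order %||% unique(c(result$group1, result$group2))
  ns_pairs <- result[result$p_adj > alpha, c("group1", "group2"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = ns_pairs, directed = FALSE,
    vertices = data.frame(name = groups))
  cl <- igraph::max_cliques(g, min = 1)
  cl <- lapply(cl, function(x) igraph::as_ids(x))
  cl <- .minimal_clique_cover(cl, ns_pairs, groups)
  # order letters by the earliest group they contain
  first <- vapply(cl, function(x) min(match(x, groups)), 0)
  cl <- cl[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cl)) {
    for (gname in cl[[k]])
      letters_out[gname] <- paste0(letters_out[gname], letters[k])
  }
  letters_out
}

# Smallest subfamily of maximal cliques covering every non-significant pair
# and every group (exhaustive for small families, greedy fallback): keeps the
# letter count minimal, since any clique extends to a maximal one.
.minimal_clique_cover <- function(cliques, ns_pairs, groups) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  need_edges <- unique(edge_key(ns_pairs$group1, ns_pairs$group2))
  covers <- lapply(cliques, function(cl) {
    if (length(cl) < 2) return(character())
    pr <- utils::combn(cl, 2)
    edge_key(pr[1, ], pr[2, ])
  })
  m <- length(cliques)
  if (m <= 16) {
    best <- seq_len(m)
    for (size in seq_len(m)) {
      if (size >= length(best)) break
      found <- NULL
      for (sel in utils::combn(m, size, simplify = FALSE)) {
        if (all(need_edges %in% unlist(covers[sel])) &&
            all(groups %in% unlist(cliques[sel]))) { found <- sel; break }
      }
      if (!is.null(found)) { best <- found; break }
    }
    return(cliques[best])
  }
  # greedy for larger families
  keep <- integer(); covered_e <- character(); covered_v <- character()
  ord <- order(-lengths(cliques))
  for (i in ord) {
    if (length(setdiff(covers[[i]], covered_e)) ||
        length(setdiff(cliques[[i]], covered_v))) {
      keep <- c(keep, i)
      covered_e <- union(covered_e, covers[[i]])
      covered_v <- union(covered_v, cliques[[i]])
    }
  }
  cliques[sort(keep)]
}

#' Five-number boxplot summary
#'
#' Median and 25th/75th percentiles (linear interpolation between order
#' statistics); whiskers extend to the minimum and maximum.
#'
#' @param values Numeric vector (n >= 1).
#' @return List with `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `n`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop_config("insufficient data: empty group")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(values), whisker_high = max(values),
       n = length(values))
}

#' Boxplot of per-condition pumping rates with significance letters
#'
#' @param per_trace The `per_trace` table from [analyze_traces()].
#' @param letters Optional named letter vector from [letter_display()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_rate_boxes <- function(per_trace, letters = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("plot_rate_boxes requires ggplot2")
  d <- per_trace[per_trace$active, , drop = FALSE]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = condition, y = rate)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = expression(
      "initial pumping rate (" * s^-1 * ")"))
  if (!is.null(letters)) {
    ymax <- tapply(d$rate, d$condition, max)
    lab <- data.frame(condition = names(letters),
                      y = ymax[names(letters)] * 1.07,
                      letter = unname(letters))
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(x = condition, y = y,
                                             label = letter))
  }
  p
}
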