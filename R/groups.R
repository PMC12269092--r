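#' Kruskal-Wallis gated pairwise Mann-Whitney comparisons
#'
#' The comparison protocol used throughout the figures: a Kruskal-Wallis
#' test across groups first; only when it is significant at `alpha` are
#' pairwise two-sided Mann-Whitney U tests run, with significance tiers
#' starred as * (p < 0.05), ** (p < 0.01), *** (p < 0.001) and
#' **** (p < 0.0001). Pairwise p-values are exact for group sizes up to
#' 8 without ties, otherwise normal-approximated with tie correction; no
#' multiple-testing correction is applied (the tiers mirror the raw
#' thresholds of the source protocol).
#'
#' @param data Data frame with a value column and a grouping column.
#' @param value,group Unquoted column names.
#' @param alpha Gate for running pairwise tests.
#' @param min_n Groups with fewer samples are excluded with a warning.
#' @return Object of class `group_comparison`; see [tidy.group_comparison()].
#' @export
compare_groups <- function(data, value, group, alpha = 0.05, min_n = 3) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]
  g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    warn(sprintf("excluding group(s) with < %d samples: %s", min_n,
                 paste(small, collapse = ", ")),
         class = "lakephoto_small_group")
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  groups <- sort(unique(g))
  if (length(groups) < 2) abort_insufficient("need >= 2 usable groups")

  kw <- kruskal.test(v, factor(g))
  pairwise <- tibble(group_a = character(), group_b = character(),
                     u_stat = numeric(), mw_p = numeric(),
                     stars = character())
  if (kw$p.value < alpha) {
    combs <- utils::combn(groups, 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(combs)), function(i) {
      a <- v[g == combs[1, i]]
      b <- v[g == combs[2, i]]
      exact <- length(a) <= 8 && length(b) <= 8 &&
        !any(duplicated(c(a, b)))
      wt <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE))
      tibble(group_a = combs[1, i], group_b = combs[2, i],
             u_stat = unname(wt$statistic), mw_p = wt$p.value,
             stars = p_stars(wt$p.value))
    })
  }
  structure(list(kw_p = kw$p.value, kw_stat = unname(kw$statistic),
                 df = unname(kw$parameter), groups = groups,
                 sizes = as.integer(sizes[groups]), pairwise = pairwise,
                 alpha = alpha),
            class = "group_comparison")
}

p_stars <- function(p) {
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi^2 = %.3f, df = %d, p = %.4g\n",
              x$kw_stat, x$df, x$kw_p))
  if (nrow(x$pairwise)) print(x$pairwise) else
    cat("no pairwise tests (Kruskal-Wallis not significant)\n")
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: the pairwise Mann-Whitney table (empty when the
#'   Kruskal-Wallis gate was not passed). `glance()`: one row with the
#'   Kruskal-Wallis statistic and p.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(kw_stat = x$kw_stat, df = x$df, kw_p = x$kw_p,
         n_groups = length(x$groups), n = sum(x$sizes))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value.
#'
#' @param x,y Paired numeric vectors, n >= 5 after removing missing
#'   pairs.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 5) abort_insufficient("need >= 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input; correlation undefined",
          class = "lakephoto_undefined_correlation")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
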