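#' Two-way fixed-effects ANOVA for morphometric treatments
#'
#' The balanced two-factor decomposition used to compare charring
#' treatments (factor A = temperature condition, factor B = duration):
#' Type I sums of squares via [stats::aov()], which are exact and
#' order-invariant on balanced data. Unbalanced designs are rejected. With
#' a single replicate per cell the additive (no-interaction) model is
#' fitted; the interaction term requires >= 2 replicates per cell.
#'
#' @param values numeric response (e.g. length in mm).
#' @param factor_a,factor_b factors (or coercible), >= 2 levels each.
#' @return an object of class `anova_table`: data.frame with one row per
#'   effect (A, B, A:B when estimable, Residuals) and columns `effect`,
#'   `sum_of_squares`, `df`, `mean_square`, `F`, `p`. Degenerate data (all
#'   values identical) report F = 0, p = 1.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  A <- factor(factor_a)
  B <- factor(factor_b)
  stopifnot(length(values) == length(A), length(values) == length(B))
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop_carposort("both factors need >= 2 levels",
                   class = "carposort_parameter_error")
  cell_n <- table(A, B)
  if (any(cell_n == 0L))
    stop_carposort("empty factor cells: design not estimable",
                   class = "carposort_parameter_error")
  if (length(unique(as.vector(cell_n))) != 1L)
    stop_carposort("unbalanced design: the balanced Type I decomposition does not apply",
                   class = "carposort_parameter_error")
  with_interaction <- all(cell_n >= 2L)
  fml <- if (with_interaction) values ~ A * B else values ~ A + B
  tab <- summary(aov(fml))[[1]]
  eff <- trimws(rownames(tab))
  out <- data.frame(effect = eff, sum_of_squares = tab[["Sum Sq"]],
                    df = tab[["Df"]], mean_square = tab[["Mean Sq"]],
                    F = tab[["F value"]], p = tab[["Pr(>F)"]])
  # all-identical responses: 0/0 F ratios (possibly rounded to noise by the
  # QR decomposition) reported as F = 0, p = 1
  noise_floor <- 1e-20 * (abs(mean(values)) + 1)^2
  bad <- (!is.finite(out$F) | stats::var(values) <= noise_floor) &
    out$effect != "Residuals"
  out$F[bad] <- 0
  out$p[bad] <- 1
  out$F[out$effect == "Residuals"] <- NA
  out$p[out$effect == "Residuals"] <- NA
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey-Kramer all-pairs comparisons
#'
#' Studentized-range test for every pair of group means with the Kramer
#' unequal-n correction: q = |m_i - m_j| / sqrt((MS_within / 2) *
#' (1/n_i + 1/n_j)), compared against the studentized-range distribution
#' with k groups and the residual df. Critical values come from
#' [stats::qtukey()]/[stats::ptukey()], not from printed tables.
#'
#' @param group_means,group_ns numeric vectors (>= 2 groups).
#' @param ms_within residual mean square (> 0).
#' @param df_within residual degrees of freedom (>= 1).
#' @param alpha familywise significance level (default 0.05).
#' @return an object of class `tukey_pairs`: list with symmetric matrices
#'   `q`, `p_value`, `significant`, plus `alpha`, `critical_q`.
#' @export
tukey_kramer <- function(group_means, group_ns, ms_within, df_within,
                         alpha = 0.05) {
  k <- length(group_means)
  stopifnot(length(group_ns) == k)
  if (k < 2L)
    stop_carposort("need >= 2 groups", class = "carposort_parameter_error")
  if (ms_within <= 0)
    stop_carposort("ms_within must be > 0",
                   class = "carposort_parameter_error")
  if (df_within < 1)
    stop_carposort("df_within must be >= 1",
                   class = "carposort_parameter_error")
  nm <- names(group_means) %||% paste0("g", seq_len(k))
  q <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((ms_within / 2) * (1 / group_ns[i] + 1 / group_ns[j]))
    q[i, j] <- q[j, i] <- abs(group_means[i] - group_means[j]) / se
  }
  p <- ptukey(q, nmeans = k, df = df_within, lower.tail = FALSE)
  diag(p) <- 1
  sig <- p < alpha
  diag(sig) <- FALSE
  structure(list(q = q, p_value = p, significant = sig, alpha = alpha,
                 critical_q = qtukey(1 - alpha, nmeans = k,
                                     df = df_within)),
            class = "tukey_pairs")
}

#' @export
print.tukey_pairs <- function(x, ...) {
  cat(sprintf("<tukey_pairs> %d groups, alpha %g, critical q %.3f, %d significant pairs\n",
              nrow(x$q), x$alpha, x$critical_q, sum(x$significant) / 2))
  invisible(x)
}

#' Compact letter display from pairwise significances
#'
#' Insert-and-absorb letter assignment: starting from one letter covering
#' all groups, each significant pair splits every letter set containing
#' both members into two sets (one without each member), after which sets
#' contained in another are absorbed. The result satisfies, exactly: two
#' groups share at least one letter if and only if their comparison is
#' non-significant. Letters are assigned in the supplied group order.
#'
#' @param significant symmetric logical matrix of pairwise significance
#'   (TRUE = means differ), e.g. `tukey_kramer(...)$significant`.
#' @param group_order optional ordering of groups for letter assignment
#'   (indices or names); default as given.
#' @return an object of class `tukey_letters`: data.frame with `group` and
#'   `letters` (e.g. "A", "BC").
#' @export
compact_letters <- function(significant, group_order = NULL) {
  sig <- as.matrix(significant)
  k <- nrow(sig)
  stopifnot(ncol(sig) == k, isTRUE(all(sig == t(sig))))
  nm <- rownames(sig) %||% paste0("g", seq_len(k))
  ord <- group_order %||% seq_len(k)
  if (is.character(ord)) ord <- match(ord, nm)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
    if (!any(hit)) next
    new_sets <- sets[!hit]
    for (s in sets[hit]) {
      new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (p in seq_along(new_sets)) for (q in seq_along(new_sets)) {
      if (p != q && keep[p] && keep[q] &&
            all(new_sets[[p]] %in% new_sets[[q]]) &&
            (length(new_sets[[p]]) < length(new_sets[[q]]) || p > q))
        keep[p] <- FALSE
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letter sets by the first (in group_order) member they contain
  pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(pos)]
  letter_of <- function(idx) paste0(LETTERS[(idx - 1) %% 26 + 1],
                                    ifelse(idx > 26, (idx - 1) %/% 26, ""))
  labels <- vapply(seq_len(k), function(g) {
    which_sets <- which(vapply(sets, function(s) g %in% s, logical(1)))
    paste(letter_of(which_sets), collapse = "")
  }, character(1))
  structure(data.frame(group = nm, letters = labels),
            class = c("tukey_letters", "data.frame"))
}

#' Group means with compact letters, from raw data
#'
#' Convenience wrapper reproducing the familiar "mean +/- SD with letters"
#' summary: one-way group structure, pooled within-group mean square, the
#' Tukey-Kramer test, and the compact letter display.
#'
#' @param values numeric response.
#' @param groups grouping factor.
#' @param alpha significance level.
#' @return data.frame with `group`, `n`, `mean`, `sd`, `letters`.
#' @export
letter_summary <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  sds <- tapply(values, g, sd)
  df_w <- length(values) - nlevels(g)
  ms_w <- sum((values - means[g])^2) / df_w
  tk <- tukey_kramer(means, ns, ms_w, df_w, alpha)
  cl <- compact_letters(tk$significant)
  data.frame(group = levels(g), n = as.integer(ns), mean = as.numeric(means),
             sd = as.numeric(sds), letters = cl$letters, row.names = NULL)
}
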