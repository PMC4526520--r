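# Statistical contrasts: depth-stratified ANOVA with Tukey HSD compact
# letters, paired treatment/control tests on delta-Cp, the three-way
# factorial GLM on fold changes, and paired Wilcoxon tests.

# Compact letter display by greedy grouping over the sorted group
# means: two groups share a letter iff their Tukey-adjusted p-value
# exceeds alpha. Deterministic; ties broken toward the lower mean.
.tukey_letters <- function(means, pmat, alpha = 0.05) {
  g <- names(means)
  ord <- order(means)
  groups <- list()  # each element: character vector of group names
  for (gi in g[ord]) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(pmat[gi, groups[[k]]] > alpha)) {
        groups[[k]] <- c(groups[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- gi
  }
  # drop letter-groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (k in seq_along(groups)) for (j in seq_along(groups)) {
    if (k != j && keep[k] && keep[j] && all(groups[[k]] %in% groups[[j]]) &&
        length(groups[[k]]) < length(groups[[j]])) keep[k] <- FALSE
  }
  groups <- groups[keep]
  lett <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(groups)) {
    for (gi in groups[[k]]) lett[gi] <- paste0(lett[gi], letters[k])
  }
  lett
}

#' Depth-stratified ANOVA with Tukey HSD letters
#'
#' One-way ANOVA of relative expression across depth classes for each
#' gene x clade, with Kolmogorov-Smirnov (Lilliefors) normality
#' checks, Tukey HSD post-hoc comparisons and a compact letter
#' display: depth classes sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param quant Data frame with columns `depth_class`, the response
#'   column, and grouping columns `gene` and `clade` (or a single
#'   `target`); typically built from [quantify_samples()] output
#'   joined to sample metadata.
#' @param response Name of the response column (default `"rel_expr"`).
#' @param log2_response Analyse `log2(response)` instead of the raw
#'   response (default FALSE).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `"depth_anova"` of per-assay results, each
#'   with `gene`, `clade`, `group_means`, `f_value`, `p_value`,
#'   `normality_p` (Lilliefors), `tukey` (adjusted p matrix) and
#'   `letters`. Assays with fewer than 2 groups of >= 3 records are
#'   skipped with a message; zero-variance assays are returned
#'   `degenerate`.
#' @export
depth_anova <- function(quant, response = "rel_expr", log2_response = FALSE,
                        alpha = 0.05) {
  if (!"gene" %in% names(quant)) quant$gene <- quant$target
  if (!"clade" %in% names(quant)) quant$clade <- ""
  need <- c("depth_class", response)
  miss <- setdiff(need, names(quant))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(quant$gene, quant$clade, drop = TRUE)
  out <- lapply(split(quant, key), function(d) {
    y <- d[[response]]
    if (log2_response) y <- log2(y)
    grp <- factor(d$depth_class)
    sizes <- table(grp)
    if (sum(sizes >= 3) < 2) {
      message("skipping ", d$gene[1], "-", d$clade[1],
              ": need >= 2 depth classes with >= 3 records")
      return(NULL)
    }
    res <- list(gene = d$gene[1], clade = d$clade[1],
                group_means = tapply(y, grp, mean),
                n = as.vector(sizes), degenerate = FALSE)
    if (stats::var(y) == 0) {
      res$degenerate <- TRUE
      res$f_value <- 0; res$p_value <- NA_real_
      res$letters <- stats::setNames(rep("a", nlevels(grp)), levels(grp))
      return(res)
    }
    res$normality_p <- tryCatch(nortest::lillie.test(stats::residuals(
      stats::aov(y ~ grp)))$p.value, error = function(e) NA_real_)
    fit <- stats::aov(y ~ grp)
    tab <- summary(fit)[[1L]]
    res$f_value <- tab[["F value"]][1L]
    res$p_value <- tab[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
    lv <- levels(grp)
    pmat <- matrix(1, nlevels(grp), nlevels(grp), dimnames = list(lv, lv))
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1L]]
      pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- tk[r, "p adj"]
    }
    res$tukey <- pmat
    res$letters <- .tukey_letters(res$group_means, pmat, alpha)
    res
  })
  structure(Filter(Negate(is.null), out), class = "depth_anova")
}

#' Paired treatment/control ratio test
#'
#' Paired t-test on delta-Cp differences between treatment and
#' control, reported together with the per-pair fold changes
#' \eqn{2^{\Delta Cp_T - \Delta Cp_C}}: their arithmetic mean and sd
#' (the tabulated treatment/control ratio), the geometric mean fold
#' \eqn{2^{\overline{\Delta\Delta Cp}}} and its 95% confidence
#' interval from the t distribution.
#'
#' @param dcp_treatment,dcp_control Paired delta-Cp vectors of equal
#'   length (>= 2 complete pairs); incomplete pairs are dropped.
#' @param gene Optional label.
#' @return An object of class `"paired_ratio_test"`: `gene`,
#'   `n_pairs`, `mean_ratio`, `sd_ratio`, `geo_mean_ratio`,
#'   `ratio_ci` (length 2), `t_statistic`, `df` (= n_pairs - 1), `p_value`.
#' @export
paired_ratio_test <- function(dcp_treatment, dcp_control,
                              gene = NA_character_) {
  if (length(dcp_treatment) != length(dcp_control))
    stop("unpaired records: treatment and control must have equal length")
  ok <- is.finite(dcp_treatment) & is.finite(dcp_control)
  dt <- dcp_treatment[ok]; dc <- dcp_control[ok]
  n <- length(dt)
  if (n < 2) stop("need at least 2 complete pairs")
  ratios <- 2^(dt - dc)
  tt <- stats::t.test(dt, dc, paired = TRUE)
  structure(list(gene = gene, n_pairs = n,
                 mean_ratio = mean(ratios), sd_ratio = stats::sd(ratios),
                 geo_mean_ratio = 2^mean(dt - dc),
                 ratio_ci = 2^tt$conf.int,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "paired_ratio_test")
}

#' @export
print.paired_ratio_test <- function(x, ...) {
  cat(sprintf("<paired_ratio_test>%s ratio %.2f +/- %.2f (n %d, t %.3f, df %d, p %.3g)\n",
              if (!is.na(x$gene)) paste0(" ", x$gene, ":") else "",
              x$mean_ratio, x$sd_ratio, x$n_pairs, x$t_statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Three-way factorial GLM on fold changes
#'
#' Factorial ANOVA (general linear model) of the per-pair fold-change
#' response on the fixed two-level factors Treatment, Strain and Time
#' with all two- and three-way interactions (1 df each on a balanced
#' design). Significance stars follow the usual
#' 0.05/0.01/0.001 convention. On a balanced design the term F values
#' are invariant to factor ordering; with unbalanced data the
#' sequential (type I) sums of squares convention is recorded in the
#' result.
#'
#' @param fold Numeric fold-change response (one value per
#'   treatment/control pair).
#' @param factors Data frame with columns `treatment`, `strain`,
#'   `time` (two levels each), same length as `fold`; every design
#'   cell must be populated.
#' @param log2_response Analyse `log2(fold)` (default FALSE, matching
#'   the raw-fold-change table semantics).
#' @return An object of class `"glm_table"`: data frame `term`, `df`,
#'   `f_value`, `p_value`, `stars`, plus attributes `response` and
#'   `ss_type`.
#' @export
exposure_glm <- function(fold, factors, log2_response = FALSE) {
  need <- c("treatment", "strain", "time")
  miss <- setdiff(need, names(factors))
  if (length(miss)) stop("missing factors: ", paste(miss, collapse = ", "))
  if (nrow(factors) != length(fold)) stop("`fold` and `factors` lengths differ")
  d <- data.frame(fold = if (log2_response) log2(fold) else fold,
                  Treatment = factor(factors$treatment),
                  Strain = factor(factors$strain),
                  Time = factor(factors$time))
  cells <- table(d$Treatment, d$Strain, d$Time)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: Treatment=%s, Strain=%s, Time=%s",
                 dimnames(cells)[[1L]][idx[1L]], dimnames(cells)[[2L]][idx[2L]],
                 dimnames(cells)[[3L]][idx[3L]]))
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  fit <- stats::aov(fold ~ Treatment * Strain * Time, data = d)
  tab <- summary(fit)[[1L]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  fv <- tab[["F value"]][keep]
  pv <- tab[["Pr(>F)"]][keep]
  if (stats::var(d$fold) == 0) { fv <- rep(0, sum(keep)); pv <- rep(NA_real_, sum(keep)) }
  stars <- ifelse(is.na(pv), "",
                  ifelse(pv < 0.001, "***",
                         ifelse(pv < 0.01, "**", ifelse(pv < 0.05, "*", ""))))
  out <- data.frame(term = terms[keep], df = tab$Df[keep],
                    f_value = fv, p_value = pv, stars = stars,
                    stringsAsFactors = FALSE)
  attr(out, "response") <- if (log2_response) "log2 fold change" else "fold change"
  attr(out, "ss_type") <- if (balanced) "balanced (type I = II = III)"
                          else "sequential (type I)"
  class(out) <- c("glm_table", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Nonparametric paired comparison (e.g. treatment versus control cell
#' concentrations).
#'
#' @param x,y Paired numeric vectors (>= 2 complete pairs).
#' @return The `htest` object from [stats::wilcox.test()] with
#'   `paired = TRUE` (exact where ties permit).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y))
    stop("unpaired records: x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) stop("need at least 2 complete pairs")
  if (all(x[ok] == y[ok])) {
    # all differences zero: no evidence of a shift in either direction
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed rank test",
                          alternative = "two.sided",
                          data.name = "x and y (all pairs tied)"),
                     class = "htest"))
  }
  stats::wilcox.test(x[ok], y[ok], paired = TRUE)
}
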