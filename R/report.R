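# Headline survey report and simple diagnostic plots.

#' Headline survey report from a Cp summary table
#'
#' Recomputes the survey's headline quantities from per-depth mean Cp
#' values: the HL clade fraction at each depth class (from the
#' reference-gene rnpB Cp means via [clade_fraction()]) and the
#' between-depth fold ratios of relative expression (HL genes, surface
#' over DCM+40; LL rbcL, DCM and DCM+40 over surface) via
#' [fold_change()]. Raw fold values are retained; the print method
#' additionally shows them rounded to the nearest integer fold.
#'
#' @param cp_summary Data frame as from [read_cp_summary()]:
#'   `target, depth_class, mean_cp` (targets `<gene>-<clade>`, depth
#'   classes `3m`, `DCM`, `DCM+40`).
#' @param reference_gene Reference gene (default `"rnpB"`).
#' @return An object of class `"survey_report"`: list with
#'   `clade_fractions` (data frame `depth_class, fraction_HL,
#'   pct_HL`), `depth_ratios` (data frame `gene, clade, contrast,
#'   fold, fold_rounded`).
#' @examples
#' tab <- read_cp_summary(system.file("extdata", "survey_cp_summary.csv",
#'                                    package = "cladeqpcr"))
#' survey_report(tab)
#' @export
survey_report <- function(cp_summary, reference_gene = "rnpB") {
  need <- c("target", "depth_class", "mean_cp")
  miss <- setdiff(need, names(cp_summary))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cp <- function(target, depth) {
    v <- cp_summary$mean_cp[cp_summary$target == target &
                              cp_summary$depth_class == depth]
    if (length(v)) v[1L] else NA_real_
  }
  depths <- c("3m", "DCM", "DCM+40")
  fr <- vapply(depths, function(d) {
    clade_fraction(cp(paste0(reference_gene, "-HL"), d),
                   cp(paste0(reference_gene, "-LL"), d))$fraction_HL
  }, numeric(1))
  fractions <- data.frame(depth_class = depths, fraction_HL = fr,
                          pct_HL = round(100 * fr), stringsAsFactors = FALSE)

  dcp <- function(gene, clade, depth) {
    delta_cp(cp(paste0(reference_gene, "-", clade), depth),
             cp(paste0(gene, "-", clade), depth))
  }
  contrasts <- list(
    list(gene = "rbcL", clade = "HL", a = "3m", b = "DCM+40"),
    list(gene = "psbA", clade = "HL", a = "3m", b = "DCM+40"),
    list(gene = "rbcL", clade = "LL", a = "DCM", b = "3m"),
    list(gene = "rbcL", clade = "LL", a = "DCM+40", b = "3m")
  )
  ratios <- do.call(rbind, lapply(contrasts, function(ct) {
    f <- fold_change(dcp(ct$gene, ct$clade, ct$a), dcp(ct$gene, ct$clade, ct$b),
                     gene = ct$gene,
                     context = paste(ct$a, "vs", ct$b))
    data.frame(gene = ct$gene, clade = ct$clade,
               contrast = paste(ct$a, "vs", ct$b),
               fold = f$value, fold_rounded = round(f$value),
               stringsAsFactors = FALSE)
  }))
  structure(list(clade_fractions = fractions, depth_ratios = ratios),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("HL clade fraction of total Prochlorococcus (from rnpB Cp means):\n")
  for (i in seq_len(nrow(x$clade_fractions)))
    cat(sprintf("  %-7s %5.1f%%  (reported as %d%%)\n",
                x$clade_fractions$depth_class[i],
                100 * x$clade_fractions$fraction_HL[i],
                x$clade_fractions$pct_HL[i]))
  cat("Between-depth expression ratios (2^(dCp_a - dCp_b)):\n")
  for (i in seq_len(nrow(x$depth_ratios)))
    cat(sprintf("  %s-%s %-14s %5.2f-fold (~%dx)\n",
                x$depth_ratios$gene[i], x$depth_ratios$clade[i],
                x$depth_ratios$contrast[i], x$depth_ratios$fold[i],
                x$depth_ratios$fold_rounded[i]))
  invisible(x)
}

#' Box plot of relative expression by depth class
#'
#' Range/quartile/median box summaries of relative expression per
#' depth class (outliers beyond 1.5 x IQR drawn as circles, the
#' standard convention), one panel per assay.
#'
#' @param quant Data frame with `depth_class`, a response column and
#'   `gene`/`clade` (or `target`) columns.
#' @param response Response column name (default `"rel_expr"`).
#' @param log2_response Plot on the log2 scale (default TRUE).
#' @return Invisibly, the list of per-assay boxplot statistics.
#' @export
plot_depth_expression <- function(quant, response = "rel_expr",
                                  log2_response = TRUE) {
  if (!"gene" %in% names(quant)) quant$gene <- quant$target
  if (!"clade" %in% names(quant)) quant$clade <- ""
  key <- interaction(quant$gene, quant$clade, drop = TRUE)
  panels <- split(quant, key)
  old <- graphics::par(mfrow = c(1, length(panels)))
  on.exit(graphics::par(old))
  out <- lapply(panels, function(d) {
    y <- d[[response]]
    if (log2_response) y <- log2(y)
    graphics::boxplot(y ~ factor(d$depth_class),
                      main = paste0(d$gene[1], "-", d$clade[1]),
                      xlab = "depth class",
                      ylab = if (log2_response)
                        paste0("log2 ", response) else response,
                      range = 1.5)
  })
  invisible(out)
}

#' Scatter plot of melting temperature against Cp
#'
#' Diagnostic view of amplicon heterogeneity: each sample's major-peak
#' Tm against its Cp, coloured by depth class.
#'
#' @param tm Numeric Tm values (degrees C).
#' @param cp Numeric Cp values (cycles).
#' @param depth_class Factor/character of depth classes (colours).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_tm_vs_cp <- function(tm, cp, depth_class = NULL, ...) {
  col <- if (is.null(depth_class)) 1L else as.integer(factor(depth_class))
  graphics::plot(cp, tm, col = col, pch = 19, xlab = "Cp (cycles)",
                 ylab = "Tm (°C)", ...)
  if (!is.null(depth_class))
    graphics::legend("topright", legend = levels(factor(depth_class)),
                     col = seq_along(levels(factor(depth_class))), pch = 19)
  invisible(NULL)
}
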