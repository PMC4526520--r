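# Delta-Cp expression algebra: relative expression, fold changes,
# rbcL/psbA ratios and HL/LL clade fractions.

#' Reference-normalized delta-Cp
#'
#' \eqn{\Delta Cp = Cp_{ref} - Cp_{target}}, with the reference gene
#' (rnpB) correcting for differential cell concentration and sample
#' processing. Higher values mean more target relative to the
#' reference; relative expression is \eqn{2^{\Delta Cp}}.
#'
#' @param cp_ref,cp_target Crossing points in cycles. `NA` (censored)
#'   inputs propagate to `NA`.
#' @return Delta-Cp in cycles.
#' @examples
#' delta_cp(20.98, 21.09)  # -0.11
#' @export
delta_cp <- function(cp_ref, cp_target) {
  ifelse(is.na(cp_ref) | is.na(cp_target), NA_real_, cp_ref - cp_target)
}

#' Fold change between two delta-Cp values
#'
#' Copy-number ratio between conditions a and b,
#' \eqn{2^{\Delta Cp_a - \Delta Cp_b}} (e.g. treatment over control,
#' or one depth class over another). A 10-cycle offset corresponds to
#' a ~1000-fold difference.
#'
#' @param dcp_a,dcp_b Delta-Cp values in cycles (`NA` propagates).
#' @param gene,context Optional labels carried on the result.
#' @return An object of class `"fold_change"`: `gene`, `context`,
#'   `value`, `log2_value`.
#' @examples
#' fold_change(10, 0)$value  # 1024 (~1000-fold)
#' @export
fold_change <- function(dcp_a, dcp_b, gene = NA_character_,
                        context = NA_character_) {
  l2 <- ifelse(is.na(dcp_a) | is.na(dcp_b), NA_real_, dcp_a - dcp_b)
  structure(list(gene = gene, context = context,
                 value = 2^l2, log2_value = l2),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change>%s %.4g (log2 %.3f)%s\n",
              if (!is.na(x$gene)) paste0(" ", x$gene, ":") else "",
              x$value, x$log2_value,
              if (!is.na(x$context)) paste0(" [", x$context, "]") else ""))
  invisible(x)
}

#' rbcL to psbA expression ratio
#'
#' Copy ratio between the two photosynthetic target genes,
#' \eqn{2^{\Delta Cp_{rbcL} - \Delta Cp_{psbA}}}; a sensitive index of
#' the balance between carbon fixation capacity and photosystem II
#' content.
#'
#' @param dcp_rbcl,dcp_psba Delta-Cp values for rbcL and psbA.
#' @param context Optional label.
#' @return A `"fold_change"` object with `gene = "rbcL/psbA"`.
#' @export
rbcl_psba_ratio <- function(dcp_rbcl, dcp_psba, context = NA_character_) {
  fold_change(dcp_rbcl, dcp_psba, gene = "rbcL/psbA", context = context)
}

#' High-light clade fraction from reference-gene Cp values
#'
#' Treats the reference-gene (rnpB) signal as a direct indicator of
#' metabolically active cells per clade: with initial copies
#' \eqn{N_0 = k (1+E)^{-Cp}} and a common detection constant k, the
#' HL:LL copy ratio is
#' \eqn{r = (1+E_{HL})^{-Cp_{HL}} / (1+E_{LL})^{-Cp_{LL}}}, which at
#' equal 100% efficiencies reduces to \eqn{r = 2^{Cp_{LL}-Cp_{HL}}},
#' and the HL fraction is \eqn{r/(1+r)}. `fraction_HL + fraction_LL`
#' is 1 by construction; equal Cp values give 0.5.
#'
#' @param cp_hl,cp_ll Reference-gene Cp for the HL and LL primer sets
#'   (cycles; `NA` propagates with `undefined = TRUE`).
#' @param efficiency_hl,efficiency_ll Per-clade amplification
#'   efficiencies (default 1, i.e. perfect doubling).
#' @param sample_id Optional label.
#' @return An object of class `"clade_fraction"`: `sample_id`,
#'   `cp_rnpB_HL`, `cp_rnpB_LL`, `fraction_HL`, `fraction_LL`,
#'   `assumes_equal_efficiency` (TRUE when both efficiencies are
#'   equal; the equal per-cell reference expression assumption always
#'   applies), `undefined`.
#' @examples
#' clade_fraction(20.98, 26.00)$fraction_HL  # 0.970
#' @export
clade_fraction <- function(cp_hl, cp_ll, efficiency_hl = 1, efficiency_ll = 1,
                           sample_id = NA_character_) {
  if (efficiency_hl <= 0 || efficiency_ll <= 0)
    stop("efficiencies must be > 0")
  undefined <- is.na(cp_hl) || is.na(cp_ll)
  if (undefined) {
    fr <- NA_real_
  } else {
    log2r <- cp_ll * log2(1 + efficiency_ll) - cp_hl * log2(1 + efficiency_hl)
    r <- 2^log2r
    fr <- if (is.infinite(r)) 1 else r / (1 + r)
  }
  structure(list(sample_id = sample_id, cp_rnpB_HL = cp_hl,
                 cp_rnpB_LL = cp_ll, fraction_HL = fr,
                 fraction_LL = 1 - fr,
                 assumes_equal_efficiency = efficiency_hl == efficiency_ll,
                 undefined = undefined),
            class = "clade_fraction")
}

#' @export
print.clade_fraction <- function(x, ...) {
  if (x$undefined) cat("<clade_fraction> undefined (censored input)\n")
  else cat(sprintf("<clade_fraction> HL %.1f%% / LL %.1f%%\n",
                   100 * x$fraction_HL, 100 * x$fraction_LL))
  invisible(x)
}

#' Quantification records from merged Cp calls
#'
#' Joins merged Cp calls (long: one row per sample x target, targets
#' named `<gene>-<clade>`) into per-sample, per-clade quantification
#' records with delta-Cp, relative expression, the rbcL/psbA ratio,
#' and the HL clade fraction where both clades' reference Cp values
#' are available.
#'
#' @param cp_calls Data frame `sample_id, target, cp` (censored rows
#'   carry `cp = NA`), e.g. from [call_cp_table()] or a survey
#'   simulation.
#' @param reference_gene Reference gene name (default `"rnpB"`).
#' @return Data frame `sample_id, clade, delta_cp_rbcL, delta_cp_psbA,
#'   rel_rbcL, rel_psbA, ratio, fraction_HL, included` (the QC flag is
#'   all-TRUE here and refined by [apply_quant_filters()]).
#' @export
quantify_samples <- function(cp_calls, reference_gene = "rnpB") {
  need <- c("sample_id", "target", "cp")
  miss <- setdiff(need, names(cp_calls))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  parts <- strsplit(as.character(cp_calls$target), "-", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1L)
  clade <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                  character(1))
  d <- data.frame(sample_id = cp_calls$sample_id, gene = gene, clade = clade,
                  cp = cp_calls$cp, stringsAsFactors = FALSE)
  # average duplicate rows (e.g. unmerged replicates)
  d <- stats::aggregate(cp ~ sample_id + gene + clade, data = d,
                        FUN = mean, na.action = stats::na.pass)
  get_cp <- function(s, g, cl) {
    v <- d$cp[d$sample_id == s & d$gene == g & d$clade == cl]
    if (length(v)) v[1L] else NA_real_
  }
  combos <- unique(d[c("sample_id", "clade")])
  combos <- combos[!is.na(combos$clade), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$sample_id[i]; cl <- combos$clade[i]
    ref <- get_cp(s, reference_gene, cl)
    drb <- delta_cp(ref, get_cp(s, "rbcL", cl))
    dps <- delta_cp(ref, get_cp(s, "psbA", cl))
    fr <- if (cl == "HL") {
      cf <- clade_fraction(get_cp(s, reference_gene, "HL"),
                           get_cp(s, reference_gene, "LL"), sample_id = s)
      cf$fraction_HL
    } else NA_real_
    data.frame(sample_id = s, clade = cl,
               delta_cp_rbcL = drb, delta_cp_psbA = dps,
               rel_rbcL = 2^drb, rel_psbA = 2^dps,
               ratio = 2^(drb - dps), fraction_HL = fr,
               included = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the single-peak and replicate-agreement quantification filters
#'
#' Marks each quantification record as included only when (a) every
#' constituent target of the record's clade has a single-peak melt
#' profile (amplifications with multiple melt peaks denote multiple
#' products and are not quantified) and (b) no constituent Cp call
#' failed replicate QC. Records are never deleted; exclusion reasons
#' are recorded.
#'
#' @param records Data frame from [quantify_samples()].
#' @param melt_profiles Data frame `sample_id, target, profile_class`
#'   (e.g. from [melt_profile_table()]); a missing profile for a
#'   constituent target excludes the record with reason
#'   `missing_melt_profile`.
#' @param cp_calls Optional data frame `sample_id, target, qc_flags`
#'   (semicolon-joined) used for replicate QC.
#' @return `records` with updated `included` and an
#'   `exclusion_reason` column (`NA` when included).
#' @export
apply_quant_filters <- function(records, melt_profiles, cp_calls = NULL) {
  stopifnot(all(c("sample_id", "clade") %in% names(records)))
  if (!all(c("sample_id", "target", "profile_class") %in% names(melt_profiles)))
    stop("`melt_profiles` needs columns sample_id, target, profile_class")
  records$exclusion_reason <- NA_character_
  for (i in seq_len(nrow(records))) {
    s <- records$sample_id[i]
    targs <- paste0(c("rnpB", "rbcL", "psbA"), "-", records$clade[i])
    reason <- NA_character_
    for (tg in targs) {
      m <- melt_profiles$profile_class[melt_profiles$sample_id == s &
                                         melt_profiles$target == tg]
      if (!length(m)) { reason <- "missing_melt_profile"; break }
      if (any(m != "single")) { reason <- "single_peak_rule"; break }
    }
    if (is.na(reason) && !is.null(cp_calls)) {
      fl <- cp_calls$qc_flags[cp_calls$sample_id == s &
                                cp_calls$target %in% targs]
      if (any(grepl("replicate_disagreement", fl)))
        reason <- "replicate_disagreement"
    }
    if (!is.na(reason)) {
      records$included[i] <- FALSE
      records$exclusion_reason[i] <- reason
    }
  }
  records
}
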