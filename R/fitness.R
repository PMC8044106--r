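#' Relative fitness from a pairwise competition (as-printed estimator)
#'
#' Computes W_A = [ln(CFU_A_48h) / ln(CFU_A_start)] /
#' [ln(CFU_B_48h) / ln(CFU_B_start)] — a ratio of the two strains'
#' log-CFU ratios, implemented exactly as the study defines it (note this is
#' a ratio of logs of absolute counts, not a Malthusian growth-rate ratio;
#' see [malthusian_fitness()] for the latter).
#'
#' @param cfu_a_start,cfu_a_48h,cfu_b_start,cfu_b_48h total viable CFU counts,
#'   all > 1 (each enters a logarithm that must be positive and nonzero).
#' @return W_A, dimensionless.
#' @export
relative_fitness <- function(cfu_a_start, cfu_a_48h, cfu_b_start, cfu_b_48h) {
  vals <- c(cfu_a_start = cfu_a_start, cfu_a_48h = cfu_a_48h,
            cfu_b_start = cfu_b_start, cfu_b_48h = cfu_b_48h)
  bad <- names(vals)[vals <= 1]
  if (length(bad))
    stop("relative_fitness(): undefined for ", paste(bad, collapse = ", "),
         " <= 1 (logs must be positive and nonzero)")
  (log(cfu_a_48h) / log(cfu_a_start)) / (log(cfu_b_48h) / log(cfu_b_start))
}

#' Malthusian relative fitness (alternative estimator, never used in
#' acceptance tests)
#'
#' W_A = ln(CFU_A_48h / CFU_A_start) / ln(CFU_B_48h / CFU_B_start): the usual
#' ratio of realised Malthusian parameters. Provided for comparison with the
#' as-printed estimator of [relative_fitness()].
#'
#' @inheritParams relative_fitness
#' @export
malthusian_fitness <- function(cfu_a_start, cfu_a_48h, cfu_b_start, cfu_b_48h) {
  if (any(c(cfu_a_start, cfu_a_48h, cfu_b_start, cfu_b_48h) <= 0))
    stop("malthusian_fitness(): CFU counts must be > 0")
  log(cfu_a_48h / cfu_a_start) / log(cfu_b_48h / cfu_b_start)
}

#' Sporulation fitness from a pairwise competition
#'
#' SF_A = [spores_A_48h / (cells+spores)_A_start] /
#' [spores_B_48h / (cells+spores)_B_start]: spore yield per inoculated cell,
#' strain A relative to strain B.
#'
#' @param spores_a_48h,spores_b_48h heat-resistant CFU at 48 h.
#' @param cfu_a_start,cfu_b_start total (cells + spores) CFU at inoculation.
#' @return SF_A, dimensionless.
#' @export
sporulation_fitness <- function(spores_a_48h, cfu_a_start,
                                spores_b_48h, cfu_b_start) {
  if (cfu_a_start <= 0 || cfu_b_start <= 0)
    stop("sporulation_fitness(): undefined for zero start CFU")
  if (spores_b_48h <= 0)
    stop("sporulation_fitness(): undefined for spores_b_48h <= 0")
  (spores_a_48h / cfu_a_start) / (spores_b_48h / cfu_b_start)
}

#' Split permissive/selective plate counts into evolved and ancestor CFU
#'
#' In evolved-vs-ancestor competitions the evolved strain carries a
#' chloramphenicol marker: LB plates grow both competitors, LB+chl only the
#' evolved one. So evolved = CFU(LB+chl) and ancestor = CFU(LB) - CFU(LB+chl),
#' truncated at zero (negative differences are plating noise and are flagged,
#' not raised).
#'
#' @param cfu_lb CFU on permissive plates.
#' @param cfu_lb_chl CFU on selective plates.
#' @return list(evolved, ancestor, flagged) — \code{flagged} is TRUE when the
#'   selective count exceeded the permissive count.
#' @export
split_plate_counts <- function(cfu_lb, cfu_lb_chl) {
  if (cfu_lb < 0 || cfu_lb_chl < 0)
    stop("split_plate_counts(): counts must be >= 0")
  flagged <- cfu_lb_chl > cfu_lb
  if (flagged)
    warning("split_plate_counts(): selective count exceeds permissive count ",
            "(plating noise); ancestor truncated at 0")
  list(evolved = cfu_lb_chl,
       ancestor = max(cfu_lb - cfu_lb_chl, 0),
       flagged = flagged)
}

#' One-sample inference on replicate fitness values
#'
#' Replicate W (or SF) values are log10-transformed and tested against 0
#' (i.e. against W = 1) with a two-sided one-sample t-test. Normality of the
#' log values is checked with a Shapiro-Wilk test at alpha = 0.05; a failure
#' is reported as a caveat but does not suppress the t-test, matching how the
#' study reports the analysis. Significance stars use the thresholds
#' 0.05 / 0.005 / 0.001.
#'
#' @param values numeric vector of W or SF replicate values (> 0), n >= 3.
#' @return a \code{fitness_result} list: n, mean_log10, arithmetic_mean,
#'   geometric_mean, t_statistic, p_value, stars, shapiro_p, normality_ok,
#'   degenerate.
#' @export
fitness_inference <- function(values) {
  if (length(values) < 3)
    stop("fitness_inference(): need at least 3 replicates, got ",
         length(values))
  if (any(values <= 0))
    stop("fitness_inference(): fitness values must be > 0 to log-transform")
  lv <- log10(values)
  degenerate <- isTRUE(all.equal(sd(lv), 0)) || sd(lv) == 0
  if (degenerate) {
    res <- list(t_statistic = NA_real_, p_value = NA_real_,
                shapiro_p = NA_real_, normality_ok = NA)
  } else {
    sw <- shapiro.test(lv)
    tt <- t.test(lv, mu = 0)
    res <- list(t_statistic = unname(tt$statistic),
                p_value = tt$p.value,
                shapiro_p = sw$p.value,
                normality_ok = sw$p.value >= 0.05)
  }
  structure(c(list(n = length(values),
                   mean_log10 = mean(lv),
                   arithmetic_mean = mean(values),
                   geometric_mean = 10^mean(lv)),
              res,
              list(stars = significance_stars(res$p_value),
                   degenerate = degenerate)),
            class = "fitness_result")
}

#' Map a p-value to the study's significance stars
#'
#' Thresholds: * P < 0.05, ** P < 0.005, *** P < 0.001; "ns" otherwise or for
#' degenerate tests.
#' @param p p-value (NA allowed).
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(
    "fitness_result: n=%d  geometric mean=%.4f  t=%s  p=%s  %s%s\n",
    x$n, x$geometric_mean,
    if (is.na(x$t_statistic)) "NA" else sprintf("%.3f", x$t_statistic),
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    x$stars,
    if (x$degenerate) "  [degenerate: zero variance]"
    else if (!isTRUE(x$normality_ok)) "  [caveat: Shapiro-Wilk p < 0.05]"
    else ""))
  invisible(x)
}

#' Read a competition table and compute per-pair fitness
#'
#' Expects a tab-separated table with the columns of a competition record:
#' strain_a, strain_b, replicate, cfu_a_start, cfu_b_start, cfu_a_48h,
#' cfu_b_48h, spores_a_48h, spores_b_48h. Returns the table with W and SF
#' columns appended.
#'
#' @param path TSV path.
#' @export
read_competition_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_a", "strain_b", "cfu_a_start", "cfu_b_start",
            "cfu_a_48h", "cfu_b_48h", "spores_a_48h", "spores_b_48h")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("competition table missing column(s): ", paste(miss, collapse = ", "))
  tab$W <- mapply(relative_fitness, tab$cfu_a_start, tab$cfu_a_48h,
                  tab$cfu_b_start, tab$cfu_b_48h)
  tab$SF <- mapply(sporulation_fitness, tab$spores_a_48h, tab$cfu_a_start,
                   tab$spores_b_48h, tab$cfu_b_start)
  tab
}

#' CFU bookkeeping helper: colonies on a plate to CFU per ml
#'
#' @param colonies colonies counted.
#' @param dilution_factor total dilution of the plated aliquot (e.g. 1e5 for
#'   a 10^-5 dilution).
#' @param volume_ml plated volume in ml.
#' @export
cfu_per_ml <- function(colonies, dilution_factor, volume_ml = 0.1) {
  colonies * dilution_factor / volume_ml
}
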