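#' One-factor PERMANOVA with Euclidean distances
#'
#' Permutational multivariate analysis of variance, implemented from first
#' principles on the squared Euclidean distance matrix. Sums of squares follow
#' the distance-based decomposition: SS_total = sum_{i<j} d_ij^2 / n over all
#' pairs, SS_within = sum over groups of the same quantity restricted to the
#' group (divided by the group size), SS_between = SS_total - SS_within.
#' pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g)); the p-value is
#' the fraction of label permutations with pseudo-F at least as large as
#' observed, with the +1 correction: p = (1 + #exceed) / (1 + n_perm).
#'
#' @param X numeric matrix or data.frame, rows = samples, columns = features
#'   (e.g. strain frequencies, already aggregated and scaled as desired).
#' @param grouping factor-like vector of length nrow(X); at least 2 groups
#'   with at least 2 samples each.
#' @param n_perm number of random label permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @param exhaustive if TRUE, enumerate all n! label orders instead of random
#'   permutations (feasible for n <= ~8); n_perm is ignored.
#' @return a \code{permanova_result}: list with factor_name, r_squared,
#'   pseudo_F, p_value, n_permutations, seed, ss (total/between/within),
#'   df (between/within).
#' @export
permanova <- function(X, grouping, n_perm = 999L, seed = NULL,
                      exhaustive = FALSE) {
  X <- as.matrix(X)
  g <- as.factor(grouping)
  if (length(g) != nrow(X))
    stop("permanova(): grouping length must equal nrow(X)")
  sizes <- table(g)
  if (length(sizes) < 2) stop("permanova(): need at least 2 groups")
  if (any(sizes < 2))
    stop("permanova(): singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- nrow(X)
  k <- nlevels(g)
  d2 <- as.matrix(dist(X))^2

  ss_within_for <- function(lab) {
    sw <- 0
    for (lev in levels(g)) {
      idx <- which(lab == lev)
      sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ss_within_for(g)
  ss_between <- ss_total - ss_within
  df_b <- k - 1L
  df_w <- n - k
  f_obs <- (ss_between / df_b) / (ss_within / df_w)
  r2 <- ss_between / ss_total

  f_for <- function(lab) {
    sw <- ss_within_for(lab)
    ((ss_total - sw) / df_b) / (sw / df_w)
  }

  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(ord) f_for(g[ord]), numeric(1))
    n_used <- length(f_perm)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(i) f_for(sample(g)), numeric(1))
    n_used <- n_perm
  }
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_used)

  structure(list(factor_name = deparse(substitute(grouping)),
                 r_squared = r2, pseudo_F = f_obs, p_value = p,
                 n_permutations = n_used, seed = seed,
                 ss = c(total = ss_total, between = ss_between,
                        within = ss_within),
                 df = c(between = df_b, within = df_w)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean): r2 = %.3f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

# all n! orderings of 1..n (recursive; intended for n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  j <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) {
      j <- j + 1L
      out[[j]] <- c(i, rest[s])
    }
  }
  out
}

#' PCA scores on column-standardised data
#'
#' Columns are centred and scaled to unit variance (zero-variance columns are
#' dropped with a warning), then decomposed by SVD. Explained-variance
#' fractions are the normalised squared singular values.
#'
#' @param X numeric matrix/data.frame, rows = samples.
#' @return list with \code{scores} (samples x components), \code{loadings},
#'   \code{explained} (fractions, non-increasing, summing to 1), and
#'   \code{dropped} (names of zero-variance columns removed).
#' @export
pca_scores <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("pca_scores(): need at least 2 samples")
  v <- apply(X, 2, sd)
  zv <- is.na(v) | v == 0
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  dropped <- nm[zv]
  if (any(zv)) {
    warning("pca_scores(): dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !zv, drop = FALSE]
  }
  if (ncol(X) < 2)
    stop("pca_scores(): fewer than 2 features with nonzero variance")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, explained = expl,
       dropped = dropped)
}

#' Spearman correlation between input and final strain representation
#'
#' For each condition, computes Spearman's rank correlation (average-rank
#' ties) between the initial inoculum frequencies and the final frequencies
#' of the same strains, and adjusts the per-condition p-values for
#' multiplicity across conditions (Benjamini-Hochberg by default, Holm by
#' flag).
#'
#' @param initial numeric vector of input frequencies, one per strain.
#' @param final matrix/data.frame of final frequencies, rows matching
#'   \code{initial}, one column per condition.
#' @param adjust "BH" (default) or "holm".
#' @return data.frame with condition, rho, p_value, p_adjusted, method.
#' @export
input_output_correlation <- function(initial, final, adjust = c("BH", "holm")) {
  adjust <- match.arg(adjust)
  final <- as.matrix(final)
  if (length(initial) != nrow(final))
    stop("input_output_correlation(): initial and final differ in strain count")
  res <- lapply(seq_len(ncol(final)), function(j) {
    ct <- suppressWarnings(
      stats::cor.test(initial, final[, j], method = "spearman", exact = FALSE))
    data.frame(condition = colnames(final)[j] %||% paste0("cond", j),
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out$method <- adjust
  out
}

#' Optical-density increment over a growth horizon
#'
#' The growth readout: OD at the sample point nearest to the horizon
#' (ties resolved to the earlier point, matching plate-reader sampling on a
#' 15-min grid) minus OD at time zero.
#'
#' @param time_min numeric vector of time points in minutes, strictly
#'   increasing.
#' @param od optical-density readings, parallel to \code{time_min}.
#' @param horizon_min horizon in minutes; default 960 (16 h).
#' @return the OD increment (a length-1 numeric).
#' @export
growth_increment <- function(time_min, od, horizon_min = 960) {
  if (length(time_min) != length(od))
    stop("growth_increment(): time and OD lengths differ")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("growth_increment(): time points must be strictly increasing")
  if (max(time_min) < horizon_min)
    stop("growth_increment(): horizon ", horizon_min,
         " min beyond curve end (", max(time_min), " min)")
  nearest <- function(t0) {
    d <- abs(time_min - t0)
    which(d == min(d))[1]   # tie -> earlier point
  }
  od[nearest(horizon_min)] - od[nearest(0)]
}
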