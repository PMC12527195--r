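## Community statistics: abundance transforms, rare-taxa filter, Bray-Curtis
## dissimilarity, PERMANOVA (global and pairwise) with restricted
## permutations, the Pearson chi-squared independence test, and stratified
## permutation tests on univariate site metrics.

#' Transform an abundance matrix
#'
#' `log1`: x -> ln(x + 1); `sqrt`: x -> sqrt(x); elementwise.
#'
#' @param m Numeric matrix (samples x taxa), non-negative.
#' @param method `"log1"`, `"sqrt"` or `"none"`.
#' @return Transformed matrix.
#' @export
transform_abundance <- function(m, method = c("log1", "sqrt", "none")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (any(m < 0)) stop("abundances must be non-negative")
  switch(method,
         log1 = log(m + 1),
         sqrt = sqrt(m),
         none = m)
}

#' Drop taxa that never reach a relative-abundance threshold
#'
#' A taxon is kept iff it represents at least `threshold` of the total
#' abundance of at least one sample. Applied before transformation.
#'
#' @param m Numeric matrix (samples x taxa), non-negative; row totals of
#'   samples used must be positive.
#' @param threshold Relative-abundance threshold (default 0.03, i.e. 3%).
#' @return The matrix restricted to the surviving taxa.
#' @export
rare_taxa_filter <- function(m, threshold = 0.03) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("abundances must be non-negative")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("rows used for relative abundance must have ",
                          "positive totals")
  rel <- m / tot
  keep <- apply(rel, 2, function(col) any(col >= threshold))
  if (!any(keep)) stop("all taxa dropped by the rare-taxa filter")
  m[, keep, drop = FALSE]
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,k) = sum_j |x_ij - x_kj| / sum_j (x_ij + x_kj)`, in [0, 1]. Two
#' all-zero samples are assigned distance 0 by convention.
#'
#' @param m Numeric matrix (samples x taxa), non-negative, >= 2 rows.
#' @return Square symmetric matrix with zero diagonal.
#' @examples
#' bray_curtis(rbind(a = c(1, 2, 0), b = c(0, 2, 2)))  # 3/7
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (any(m < 0)) stop("abundances must be non-negative")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      denom <- sum(m[i, ] + m[k, ])
      d[i, k] <- d[k, i] <-
        if (denom == 0) 0 else sum(abs(m[i, ] - m[k, ])) / denom
    }
  }
  d
}

## within-group sum of squared distances, divided by group size
.ss_within <- function(d2, groups) {
  ss <- 0
  for (g in unique(groups)) {
    s <- which(groups == g)
    ss <- ss + sum(d2[s, s]) / (2 * length(s))
  }
  ss
}

## one restricted permutation of indices (identity strata = free permutation)
.perm_within_strata <- function(n, strata) {
  idx <- seq_len(n)
  if (is.null(strata)) return(sample(idx))
  for (s in unique(strata)) {
    w <- which(strata == s)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

## all permutations of 1..n (n small)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance. With squared
#' distances `d2`, `SS_T = sum_{i<k} d2_ik / N`,
#' `SS_W = sum_g sum_{i<k in g} d2_ik / n_g`, `SS_A = SS_T - SS_W`, and
#' `pseudo-F = (SS_A / (a - 1)) / (SS_W / (N - a))`. The p-value is
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)` under random relabelings;
#' when `strata` is given labels permute only within strata (the restricted
#' permutation analogue of a region random effect). With
#' `exhaustive = TRUE` every relabeling is enumerated (N <= 8) and the
#' p-value is the exact proportion of relabelings (identity included) with
#' `F_perm >= F_obs`.
#'
#' @param d Square distance matrix (or `dist`).
#' @param groups Group labels, one per sample; every group needs >= 2
#'   samples.
#' @param n_perm Number of random permutations (>= 99; default 9999).
#' @param strata Optional stratum labels restricting permutations.
#' @param seed Optional integer seed for the permutation stream.
#' @param exhaustive Enumerate all relabelings instead of sampling.
#' @return Object of class `permanova`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
permanova <- function(d, groups, n_perm = 9999, strata = NULL, seed = NULL,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  if (!is.null(strata) && length(strata) != n)
    stop("strata inconsistent with samples")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 samples; group '",
                           names(sizes)[sizes < 2][1], "' has fewer")
  a <- length(sizes)
  if (a < 2) stop("need >= 2 groups")
  if (!exhaustive && n_perm < 99) stop("n_perm must be >= 99")

  d2 <- d^2
  ss_t <- sum(d2) / (2 * n)
  ss_w <- .ss_within(d2, groups)
  ss_a <- ss_t - ss_w
  f_obs <- (ss_a / (a - 1)) / (ss_w / (n - a))

  f_for <- function(idx) {
    ssw <- .ss_within(d2, groups[idx])
    ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
  }

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- .all_perms(n)
    if (!is.null(strata)) {
      ok <- apply(perms, 1, function(idx)
        all(strata[idx] == strata))
      perms <- perms[ok, , drop = FALSE]
    }
    f_perm <- apply(perms, 1, f_for)
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (f_for(.perm_within_strata(n, strata)) >= f_obs - 1e-12)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_used,
                 df_between = a - 1, df_within = n - a,
                 ss_between = ss_a, ss_within = ss_w, ss_total = ss_t),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, " permutations)\n", sep = "")
  cat(sprintf("  pseudo-F = %.4f  (df %d, %d)\n",
              x$pseudo_F, x$df_between, x$df_within))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Pairwise PERMANOVA between group pairs
#'
#' Runs an independent two-group PERMANOVA on each pair's samples and
#' reports unadjusted p-values alongside Holm-adjusted ones.
#'
#' @inheritParams permanova
#' @param pairs Two-column character matrix of group pairs (default: all
#'   pairs of observed groups).
#' @return Data frame of class `pairwise_permanova`: `group1`, `group2`,
#'   `pseudo_F`, `p_value`, `p_holm`.
#' @export
pairwise_permanova <- function(d, groups, pairs = NULL, n_perm = 9999,
                               strata = NULL, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (is.null(pairs)) {
    gl <- sort(unique(groups))
    pairs <- t(utils::combn(gl, 2))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- groups %in% pairs[i, ]
    pr <- permanova(d[sel, sel, drop = FALSE], groups[sel], n_perm = n_perm,
                    strata = if (is.null(strata)) NULL else strata[sel])
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               pseudo_F = pr$pseudo_F, p_value = pr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}

#' Pearson chi-squared test of independence
#'
#' `X2 = sum (O - E)^2 / E` with expected counts from the margins, no
#' continuity correction; `df = (r - 1)(c - 1)`; p from the chi-squared
#' distribution.
#'
#' @param tab Non-negative integer contingency matrix with positive margins.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' feeding <- rbind(feeding = c(1, 0, 4, 6), not_feeding = c(15, 7, 6, 6))
#' chi_square_independence(feeding)
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("cells must be non-negative")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("cells must be integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  e <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = e)
}

#' Stratified permutation test on a univariate site metric
#'
#' For each treatment pair, the statistic is the difference of treatment
#' means; its null distribution is built by permuting treatment labels
#' within strata (regions) among the pair's sites. Two-sided p-values are
#' `(1 + #[|diff_perm| >= |diff_obs|]) / (1 + n_perm)`, Holm-adjusted across
#' the pairs.
#'
#' @param values Numeric vector, one value per site.
#' @param treatments Treatment label per site (>= 2 sites per treatment).
#' @param strata Optional stratum (region) label per site.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return Data frame: `group1`, `group2`, `diff_means`, `p_value`,
#'   `p_holm`.
#' @export
permutation_metric_test <- function(values, treatments, strata = NULL,
                                    n_perm = 999, seed = NULL) {
  treatments <- as.character(treatments)
  stopifnot(length(values) == length(treatments))
  if (!is.null(strata) && length(strata) != length(values))
    stop("strata inconsistent with samples")
  sizes <- table(treatments)
  if (any(sizes < 2)) stop("every treatment needs >= 2 sites; '",
                           names(sizes)[sizes < 2][1], "' has fewer")
  if (!is.null(seed)) set.seed(seed)
  gl <- sort(unique(treatments))
  pairs <- t(utils::combn(gl, 2))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- which(treatments %in% pairs[i, ])
    v <- values[sel]; g <- treatments[sel]
    st <- if (is.null(strata)) NULL else strata[sel]
    obs <- mean(v[g == pairs[i, 1]]) - mean(v[g == pairs[i, 2]])
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[.perm_within_strata(length(v), st)]
      dp <- mean(v[gp == pairs[i, 1]]) - mean(v[gp == pairs[i, 2]])
      if (abs(dp) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               diff_means = obs, p_value = (1 + hits) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}
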