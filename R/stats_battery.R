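# Statistical battery: common-language effect size, Kruskal-Wallis with
# Conover post hoc, Mann-Whitney screens with Benjamini-Hochberg correction,
# and contingency-table adjusted residuals with cell-wise exact tests.

#' Common-language effect size
#'
#' Probability that a random observation from `x` exceeds a random
#' observation from `y`, ties counted half:
#' `(#\{x_i > y_j\} + 0.5 #\{x_i = y_j\}) / (n_x n_y)`. Values above 0.5 mean
#' the `x` distribution is shifted to larger values. Computed through the
#' rank-sum (Mann-Whitney U) identity, which reproduces the pair count
#' exactly.
#'
#' @param x,y non-empty numeric samples.
#' @return effect size in [0, 1]; `cles(x, y) + cles(y, x) == 1`.
#' @export
cles <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u / (nx * ny)
}

#' Kruskal-Wallis omnibus with Conover post hoc and CLES directions
#'
#' Omnibus p-value from the tie-corrected Kruskal-Wallis test; when more than
#' two groups are supplied, all-pairs Conover tests on the pooled tie-
#' corrected ranks (t statistics with the chi-square-adjusted pooled
#' variance, two-sided, N - k degrees of freedom) with a multiplicity
#' correction, plus the pairwise CLES matrix for effect direction.
#'
#' @param groups named list of numeric samples, each with at least 2
#'   observations; at least 2 groups.
#' @param p_adjust correction for the pairwise p-values (a `p.adjust`
#'   method; default Bonferroni).
#' @return object of class `gutperm_groupcomp`: `omnibus_p`, `pairwise_p`,
#'   `adjusted_p`, `cles` (matrices with group names), `method`.
#' @export
kruskal_conover <- function(groups, p_adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 observations")
  k <- length(groups)
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), sizes)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, factor(grp, levels = names(groups)), mean)
  H <- unname(kw$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pair_p <- cles_m <- matrix(NA_real_, k, k,
                             dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        pair_p[i, j] <- 1; cles_m[i, j] <- 0.5
        next
      }
      se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / sizes[i] + 1 / sizes[j]))
      tt <- (rbar[i] - rbar[j]) / se
      pair_p[i, j] <- 2 * stats::pt(-abs(tt), df = N - k)
      cles_m[i, j] <- cles(groups[[i]], groups[[j]])
    }
  }
  adj <- pair_p
  ut <- upper.tri(pair_p)
  adj[ut] <- stats::p.adjust(pair_p[ut], method = p_adjust)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  structure(list(omnibus_p = unname(kw$p.value),
                 pairwise_p = if (k > 2) pair_p else NULL,
                 adjusted_p = if (k > 2) adj else NULL,
                 cles = cles_m,
                 method = list(omnibus = "kruskal-wallis",
                               posthoc = if (k > 2) "conover" else NULL,
                               p_adjust = p_adjust)),
            class = "gutperm_groupcomp")
}

#' Class-by-property Mann-Whitney screen with BH correction
#'
#' For every combination of chemical class and property, a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test compares the property distribution
#' between the two permanence groups; Benjamini-Hochberg correction is
#' applied jointly across all tested cells, and the direction comes from the
#' CLES against 0.5. Classes absent from either group are marked untested.
#'
#' @param records table with the property columns, a class column and a
#'   two-level group column.
#' @param properties character vector of property column names.
#' @param class_col,group_col column names for the chemical class and the
#'   comparison group.
#' @param groups length-2 character vector: first element is the focal group
#'   (direction `higher` means higher in this group).
#' @param alpha significance level after correction.
#' @return tidy data.frame: class, property, n per group, p, `p_adj`, cles,
#'   direction in {higher, lower, ns, not_tested}.
#' @export
mannwhitney_bh <- function(records, properties, class_col = "chem_class",
                           group_col = "permanence_label",
                           groups = c("Lingerer", "Traverser"),
                           alpha = 0.05) {
  stopifnot(length(groups) == 2L, all(properties %in% names(records)))
  cls <- as.character(records[[class_col]])
  grp <- as.character(records[[group_col]])
  present <- function(g) unique(cls[grp == g & !is.na(cls)])
  both <- intersect(present(groups[1]), present(groups[2]))
  all_cls <- sort(unique(cls[!is.na(cls)]))
  res <- expand.grid(class = all_cls, property = properties,
                     stringsAsFactors = FALSE)
  res$n1 <- res$n2 <- NA_integer_
  res$p <- res$cles <- NA_real_
  for (i in seq_len(nrow(res))) {
    if (!(res$class[i] %in% both)) next
    x <- records[[res$property[i]]][grp == groups[1] & cls == res$class[i]]
    y <- records[[res$property[i]]][grp == groups[2] & cls == res$class[i]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) next
    res$n1[i] <- length(x); res$n2[i] <- length(y)
    res$p[i] <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE)$p.value)
    res$cles[i] <- cles(x, y)
  }
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$direction <- ifelse(!tested, "not_tested",
                   ifelse(res$p_adj >= alpha | is.na(res$p_adj), "ns",
                   ifelse(res$cles > 0.5, "higher", "lower")))
  res
}

#' Contingency-table post hoc: adjusted residuals and exact cell p-values
#'
#' Expected counts from the margins; adjusted residuals
#' `(O - E) / sqrt(E (1 - rowfrac) (1 - colfrac))`; a cell-specific p-value
#' from the two-sided exact Fisher test of the 2x2 collapse of the cell
#' against the rest of its row and column; multiplicity correction across all
#' R x C cells; direction (over/under-representation) from the residual
#' sign.
#'
#' @param observed non-negative integer matrix, at least 2x2, grand total
#'   positive.
#' @param alpha significance level after correction.
#' @param correction `"bonferroni"` or `"bh"`.
#' @return object of class `gutperm_contingency` with fields `observed`,
#'   `expected`, `adjusted_residuals`, `cell_pvalues`, `adjusted_pvalues`,
#'   `significant`, `direction`, `alpha`, `correction`. Cells on a zero
#'   margin are untestable (`NA` p-value, direction `none`).
#' @export
contingency_posthoc <- function(observed, alpha = 0.05,
                                correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L) stop("need at least 2x2")
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed must be non-negative integers")
  }
  N <- sum(observed)
  if (N <= 0) stop("grand total must be positive")
  rs <- rowSums(observed); cs <- colSums(observed)
  E <- outer(rs, cs) / N
  denom <- sqrt(E * (1 - rs / N) %o% (1 - cs / N))
  resid <- (observed - E) / denom
  resid[!is.finite(resid)] <- NA_real_
  pv <- matrix(NA_real_, nrow(observed), ncol(observed),
               dimnames = dimnames(observed))
  for (i in seq_len(nrow(observed))) {
    for (j in seq_len(ncol(observed))) {
      if (rs[i] == 0 || cs[j] == 0 || rs[i] == N || cs[j] == N) next
      o <- observed[i, j]
      tab <- matrix(c(o, rs[i] - o, cs[j] - o, N - rs[i] - cs[j] + o), 2)
      pv[i, j] <- stats::fisher.test(tab)$p.value
    }
  }
  adj <- pv
  testable <- !is.na(pv)
  # family size = number of cells in the table
  adj[testable] <- stats::p.adjust(
    pv[testable],
    method = if (correction == "bh") "BH" else "bonferroni",
    n = length(pv))
  sig <- !is.na(adj) & adj < alpha
  direction <- matrix("none", nrow(observed), ncol(observed),
                      dimnames = dimnames(observed))
  direction[sig & !is.na(resid) & resid > 0] <- "over"
  direction[sig & !is.na(resid) & resid < 0] <- "under"
  structure(list(observed = observed, expected = E,
                 adjusted_residuals = resid, cell_pvalues = pv,
                 adjusted_pvalues = adj, significant = sig,
                 direction = direction, alpha = alpha,
                 correction = correction),
            class = "gutperm_contingency")
}

#' Tidy a contingency post hoc result
#'
#' @param x result of [contingency_posthoc()].
#' @return long data.frame (row, col, observed, expected, residual, p,
#'   `p_adj`, direction) suitable for heatmap plotting.
#' @export
tidy_contingency <- function(x) {
  stopifnot(inherits(x, "gutperm_contingency"))
  rn <- rownames(x$observed); cn <- colnames(x$observed)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(x$observed)))
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(x$observed)))
  data.frame(row = rep(rn, times = length(cn)),
             col = rep(cn, each = length(rn)),
             observed = as.vector(x$observed),
             expected = as.vector(x$expected),
             residual = as.vector(x$adjusted_residuals),
             p = as.vector(x$cell_pvalues),
             p_adj = as.vector(x$adjusted_pvalues),
             direction = as.vector(x$direction),
             stringsAsFactors = FALSE)
}
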