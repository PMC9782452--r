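#' Two-group comparison
#'
#' Compares one variable between two groups with an independent-samples
#' t-test (pooled-variance Student form by default, Welch optionally), a
#' Wilcoxon rank-sum test (exact for small samples without ties, normal
#' approximation with continuity and tie correction otherwise) or a
#' chi-squared test for categorical variables.  Pairs with missing values
#' are excluded and the per-group n after exclusion is reported.
#'
#' @param values per-subject values (numeric for `"t"`/`"wilcoxon"`,
#'   anything coercible to a factor for `"chi2"`).
#' @param groups group labels, exactly two levels after NA removal.
#' @param test one of `"t"`, `"wilcoxon"`, `"chi2"`.
#' @param var_equal pooled-variance (Student) t-test when `TRUE` (default);
#'   Welch when `FALSE`.
#' @return A list of class `group_comparison`: `test`, `statistic`, `p`,
#'   `n` (per group), `estimate` (group means for t, medians for
#'   Wilcoxon, `NA` for chi2).
#' @export
compare_groups <- function(values, groups,
                           test = c("t", "wilcoxon", "chi2"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have the same length", call. = FALSE)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) != 2L)
    stop("need exactly two groups with data", call. = FALSE)
  v1 <- values[groups == levels(groups)[1L]]
  v2 <- values[groups == levels(groups)[2L]]
  if (length(v1) == 0L || length(v2) == 0L)
    stop("one group is empty", call. = FALSE)
  n <- c(length(v1), length(v2))
  names(n) <- levels(groups)
  if (test == "t") {
    if (n[1L] < 2L || n[2L] < 2L)
      stop("the t-test needs at least 2 subjects per group", call. = FALSE)
    est <- c(mean(v1), mean(v2))
    sp2 <- (sum((v1 - est[1L])^2) + sum((v2 - est[2L])^2)) /
      (sum(n) - 2L)
    if (sp2 == 0 && stats::var(c(v1, v2)) == 0) {
      stat <- 0
      p <- 1
    } else {
      ht <- stats::t.test(v1, v2, var.equal = var_equal)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else if (test == "wilcoxon") {
    est <- c(stats::median(v1), stats::median(v2))
    if (stats::var(c(v1, v2)) == 0) {
      stat <- length(v1) * length(v2) / 2
      p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(v1, v2))
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else {
    tab <- table(values, groups)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
    est <- c(NA_real_, NA_real_)
  }
  names(est) <- levels(groups)
  structure(list(test = test, statistic = stat, p = p, n = n,
                 estimate = est),
            class = "group_comparison")
}

#' Adjust values to the mean age of the sample
#'
#' Regresses the values on age by least squares and removes the age trend
#' around the sample mean age:
#' `adjusted_i = value_i - beta * (age_i - mean(age))`.
#' The adjusted mean equals the raw mean, and applying the adjustment
#' twice changes nothing (the adjusted values have zero age slope).
#' With zero age variance the values are returned unchanged.
#'
#' @param values numeric vector.
#' @param ages numeric vector of the same length; at least 3 complete
#'   pairs.
#' @return Adjusted values (NA where `values` or `ages` are NA).
#' @export
age_adjust <- function(values, ages) {
  if (length(values) != length(ages))
    stop("'values' and 'ages' must have the same length", call. = FALSE)
  ok <- !is.na(values) & !is.na(ages)
  if (sum(ok) < 3L)
    stop("age adjustment needs at least 3 complete pairs", call. = FALSE)
  if (stats::var(ages[ok]) == 0) return(values)
  beta <- stats::cov(ages[ok], values[ok]) / stats::var(ages[ok])
  out <- values - beta * (ages - mean(ages[ok]))
  out[!ok] <- NA_real_
  out
}

#' Correlation overall and within groups
#'
#' Pearson (default) or Spearman correlation with its two-sided p-value,
#' computed over all complete pairs and, when group labels are given,
#' within each group.
#'
#' @param x,y numeric vectors.
#' @param groups optional group labels.
#' @param method `"pearson"` or `"spearman"`.
#' @return A data frame with columns `stratum`, `n`, `r`, `p`.
#' @export
correlate <- function(x, y, groups = NULL,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  one <- function(xi, yi, label) {
    ok <- !is.na(xi) & !is.na(yi)
    xi <- xi[ok]
    yi <- yi[ok]
    if (length(xi) < 3L)
      stop("stratum '", label, "' has fewer than 3 complete pairs",
           call. = FALSE)
    if (stats::var(xi) == 0 || stats::var(yi) == 0)
      stop("zero variance in stratum '", label,
           "': correlation undefined", call. = FALSE)
    ht <- suppressWarnings(stats::cor.test(xi, yi, method = method))
    data.frame(stratum = label, n = length(xi),
               r = unname(ht$estimate), p = ht$p.value)
  }
  out <- one(x, y, "overall")
  if (!is.null(groups)) {
    for (g in levels(factor(groups)))
      out <- rbind(out, one(x[groups == g], y[groups == g], g))
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (monotone, order of the input preserved) and
#' the significance calls at level `q`.
#'
#' @param p p-values in \[0, 1\].
#' @param q FDR level; default 0.05.
#' @return List with `adjusted`, `significant` (logical) and `q`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= q, q = q)
}

#' Simplified voxelwise two-group comparison
#'
#' A desk-scale stand-in for statistical parametric mapping: a two-sample
#' pooled-variance t-test per voxel, Benjamini-Hochberg FDR across the
#' tested voxels, a binary significance mask and 26-connectivity connected
#' components of the mask.  Voxels with zero pooled variance are excluded
#' from testing and from the FDR family (their t is undefined); they can
#' never enter the mask.  Cluster-extent inference in the random-field
#' sense is out of scope.
#'
#' @param maps_a,maps_b lists of 3-D arrays (one per subject) or 4-D
#'   arrays with subjects in the 4th dimension; all maps must share the
#'   same 3-D shape, with at least 2 subjects per group.
#' @param q FDR level.
#' @return A list of class `voxel_map_result`: arrays `t`, `p`,
#'   `p_adjusted`, logical `mask`, integer `cluster_labels`, vector
#'   `cluster_sizes`, and `q`.
#' @export
voxelwise_group_map <- function(maps_a, maps_b, q = 0.05) {
  ma <- stack_maps(maps_a)
  mb <- stack_maps(maps_b)
  if (!identical(attr(ma, "shape"), attr(mb, "shape")))
    stop("all maps must share the same shape", call. = FALSE)
  n1 <- ncol(ma)
  n2 <- ncol(mb)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  shape <- attr(ma, "shape")
  m1 <- rowMeans(ma)
  m2 <- rowMeans(mb)
  ss1 <- rowSums((ma - m1)^2)
  ss2 <- rowSums((mb - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tested <- se > 0
  tv <- pv <- pa <- rep(NA_real_, length(se))
  tv[tested] <- (m1[tested] - m2[tested]) / se[tested]
  pv[tested] <- 2 * stats::pt(-abs(tv[tested]), df)
  if (any(tested))
    pa[tested] <- stats::p.adjust(pv[tested], method = "BH")
  mask <- !is.na(pa) & pa <= q
  lab <- label_components(array(mask, shape))
  structure(list(t = array(tv, shape), p = array(pv, shape),
                 p_adjusted = array(pa, shape),
                 mask = array(mask, shape),
                 cluster_labels = lab$labels,
                 cluster_sizes = lab$sizes, q = q),
            class = "voxel_map_result")
}

## list of 3-D arrays or 4-D array -> voxel x subject matrix
stack_maps <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    shape <- dim(maps)[1:3]
    out <- matrix(maps, prod(shape), dim(maps)[4L])
  } else if (is.list(maps)) {
    shapes <- lapply(maps, dim)
    if (length(maps) == 0L || any(vapply(shapes, length, 1L) != 3L))
      stop("maps must be 3-D arrays", call. = FALSE)
    if (length(unique(lapply(shapes, identity))) != 1L)
      stop("all maps must share the same shape", call. = FALSE)
    shape <- shapes[[1L]]
    out <- vapply(maps, as.numeric, numeric(prod(shape)))
  } else stop("maps must be a list of 3-D arrays or a 4-D array",
              call. = FALSE)
  attr(out, "shape") <- as.integer(shape)
  out
}

## 26-connectivity connected components of a logical 3-D array
label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0L, , drop = FALSE]
  todo <- which(mask)
  cur <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    labels[seed] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      ai <- arrayInd(v, d)
      cand <- sweep(nb, 2L, as.integer(ai), `+`)
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
        cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
        cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1L] + d[1L] * (cand[, 2L] - 1L) +
        d[1L] * d[2L] * (cand[, 3L] - 1L)
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- cur
      queue <- c(queue, new)
    }
  }
  sizes <- if (cur > 0L) tabulate(labels[labels > 0L], cur) else integer(0)
  list(labels = labels, sizes = sizes)
}
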