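#' @include AllGenerics.R
NULL

#' Fragments per million from raw counts
#'
#' Library-size scaling: `FPM = count / library_size * 1e6`. When the library
#' sizes are the column sums of the count matrix, every FPM column sums to
#' one million. With `groups` supplied, per-group mean FPM are attached — the
#' quantity the abundance filter in [filterDEGs()] operates on.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @param librarySizes per-sample library sizes (> 0); defaults to the column
#'   sums.
#' @param groups optional factor/character of length `ncol(counts)` assigning
#'   samples to groups.
#' @return FPM matrix; when `groups` is given, with attribute `groupMeans`
#'   (genes x groups matrix of mean FPM).
#' @export
computeFPM <- function(counts, librarySizes = colSums(counts), groups = NULL) {
  counts <- as.matrix(counts)
  if (any(librarySizes <= 0)) stop("library sizes must be > 0")
  if (length(librarySizes) != ncol(counts)) {
    stop("'librarySizes' must have one entry per sample")
  }
  fpm <- sweep(counts, 2, librarySizes, "/") * 1e6
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != ncol(counts)) {
      stop("'groups' must have one entry per sample")
    }
    gm <- vapply(
      levels(groups),
      function(g) rowMeans(fpm[, groups == g, drop = FALSE]),
      numeric(nrow(fpm))
    )
    gm <- matrix(gm,
      nrow = nrow(fpm),
      dimnames = list(rownames(fpm), levels(groups))
    )
    attr(fpm, "groupMeans") <- gm
  }
  fpm
}

#' Filter a differential-expression table to DEGs
#'
#' A gene is differentially expressed when all three hold:
#' `|log2FC| >= fcThreshold` (inclusive), `FDR <= fdrThreshold` (inclusive),
#' and the mean FPM exceeds `fpmThreshold` (strict) in at least one group.
#' Defaults are |log2FC| >= 0.59 (1.5-fold), FDR <= 0.05, FPM > 5 in at least
#' one group. The filter is monotone: relaxing any threshold never removes a
#' retained gene.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `fdr` and one or
#'   more `fpm_<group>` columns of per-group mean FPM.
#' @param fcThreshold inclusive |log2FC| bound (default 0.59).
#' @param fdrThreshold inclusive FDR bound (default 0.05).
#' @param fpmThreshold strict mean-FPM bound, required in >= 1 group
#'   (default 5).
#' @return the retained rows of `table`.
#' @export
filterDEGs <- function(table, fcThreshold = 0.59, fdrThreshold = 0.05,
                       fpmThreshold = 5) {
  for (col in c("gene_id", "log2fc", "fdr")) {
    if (!col %in% names(table)) {
      stop("DEG table is missing required column '", col, "'")
    }
  }
  fpm_cols <- grep("^fpm_", names(table), value = TRUE)
  if (!length(fpm_cols)) {
    stop("DEG table is missing required column 'fpm_<group>'")
  }
  max_fpm <- do.call(pmax, c(table[fpm_cols], na.rm = TRUE))
  keep <- abs(table$log2fc) >= fcThreshold &
    table$fdr <= fdrThreshold &
    max_fpm > fpmThreshold
  table[which(keep), , drop = FALSE]
}

#' Partition three gene sets into the seven Venn regions
#'
#' @param setA,setB,setC character vectors of gene ids.
#' @param labels labels for the three sets (default
#'   `c("HCl", "LA", "Na_lactate")`, the three treatment contrasts).
#' @return a [VennPartition-class]; region names join the labels of the sets
#'   a region belongs to with `"&"`.
#' @examples
#' vp <- vennPartition(c("a", "b"), c("b", "c"), "d")
#' vennCounts(vp)
#' @export
vennPartition <- function(setA, setB, setC,
                          labels = c("HCl", "LA", "Na_lactate")) {
  stopifnot(length(labels) == 3L)
  a <- unique(as.character(setA))
  b <- unique(as.character(setB))
  cc <- unique(as.character(setC))
  universe <- unique(c(a, b, cc))
  inA <- universe %in% a
  inB <- universe %in% b
  inC <- universe %in% cc
  region_of <- function(ia, ib, ic) universe[inA == ia & inB == ib & inC == ic]
  regions <- list(
    region_of(TRUE, FALSE, FALSE),
    region_of(FALSE, TRUE, FALSE),
    region_of(FALSE, FALSE, TRUE),
    region_of(TRUE, TRUE, FALSE),
    region_of(TRUE, FALSE, TRUE),
    region_of(FALSE, TRUE, TRUE),
    region_of(TRUE, TRUE, TRUE)
  )
  names(regions) <- c(
    labels,
    paste(labels[1], labels[2], sep = "&"),
    paste(labels[1], labels[3], sep = "&"),
    paste(labels[2], labels[3], sep = "&"),
    paste(labels, collapse = "&")
  )
  totals <- c(length(a), length(b), length(cc))
  names(totals) <- labels
  new("VennPartition", setNames = labels, regions = regions, totals = totals)
}

#' @rdname venn-accessors
#' @export
setMethod("vennRegions", "VennPartition", function(object) object@regions)

#' @rdname venn-accessors
#' @export
setMethod("vennCounts", "VennPartition", function(object) {
  vapply(object@regions, length, integer(1))
})

#' @rdname venn-accessors
#' @export
setMethod("vennTotals", "VennPartition", function(object) object@totals)

setMethod("show", "VennPartition", function(object) {
  cat("VennPartition of", paste(object@setNames, collapse = ", "), "\n")
  cnt <- vapply(object@regions, length, integer(1))
  for (i in seq_along(cnt)) {
    cat(sprintf("  %-30s %d\n", names(cnt)[i], cnt[i]))
  }
  cat("  totals:", paste(names(object@totals), object@totals, collapse = " | "), "\n")
  invisible(NULL)
})

#' Sign concordance and effect-size slope between two contrasts
#'
#' Over genes present in both tables, computes the fraction regulated in the
#' same sense (a log2FC of exactly 0 is discordant with any non-zero value,
#' and concordant with another 0) and the regression of contrast B's log2FC
#' on contrast A's. The default slope is ordinary least squares with
#' intercept; total least squares (first principal axis) is available and
#' satisfies `slope(A,B) = 1/slope(B,A)`. A slope below 1 marks contrast A as
#' the more pronounced; the deviation from the bisector is `slope - 1`.
#'
#' @param tableA,tableB data.frames with columns `gene_id` and `log2fc`
#'   (typically already filtered to DEGs of interest).
#' @param universe `"intersection"` (default): the concordant fraction is
#'   over shared genes only; `"union"`: genes present in only one table count
#'   as discordant.
#' @param slopeMethod `"ols"` or `"tls"`.
#' @return a [ConcordanceResult-class].
#' @export
concordance <- function(tableA, tableB,
                        universe = c("intersection", "union"),
                        slopeMethod = c("ols", "tls")) {
  universe <- match.arg(universe)
  slopeMethod <- match.arg(slopeMethod)
  for (tb in list(tableA, tableB)) {
    if (!all(c("gene_id", "log2fc") %in% names(tb))) {
      stop("both tables need columns 'gene_id' and 'log2fc'")
    }
  }
  shared <- intersect(tableA$gene_id, tableB$gene_id)
  n_union <- length(union(tableA$gene_id, tableB$gene_id))
  if (length(shared) < 2L) {
    stop("fewer than 2 genes shared between the two tables")
  }
  x <- tableA$log2fc[match(shared, tableA$gene_id)]
  y <- tableB$log2fc[match(shared, tableB$gene_id)]
  same <- sign(x) == sign(y)
  denom <- if (universe == "union") n_union else length(shared)
  frac <- sum(same) / denom
  if (slopeMethod == "ols") {
    b <- unname(stats::coef(stats::lm(y ~ x)))
    icpt <- b[1]
    slp <- b[2]
  } else {
    sxx <- stats::var(x)
    syy <- stats::var(y)
    sxy <- stats::cov(x, y)
    if (sxy == 0) {
      slp <- if (syy > sxx) Inf else 0
    } else {
      slp <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    }
    icpt <- mean(y) - slp * mean(x)
  }
  new("ConcordanceResult",
    nUnion = n_union, nCommon = length(shared),
    fractionSameSign = frac, slope = slp, intercept = icpt,
    slopeMethod = slopeMethod
  )
}

#' @rdname concordance-accessors
#' @export
setMethod("fractionSameSign", "ConcordanceResult", function(object) {
  object@fractionSameSign
})

#' @rdname concordance-accessors
#' @export
setMethod("concordanceSlope", "ConcordanceResult", function(object) {
  object@slope
})

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult over", object@nCommon, "shared genes",
      "(union", paste0(object@nUnion, "):\n"))
  cat(sprintf(
    "  same sign: %.3f | slope (%s): %.4g (bisector deviation %+.4g)\n",
    object@fractionSameSign, object@slopeMethod, object@slope,
    object@slope - 1
  ))
  invisible(NULL)
})
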