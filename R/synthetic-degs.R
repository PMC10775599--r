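#' @include synthetic-design.R
NULL

#' Simulate paired differential-expression tables
#'
#' Generates per-contrast DEG tables (`LA`, `HCl`, `Na_lactate` vs control)
#' with a known concordance structure:
#'
#' * The LA contrast carries the primary effects: a fraction `propDE` of
#'   genes get a true log2 fold change of random sign and magnitude
#'   `Normal(effectMean, effectSd)`; the rest get small null wobble.
#' * The HCl contrast's effects are the LA effects scaled by `slope` and
#'   sign-flipped independently per gene with probability `flipProb`, plus
#'   optional measurement noise of standard deviation `noiseSd`. At
#'   `noiseSd = 0` and `flipProb = 0` the regression of HCl on LA recovers
#'   `slope` exactly, and the expected same-sign fraction is `1 - flipProb`.
#' * The Na-lactate contrast's effects are the LA effects scaled by
#'   `lactateScale` (near zero: hyperlactatemia alone barely regulates
#'   genes), giving the condition-ordered DEG counts LA > HCl >> Na-lactate.
#'
#' FDR values come from a normal test on `log2fc / se` with
#' Benjamini-Hochberg adjustment within each table; per-group mean FPM are
#' log-normal, so a small tail of genes fails the abundance filter.
#'
#' @param nGenes number of genes (default 15000).
#' @param propDE fraction of genes with a planted LA effect (default 0.12).
#' @param effectMean,effectSd magnitude distribution of planted log2 fold
#'   changes (defaults 1.2 and 0.4).
#' @param slope effect scaling of HCl relative to LA (default 0.5).
#' @param flipProb per-gene sign-flip probability between the LA and HCl
#'   contrasts, in \[0, 1\] (default 0.05).
#' @param lactateScale effect scaling of the Na-lactate contrast
#'   (default 0.02).
#' @param noiseSd additive log2FC noise on the derived contrasts (default 0).
#' @param se per-gene standard error used for the p-value model
#'   (default 0.25).
#' @param seed integer seed.
#' @return named list of three data.frames (`HCl`, `LA`, `Na_lactate`), each
#'   with columns `gene_id`, `log2fc`, `fdr`, `fpm_ctrl`, `fpm_treat`, plus
#'   attribute `truth` (a list with the planted `slope`, `flipProb` and the
#'   per-gene flip indicator).
#' @export
simulateDEGTables <- function(nGenes = 15000L, propDE = 0.12,
                              effectMean = 1.2, effectSd = 0.4,
                              slope = 0.5, flipProb = 0.05,
                              lactateScale = 0.02, noiseSd = 0,
                              se = 0.25, seed = 1L) {
  if (nGenes < 1L) stop("'nGenes' must be >= 1")
  if (flipProb < 0 || flipProb > 1) stop("'flipProb' must lie in [0, 1]")
  set.seed(.substreamSeed(seed, "degs"))
  ids <- sprintf("gene_%05d", seq_len(nGenes))
  is_de <- stats::runif(nGenes) < propDE
  magnitude <- ifelse(
    is_de,
    abs(stats::rnorm(nGenes, effectMean, effectSd)),
    abs(stats::rnorm(nGenes, 0, 0.08))
  )
  magnitude <- pmax(magnitude, 1e-6)  # keep every effect nonzero
  sgn <- sample(c(-1, 1), nGenes, replace = TRUE)
  la <- sgn * magnitude
  flip <- stats::runif(nGenes) < flipProb
  hcl <- slope * la * ifelse(flip, -1, 1)
  nal <- lactateScale * la
  if (noiseSd > 0) {
    hcl <- hcl + stats::rnorm(nGenes, 0, noiseSd)
    nal <- nal + stats::rnorm(nGenes, 0, noiseSd)
  }
  base_fpm <- exp(stats::rnorm(nGenes, log(50), 1.2))
  mk_table <- function(l2fc) {
    p <- 2 * stats::pnorm(-abs(l2fc) / se)
    data.frame(
      gene_id = ids,
      log2fc = l2fc,
      fdr = stats::p.adjust(p, method = "BH"),
      fpm_ctrl = base_fpm,
      fpm_treat = base_fpm * 2^l2fc,
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    HCl = mk_table(hcl),
    LA = mk_table(la),
    Na_lactate = mk_table(nal)
  )
  attr(out, "truth") <- list(slope = slope, flipProb = flipProb, flip = flip)
  out
}
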