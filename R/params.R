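#' Analysis thresholds for the three-tissue expression pipeline
#'
#' Bundles every threshold the pipeline uses, so each run records its full
#' effective configuration. The defaults are the conventional choices for this
#' analysis: detection at 1 read per million (RPM), a stricter 5-RPM gate for
#' membership in the significant-set Venn partition, a twofold preferential
#' ratio, a fourfold anther-wall exclusion ratio, and a 5% false discovery
#' rate. The default mitochondrial-genomic-insertion (MGI) interval is the
#' pericentromeric block on chromosome II spanning positions
#' 3,222,935-3,626,460 (1-based inclusive, TAIR coordinates).
#'
#' @param detect_low RPM threshold above which a gene counts as detected
#'   (inclusive). Default 1.
#' @param detect_high RPM threshold ("in at least one sample") gating
#'   membership of the significant sets. Default 5.
#' @param fold_pref minimum fold ratio for preferential expression. Default 2.
#' @param fold_exclude minimum anther/meiocyte ratio triggering the
#'   anther-wall exclusion. Default 4.
#' @param alpha false-discovery-rate level for Benjamini-Hochberg adjusted
#'   q-values. Default 0.05.
#' @param mgi_chrom,mgi_start,mgi_end the MGI interval (1-based inclusive).
#' @param per_million scaling constant for RPM; 1e6.
#'
#' @return A list of class `meio_params`.
#' @examples
#' analysis_params()
#' @export
analysis_params <- function(detect_low = 1, detect_high = 5,
                            fold_pref = 2, fold_exclude = 4, alpha = 0.05,
                            mgi_chrom = "II", mgi_start = 3222935,
                            mgi_end = 3626460, per_million = 1e6) {
  stopifnot(
    detect_low > 0, detect_low <= detect_high,
    fold_pref > 1, fold_pref <= fold_exclude,
    alpha > 0, alpha < 1,
    mgi_start <= mgi_end, per_million > 0
  )
  structure(
    list(detect_low = detect_low, detect_high = detect_high,
         fold_pref = fold_pref, fold_exclude = fold_exclude, alpha = alpha,
         mgi_chrom = mgi_chrom, mgi_start = mgi_start, mgi_end = mgi_end,
         per_million = per_million),
    class = "meio_params"
  )
}

#' @export
print.meio_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  cat(sprintf("  detection: >= %g RPM (low), >= %g RPM (Venn gate)\n",
              x$detect_low, x$detect_high))
  cat(sprintf("  fold thresholds: %gx preferential, %gx anther-wall exclusion\n",
              x$fold_pref, x$fold_exclude))
  cat(sprintf("  FDR level: %g\n", x$alpha))
  cat(sprintf("  MGI interval: %s:%d-%d\n", x$mgi_chrom,
              as.integer(x$mgi_start), as.integer(x$mgi_end)))
  invisible(x)
}
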