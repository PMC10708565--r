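# Plate-count total viable count (TVC) arithmetic.

#' Colonies per gram from plate counts at two dilutions
#'
#' Weighted plate-count rule for the standard two-dilution scheme:
#' `N = sum(C) / ((n1 +/- 0.1 * n2) * d)` where `C` are the colony counts on
#' all counted plates, `n1` and `n2` the numbers of plates at the first
#' (10x) and second (100x) dilution and `d` the dilution factor of the first
#' dilution. The national-standard convention weights the second dilution
#' with a plus sign (`gb_plus`, the default); `paper_minus` exposes the
#' minus-sign variant occasionally seen in print, for fidelity audits. Both
#' agree exactly when `n2 = 0`.
#'
#' @param counts colony counts on all counted plates.
#' @param n1 number of plates at the lower (10x) dilution.
#' @param n2 number of plates at the higher (100x) dilution.
#' @param d dilution factor of the first dilution, in (0, 1].
#' @param sign_convention `"gb_plus"` (default) or `"paper_minus"`.
#' @return N, colonies per gram (CFU/g).
#' @examples
#' plate_count_tvc(c(232, 244, 33, 35), n1 = 2, n2 = 2, d = 0.01)
#' @export
plate_count_tvc <- function(counts, n1, n2 = 0, d = 0.1,
                            sign_convention = c("gb_plus", "paper_minus")) {
  sign_convention <- match.arg(sign_convention)
  if (any(counts < 0)) stop("counting error: negative colony count",
                            call. = FALSE)
  if (n1 < 0 || n2 < 0 || (n1 + n2) < 1) {
    stop("counting error: need at least one plate", call. = FALSE)
  }
  if (d <= 0 || d > 1) stop("counting error: d must be in (0, 1]",
                            call. = FALSE)
  w <- if (sign_convention == "gb_plus") n1 + 0.1 * n2 else n1 - 0.1 * n2
  denom <- w * d
  if (denom <= 0) stop("counting error: non-positive denominator",
                       call. = FALSE)
  sum(counts) / denom
}

#' Log-transform a TVC value
#'
#' @param N colonies per gram (CFU/g), positive.
#' @return base-10 logarithm, log10 CFU/g.
#' @export
log10_tvc <- function(N) {
  if (any(!is.finite(N)) || any(N <= 0)) {
    stop("domain error: N must be positive", call. = FALSE)
  }
  log10(N)
}

#' Per-sample TVC from a plate-count table
#'
#' Convenience wrapper for tabular records with columns `sample_id`,
#' `plate_count` and `dilution_level` (1 = first dilution, 2 = second).
#'
#' @param records data.frame with the columns above.
#' @param d dilution factor of the first dilution.
#' @param sign_convention see [plate_count_tvc()].
#' @return data.frame with columns `sample_id`, `N`, `log10_tvc`.
#' @export
tvc_from_records <- function(records, d = 0.1,
                             sign_convention = c("gb_plus", "paper_minus")) {
  sign_convention <- match.arg(sign_convention)
  need <- c("sample_id", "plate_count", "dilution_level")
  if (!all(need %in% names(records))) {
    stop("format error: records need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(records, records$sample_id), function(g) {
    N <- plate_count_tvc(g$plate_count,
                         n1 = sum(g$dilution_level == 1),
                         n2 = sum(g$dilution_level == 2),
                         d = d, sign_convention = sign_convention)
    data.frame(sample_id = g$sample_id[1L], N = N, log10_tvc = log10_tvc(N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
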