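## RT-qPCR relative quantification (Livak 2^-ddCt).

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` is the
#' arithmetic mean dCt of the treated condition minus that of the
#' control condition, and the reported fold change is `2^-ddCt`.
#'
#' @param measurements data.frame with columns `sample`, `condition`,
#'   `ct_target`, `ct_reference`.
#' @param treated,control condition labels (defaults `"treated"`,
#'   `"control"`).
#' @return list with `fold_change`, `ddct`, and `dct` (per-sample
#'   data.frame).
#' @export
ddct_fold_change <- function(measurements, treated = "treated",
                             control = "control") {
  req <- c("sample", "condition", "ct_target", "ct_reference")
  stopifnot(all(req %in% names(measurements)))
  ct <- measurements$ct_target
  cr <- measurements$ct_reference
  if (anyNA(ct) || anyNA(cr) || any(!is.finite(ct)) || any(!is.finite(cr))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  dct <- data.frame(sample = measurements$sample,
                    condition = measurements$condition,
                    dct = ct - cr, stringsAsFactors = FALSE)
  for (cond in c(treated, control)) {
    if (!any(dct$condition == cond)) {
      stop("no measurements for condition ", cond, call. = FALSE)
    }
  }
  ddct <- mean(dct$dct[dct$condition == treated]) -
    mean(dct$dct[dct$condition == control])
  list(fold_change = 2^(-ddct), ddct = ddct, dct = dct)
}
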