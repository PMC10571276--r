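# Reversed oral-absorption rules as gut-permanence baselines. The classical
# rules describe orally absorbed, systemically acting molecules; reversing
# them (gut permanence = positive class) turns rule violations into
# Lingerer predictions.

#' Rule thresholds
#'
#' Fixed thresholds of the reversed rules; all inequalities are strict.
#' @export
RULE_THRESHOLDS <- list(
  lipinski = list(mw_gt = 500, logp_gt = 5, hba_gt = 10, hbd_gt = 5,
                  min_violations = 2L),
  veber = list(tpsa_gt = 140, rb_gt = 10)
)

#' Reversed Lipinski rule
#'
#' Predicts `Lingerer` when two or more of mw > 500 Da, logp > 5, hba > 10,
#' hbd > 5 hold; `Traverser` otherwise. The violation count is returned for
#' diagnostics of near-misses.
#'
#' @param d data.frame with columns `mw`, `logp`, `hba`, `hbd` (e.g. from
#'   [compute_descriptors()]).
#' @return data.frame with `label` (factor Traverser/Lingerer) and
#'   `violations` (integer 0-4).
#' @export
reversed_lipinski <- function(d) {
  th <- RULE_THRESHOLDS$lipinski
  stopifnot(all(c("mw", "logp", "hba", "hbd") %in% names(d)))
  v <- (d$mw > th$mw_gt) + (d$logp > th$logp_gt) +
       (d$hba > th$hba_gt) + (d$hbd > th$hbd_gt)
  lab <- ifelse(v >= th$min_violations, "Lingerer", "Traverser")
  data.frame(label = factor(lab, levels = PERMANENCE_LABELS),
             violations = as.integer(v))
}

#' Reversed Veber rule
#'
#' Predicts `Lingerer` when tpsa > 140 A^2 or rb > 10; `Traverser`
#' otherwise.
#'
#' @param d data.frame with columns `tpsa`, `rb`.
#' @return data.frame with `label` and `violations` (0-2).
#' @export
reversed_veber <- function(d) {
  th <- RULE_THRESHOLDS$veber
  stopifnot(all(c("tpsa", "rb") %in% names(d)))
  v <- (d$tpsa > th$tpsa_gt) + (d$rb > th$rb_gt)
  lab <- ifelse(v >= 1L, "Lingerer", "Traverser")
  data.frame(label = factor(lab, levels = PERMANENCE_LABELS),
             violations = as.integer(v))
}
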