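# pKa-based ionization-class assignment at a configurable environment pH.
#
# A molecule is taken to carry at least one ionized acidic group when its
# strongest-acidic pKa lies strictly below the environment pH, and at least
# one ionized basic group when its strongest-basic pKa lies strictly above
# it. The class follows the truth table acid/basic/neutral/zwitterion.
# Missing pKa values mean the corresponding group is absent; boundary
# equality (pKa == pH) also counts as absent (strict inequalities).

ION_CLASSES <- c("acid", "basic", "neutral", "zwitterion")

#' Gut-region pH presets
#'
#' Named pH values used for region-specific ionization analyses: duodenum
#' 6.0, caecum 6.4, jejunum and descending colon 7.0, ileum, sigmoid and
#' rectum 7.4 (the 7.4 preset is the default, systemic-like reference).
#' @export
GUT_PH_PRESETS <- c(duodenum = 6.0, caecum = 6.4, jejunum = 7.0,
                    descending_colon = 7.0, ileum = 7.4, sigmoid = 7.4,
                    rectum = 7.4)

#' Assign ionization classes from pKa pairs
#'
#' @param pka_acid strongest-acidic pKa; `NA` when the molecule reports none.
#' @param pka_base strongest-basic pKa; `NA` when the molecule reports none.
#' @param ph environment pH in [0, 14] (scalar or vector recycled against the
#'   pKa vectors).
#' @return data.frame with columns `ion_class` (factor with levels acid,
#'   basic, neutral, zwitterion), `ph`, `has_acid_group`, `has_basic_group`.
#' @export
assign_ionization_class <- function(pka_acid, pka_base, ph = 7.4) {
  n <- max(length(pka_acid), length(pka_base), length(ph))
  pka_acid <- rep_len(as.numeric(pka_acid), n)
  pka_base <- rep_len(as.numeric(pka_base), n)
  ph <- rep_len(as.numeric(ph), n)
  if (any(is.na(ph)) || any(ph < 0 | ph > 14)) {
    stop("ph must be in [0, 14]")
  }
  bad <- (!is.na(pka_acid) & !is.finite(pka_acid)) |
         (!is.na(pka_base) & !is.finite(pka_base))
  if (any(bad)) stop("non-finite pKa value(s) at position(s): ",
                     paste(utils::head(which(bad), 10), collapse = ", "))
  has_acid <- !is.na(pka_acid) & pka_acid < ph
  has_base <- !is.na(pka_base) & pka_base > ph
  cls <- ifelse(has_acid & has_base, "zwitterion",
         ifelse(has_acid, "acid",
         ifelse(has_base, "basic", "neutral")))
  data.frame(ion_class = factor(cls, levels = ION_CLASSES), ph = ph,
             has_acid_group = has_acid, has_basic_group = has_base)
}

#' Append the ionization class to a compound table
#'
#' @param records compound table with the two pKa columns.
#' @param ph environment pH (default 7.4).
#' @return the table with an `ion_class` column appended.
#' @export
ionize_table <- function(records, ph = 7.4) {
  call <- assign_ionization_class(records$pka_strongest_acidic,
                                  records$pka_strongest_basic, ph)
  records$ion_class <- call$ion_class
  records
}

#' Per-set ionization-class distributions
#'
#' @param records compound table carrying a set-label column.
#' @param ph environment pH.
#' @param by name of the set-label column (e.g. `"compartment_set"` or
#'   `"permanence_label"`).
#' @return matrix of class proportions (rows = sets, columns = the four
#'   ionization classes); each row sums to 1. Empty sets are omitted with a
#'   warning.
#' @export
ionization_distribution <- function(records, ph = 7.4, by = "compartment_set") {
  if (!by %in% names(records)) stop("column '", by, "' not found")
  call <- assign_ionization_class(records$pka_strongest_acidic,
                                  records$pka_strongest_basic, ph)
  lab <- records[[by]]
  lv <- if (is.factor(lab)) levels(lab) else unique(lab[!is.na(lab)])
  keep <- !is.na(lab)
  tab <- table(factor(lab[keep], levels = lv), call$ion_class[keep])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("empty set(s) omitted: ", paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}
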