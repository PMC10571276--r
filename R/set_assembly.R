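# Construction of the compound sets and permanence labels: the Gut /
# Gut-Serum / Serum / DrugBank compartment partition, the fatty-lipid (FL)
# reassignment of Gut/Serum records, the Gut-FL vs Gut-noFL split, and the
# binary Gut Traverser / Gut Lingerer permanence labels.

#' The four fatty-lipid (FL) chemical classes
#'
#' Lipid classes hydrolyzed in the gut lumen before absorption; molecules in
#' these classes are treated as unable to cross the gut wall intact.
#' @export
FL_CLASSES <- c("Glycerolipids", "Glycerophospholipids", "Fatty acyls",
                "Sphingolipids")

#' Closed chemical-class vocabulary
#'
#' The 18 ClassyFire-style class labels used throughout (17 named classes
#' plus "Other"). Unseen labels map to "Other" with a warning.
#' @export
CHEM_CLASSES <- c(
  "Glycerolipids", "Glycerophospholipids", "Fatty acyls", "Sphingolipids",
  "Saccharolipids", "Endocannabinoids", "Hydrocarbons",
  "Organoheterocyclic compounds", "Benzenoids",
  "Organic acids and derivatives", "Organic oxygen compounds",
  "Steroids and steroid derivatives", "Prenol lipids",
  "Organosulfur compounds", "Organic nitrogen compounds",
  "Phenylpropanoids and polyketides",
  "Nucleosides, nucleotides, and analogues", "Other")

COMPARTMENT_SETS <- c("Gut", "GutSerum", "Serum", "DrugBank")
PERMANENCE_LABELS <- c("Traverser", "Lingerer")

# coerce chem_class onto the closed vocabulary
normalize_chem_class <- function(x) {
  x <- as.character(x)
  unseen <- !is.na(x) & !(x %in% CHEM_CLASSES)
  if (any(unseen)) {
    warning("unseen chemical class label(s) mapped to 'Other': ",
            paste(unique(x[unseen]), collapse = ", "))
    x[unseen] <- "Other"
  }
  factor(x, levels = CHEM_CLASSES)
}

#' Assign compartment sets
#'
#' DrugBank-sourced records go to `DrugBank`; metabolites detected in both
#' gut and serum to `GutSerum`; gut-only to `Gut`; serum-only to `Serum`.
#' Metabolite records with neither biospecimen flag are rejected with a
#' warning.
#'
#' @param records deduplicated compound table.
#' @return the table with a `compartment_set` factor column appended.
#' @export
assign_compartment_sets <- function(records) {
  cs <- ifelse(records$source == "drugbank", "DrugBank",
        ifelse(records$in_gut & records$in_serum, "GutSerum",
        ifelse(records$in_gut, "Gut",
        ifelse(records$in_serum, "Serum", NA_character_))))
  bad <- is.na(cs)
  if (any(bad)) {
    warning(sum(bad), " metabolite record(s) without biospecimen flags rejected: ",
            paste(utils::head(records$id[bad], 5), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
    cs <- cs[!bad]
  }
  records$compartment_set <- factor(cs, levels = COMPARTMENT_SETS)
  rownames(records) <- NULL
  records
}

#' Reassign fatty-lipid Gut/Serum records to Gut
#'
#' Fatty-lipid compounds detected in both compartments are attributed to de
#' novo serum synthesis rather than gut-wall crossing, so every `GutSerum`
#' record whose chemical class is one of [FL_CLASSES] is moved to `Gut`.
#'
#' @param records table with `compartment_set` assigned.
#' @return the table with the updated `compartment_set`; the number of moved
#'   records is attached as `attr(x, "moved_fl")`.
#' @export
reassign_fl <- function(records) {
  records$chem_class <- normalize_chem_class(records$chem_class)
  missing_cls <- records$compartment_set == "GutSerum" & is.na(records$chem_class)
  if (any(missing_cls)) {
    warning(sum(missing_cls),
            " GutSerum record(s) without chem_class left in place")
  }
  move <- records$compartment_set == "GutSerum" &
    !is.na(records$chem_class) & records$chem_class %in% FL_CLASSES
  records$compartment_set[move] <- "Gut"
  attr(records, "moved_fl") <- sum(move)
  records
}

#' Split Gut records into Gut-FL and Gut-noFL
#'
#' @param records table after [reassign_fl()].
#' @return the table with a logical `fl_flag` column (`TRUE` iff the chemical
#'   class is one of [FL_CLASSES]); Gut-FL is `compartment_set == "Gut" &
#'   fl_flag`.
#' @export
split_fl <- function(records) {
  records$chem_class <- normalize_chem_class(records$chem_class)
  records$fl_flag <- !is.na(records$chem_class) &
    records$chem_class %in% FL_CLASSES
  records
}

#' Attach gut-permanence labels
#'
#' `Lingerer` (the positive class) for Gut records (both FL and noFL);
#' `Traverser` for DrugBank and updated Gut/Serum records; serum-only records
#' receive no label and are excluded from permanence modeling.
#'
#' @param records table after [split_fl()].
#' @return the table with a `permanence_label` factor column.
#' @export
build_permanence_labels <- function(records) {
  lab <- ifelse(records$compartment_set %in% c("DrugBank", "GutSerum"),
                "Traverser",
         ifelse(records$compartment_set == "Gut", "Lingerer", NA_character_))
  records$permanence_label <- factor(lab, levels = PERMANENCE_LABELS)
  records
}

#' Run the full set-assembly stage
#'
#' Compartment assignment, FL reassignment, FL split and permanence labels in
#' one call. Idempotent: re-running on its own output leaves the labels
#' unchanged.
#'
#' @param records deduplicated compound table.
#' @return labeled table; bookkeeping (per-set sizes before and after the FL
#'   reassignment, number moved) in `attr(x, "assembly")`.
#' @export
assemble_sets <- function(records) {
  records$compartment_set <- NULL
  records <- assign_compartment_sets(records)
  sizes_before <- table(records$compartment_set)
  records <- reassign_fl(records)
  moved <- attr(records, "moved_fl")
  records <- split_fl(records)
  records <- build_permanence_labels(records)
  sizes_after <- table(records$compartment_set)
  attr(records, "assembly") <- list(
    sizes_before = sizes_before,
    sizes_after = sizes_after,
    moved_fl = moved,
    n_gut_fl = sum(records$compartment_set == "Gut" & records$fl_flag),
    n_gut_nofl = sum(records$compartment_set == "Gut" & !records$fl_flag)
  )
  records
}
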