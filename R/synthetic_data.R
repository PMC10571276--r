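# Synthetic compound libraries with the statistical structure the analysis
# assumes: a large, homogeneous, ringless fatty-lipid (FL) stratum of
# long-chain acylglycerol-like Lingerers; a stratum of small polar noFL
# Lingerers; and a drug-like stratum of scaffolded aromatic Traversers.
# Molecules are assembled from closed template grammars (guaranteeing
# chemical validity and controllable descriptor profiles) and emitted as
# canonical parent SMILES, so they survive normalization unchanged.

chain <- function(len) strrep("C", len)

# --- FL grammar ------------------------------------------------------------
# Template families, their chemical class, their ionization behaviour and
# the minimum acyl chain length that keeps the family inside the designed
# descriptor envelope (mw > 500, logp > 5, rb > 10, nring 0, hbd <= 1).
FL_TEMPLATES <- list(
  tag = list(class = "Glycerolipids", min_chain = 10L, w = 0.50,
             build = function(l) sprintf("%sC(=O)OCC(OC(=O)%s)COC(=O)%s",
                                         chain(l[1]), chain(l[2]), chain(l[3])),
             nchains = 3L, ion = "neutral"),
  dag = list(class = "Glycerolipids", min_chain = 15L, w = 0.18,
             build = function(l) sprintf("%sC(=O)OCC(O)COC(=O)%s",
                                         chain(l[1]), chain(l[2])),
             nchains = 2L, ion = "neutral"),
  wax_ester = list(class = "Fatty acyls", min_chain = 17L, w = 0.10,
                   build = function(l) sprintf("%sC(=O)O%s", chain(l[1]), chain(l[2])),
                   nchains = 2L, ion = "neutral"),
  amide = list(class = "Sphingolipids", min_chain = 17L, w = 0.05,
               build = function(l) sprintf("%sC(=O)N(C)%s", chain(l[1]), chain(l[2])),
               nchains = 2L, ion = "neutral"),
  phosphotriester = list(class = "Glycerophospholipids", min_chain = 13L, w = 0.02,
                         build = function(l) sprintf("%sC(=O)OCC(OC(=O)%s)COP(=O)(OC)OC",
                                                     chain(l[1]), chain(l[2])),
                         nchains = 2L, ion = "neutral"),
  phosphodiester = list(class = "Glycerophospholipids", min_chain = 13L, w = 0.15,
                        build = function(l) sprintf("%sC(=O)OCC(OC(=O)%s)COP(=O)(O)OC",
                                                    chain(l[1]), chain(l[2])),
                        nchains = 2L, ion = "acid")
)

#' Generate a synthetic fatty-lipid (FL) library
#'
#' Long-chain triacylglycerol-, diacylglycerol-, wax-ester-, fatty-amide- and
#' glycerophosphate-template molecules with random acyl chain lengths;
#' chemical classes follow the template family (Glycerolipids dominate), the
#' ionization mix is neutral-dominated with an acid minority (free
#' phosphodiesters), and the ground-truth permanence is Lingerer.
#'
#' @param n number of molecules.
#' @param chain_length_range integer pair: acyl chain length bounds in
#'   carbons (template families enforce their own larger minima where the
#'   designed descriptor envelope requires it).
#' @param seed integer seed.
#' @return compound table ([COMPOUND_COLUMNS]) with a `stratum` column.
#' @export
generate_fl_library <- function(n, chain_length_range = c(10L, 20L), seed = 1L) {
  if (length(chain_length_range) != 2L ||
      chain_length_range[1] > chain_length_range[2] ||
      chain_length_range[1] < 1L) {
    stop("invalid chain length range")
  }
  if (n == 0L) return(empty_library())
  set.seed(seed)
  w <- vapply(FL_TEMPLATES, `[[`, numeric(1), "w")
  fam <- sample(names(FL_TEMPLATES), n, replace = TRUE, prob = w)
  smiles <- character(n); cls <- character(n)
  pka_a <- rep(NA_real_, n); pka_b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tpl <- FL_TEMPLATES[[fam[i]]]
    lo <- max(chain_length_range[1], tpl$min_chain)
    hi <- max(chain_length_range[2], lo)
    lens <- sample(seq(lo, hi), tpl$nchains, replace = TRUE)
    smiles[i] <- tpl$build(lens)
    cls[i] <- tpl$class
    if (tpl$ion == "acid") pka_a[i] <- min(max(stats::rnorm(1, 2.5, 0.5), 1), 5)
  }
  finalize_library(smiles, cls, pka_a, pka_b, stratum = "FL",
                   source = "hmdb_gut", prefix = "FL")
}

# --- noFL grammar ----------------------------------------------------------
NOFL_TEMPLATES <- list(
  diacid = list(class = "Organic acids and derivatives", w = 0.14, ion = "acid",
                build = function() sprintf("OC(=O)%sC(=O)O", chain(sample(1:5, 1)))),
  hydroxy_acid = list(class = "Organic acids and derivatives", w = 0.12, ion = "acid",
                      build = function() sample(c("CC(O)C(=O)O", "OCC(O)C(=O)O",
                                                  "OC(=O)CC(O)C(=O)O", "CC(=O)C(=O)O"), 1)),
  amino_acid = list(class = "Organic acids and derivatives", w = 0.18, ion = "zwitterion",
                    build = function() sprintf("NC(%s)C(=O)O",
                                               sample(c("C", "CC", "CO", "CC(C)C",
                                                        "Cc1ccccc1", "CS"), 1))),
  polyol = list(class = "Organic oxygen compounds", w = 0.14, ion = "neutral",
                build = function() sprintf("OC%sCO",
                                           strrep("C(O)", sample(1:4, 1)))),
  sugar = list(class = "Organic oxygen compounds", w = 0.12, ion = "neutral",
               build = function() sample(c("OCC1OC(O)C(O)C(O)C1O",
                                           "OCC1OC(O)C(O)C1O",
                                           "OCC(O)C(=O)CO"), 1)),
  phenol = list(class = "Benzenoids", w = 0.10, ion = "weak_acid",
                build = function() sample(c("Oc1ccccc1", "Oc1ccc(O)cc1",
                                            "Oc1ccccc1O", "Cc1ccc(O)cc1"), 1)),
  benzoic = list(class = "Benzenoids", w = 0.08, ion = "acid",
                 build = function() sample(c("OC(=O)c1ccccc1", "OC(=O)c1ccc(O)cc1",
                                             "OC(=O)Cc1ccccc1"), 1)),
  heterocycle = list(class = "Organoheterocyclic compounds", w = 0.07, ion = "neutral",
                     build = function() sample(c("c1cc[nH]c1", "Cc1cc2ccccc2[nH]1",
                                                 "O=C1CCCO1", "c1ccc2[nH]ccc2c1"), 1)),
  thio = list(class = "Organosulfur compounds", w = 0.05, ion = "acid",
              build = function() sample(c("CSCCC(=O)O", "CS(=O)CC(=O)O"), 1))
)

#' Generate a synthetic small-polar (noFL) library
#'
#' Short di-/hydroxy-/amino-acids, polyols and sugar-like molecules, simple
#' benzenoids, small heterocycles and organosulfur acids: the small,
#' low-logp, low-hba compounds that remain in the gut. Ground-truth
#' permanence is Lingerer; pKa sampling is acid/zwitterion-enriched with
#' essentially no purely basic molecules.
#'
#' @inheritParams generate_fl_library
#' @return compound table with a `stratum` column.
#' @export
generate_nofl_library <- function(n, seed = 1L) {
  if (n == 0L) return(empty_library())
  set.seed(seed)
  w <- vapply(NOFL_TEMPLATES, `[[`, numeric(1), "w")
  fam <- sample(names(NOFL_TEMPLATES), n, replace = TRUE, prob = w)
  smiles <- character(n); cls <- character(n)
  pka_a <- rep(NA_real_, n); pka_b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tpl <- NOFL_TEMPLATES[[fam[i]]]
    smiles[i] <- tpl$build()
    cls[i] <- tpl$class
    if (tpl$ion == "acid") pka_a[i] <- min(max(stats::rnorm(1, 4.0, 0.7), 2), 6.5)
    if (tpl$ion == "weak_acid") pka_a[i] <- min(max(stats::rnorm(1, 9.8, 0.5), 8), 12)
    if (tpl$ion == "zwitterion") {
      pka_a[i] <- min(max(stats::rnorm(1, 2.3, 0.3), 1.5), 3.5)
      pka_b[i] <- min(max(stats::rnorm(1, 9.6, 0.4), 8.5), 11)
    }
  }
  finalize_library(smiles, cls, pka_a, pka_b, stratum = "noFL",
                   source = "hmdb_gut", prefix = "NF")
}

# --- Traverser grammar -----------------------------------------------------
TRAVERSER_SUBSTITUENTS <- c("C", "CC", "OC", "Cl", "F", "C(=O)NC", "CCN(C)C",
                            "CNC(C)=O", "S(=O)(=O)N", "C(=O)OC", "C#N", "O")
TRAVERSER_TEMPLATES <- list(
  benzene = list(class = "Benzenoids", w = 0.22, ion = "mixed",
                 build = function() sprintf("c1ccc(%s)cc1",
                                            sample(TRAVERSER_SUBSTITUENTS, 1))),
  pyridine = list(class = "Organoheterocyclic compounds", w = 0.16, ion = "neutral",
                  build = function() sprintf("c1ccnc(%s)c1",
                                             sample(TRAVERSER_SUBSTITUENTS, 1))),
  biphenyl = list(class = "Benzenoids", w = 0.10, ion = "neutral",
                  build = function() sprintf("c1ccc(-c2ccc(%s)cc2)cc1",
                                             sample(TRAVERSER_SUBSTITUENTS, 1))),
  indole = list(class = "Organoheterocyclic compounds", w = 0.12, ion = "neutral",
                build = function() sprintf("%sc1cc2ccccc2[nH]1",
                                           sample(c("C", "CC", "OCC", "CCN"), 1))),
  quinoline = list(class = "Organoheterocyclic compounds", w = 0.10, ion = "basic",
                   build = function() sprintf("%sc1ccc2ncccc2c1",
                                              sample(c("C", "OC", "N", "CN"), 1))),
  benzamide = list(class = "Benzenoids", w = 0.10, ion = "neutral",
                   build = function() sample(c("O=C(c1ccccc1)N1CCCCC1",
                                               "O=C(c1ccccc1)N1CCOCC1",
                                               "O=C(Nc1ccccc1)C1CC1"), 1)),
  amine = list(class = "Organic nitrogen compounds", w = 0.10, ion = "basic",
               build = function() sample(c("CN(C)CCc1ccccc1", "NCCc1ccc(O)cc1",
                                           "CN1CCC(c2ccccc2)CC1"), 1)),
  aryl_acid = list(class = "Organic acids and derivatives", w = 0.06, ion = "acid",
                   build = function() sample(c("OC(=O)Cc1ccc(CC(C)C)cc1",
                                               "OC(=O)c1ccccc1OC(C)=O",
                                               "OC(=O)CCc1ccncc1"), 1)),
  nucleoside = list(class = "Nucleosides, nucleotides, and analogues", w = 0.04,
                    ion = "neutral",
                    build = function() "OCC1OC(N2C=CC(=O)NC2=O)CC1O")
)

#' Generate a synthetic drug-like Traverser library
#'
#' Scaffolded aromatic/heterocyclic molecules from a ring-plus-linker
#' grammar: the profile of orally absorbed, systemically acting drugs.
#' Ground-truth permanence is Traverser; pKa sampling is neutral/basic-
#' enriched.
#'
#' @inheritParams generate_fl_library
#' @return compound table with a `stratum` column.
#' @export
generate_traverser_library <- function(n, seed = 1L) {
  if (n == 0L) return(empty_library())
  set.seed(seed)
  w <- vapply(TRAVERSER_TEMPLATES, `[[`, numeric(1), "w")
  fam <- sample(names(TRAVERSER_TEMPLATES), n, replace = TRUE, prob = w)
  smiles <- character(n); cls <- character(n)
  pka_a <- rep(NA_real_, n); pka_b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tpl <- TRAVERSER_TEMPLATES[[fam[i]]]
    smiles[i] <- tpl$build()
    cls[i] <- tpl$class
    ion <- tpl$ion
    if (ion == "mixed") ion <- sample(c("neutral", "basic", "acid"),
                                      1, prob = c(0.6, 0.25, 0.15))
    if (ion == "acid") pka_a[i] <- min(max(stats::rnorm(1, 4.2, 0.5), 3), 6)
    if (ion == "basic") pka_b[i] <- min(max(stats::rnorm(1, 9.0, 0.8), 8), 11)
  }
  finalize_library(smiles, cls, pka_a, pka_b, stratum = "Traverser",
                   source = "drugbank", prefix = "TR")
}

empty_library <- function() {
  out <- data.frame(id = character(0), smiles = character(0),
                    source = character(0), in_gut = logical(0),
                    in_serum = logical(0), pka_strongest_acidic = numeric(0),
                    pka_strongest_basic = numeric(0), chem_class = character(0),
                    quant_status = character(0), stratum = character(0),
                    stringsAsFactors = FALSE)
  out
}

finalize_library <- function(smiles, cls, pka_a, pka_b, stratum, source,
                             prefix) {
  can <- normalize_structures(smiles)
  if (anyNA(can)) stop("internal: generated SMILES failed to normalize")
  n <- length(can)
  data.frame(
    id = sprintf("%s%05d", prefix, seq_len(n)),
    smiles = can,
    source = source,
    in_gut = source != "drugbank",
    in_serum = FALSE,
    pka_strongest_acidic = pka_a,
    pka_strongest_basic = pka_b,
    chem_class = cls,
    quant_status = sample(QUANT_STATUSES, n, replace = TRUE,
                          prob = c(0.4, 0.6)),
    stratum = stratum,
    stringsAsFactors = FALSE
  )
}

#' Benchmark specification
#'
#' @param n_fl,n_nofl,n_traverser stratum sizes.
#' @param chain_length_range acyl chain bounds for the FL stratum.
#' @param separation in [0, 1]: structural separation between the
#'   noFL-Lingerer and Traverser strata. Descriptors are computed from
#'   structures, so the knob controls the fraction of cross-grammar template
#'   draws: 1 keeps the two template pools fully disjoint, 0 mixes them
#'   completely (no structural signal).
#' @param label_noise fraction of permanence labels flipped (in [0, 0.5]).
#' @param seed integer master seed.
#' @return validated spec list of class `gutperm_benchmark_spec`.
#' @export
benchmark_spec <- function(n_fl = 400L, n_nofl = 400L, n_traverser = 400L,
                           chain_length_range = c(10L, 20L),
                           separation = 1, label_noise = 0, seed = 1L) {
  stopifnot(n_fl >= 0, n_nofl >= 0, n_traverser >= 0,
            separation >= 0, label_noise >= 0, label_noise <= 0.5)
  if (sum(c(n_fl, n_nofl, n_traverser) > 0) < 2L) {
    stop("at least two strata must be non-empty")
  }
  structure(list(n_fl = n_fl, n_nofl = n_nofl, n_traverser = n_traverser,
                 chain_length_range = chain_length_range,
                 separation = min(separation, 1), label_noise = label_noise,
                 seed = seed),
            class = "gutperm_benchmark_spec")
}

#' Generate a labeled synthetic benchmark
#'
#' Concatenates the three strata, applies cross-grammar mixing according to
#' the separation knob, flips the requested fraction of permanence labels
#' (recorded in the truth table), and returns the compound table in the
#' schema the reader emits plus the ground-truth table.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `compounds` (compound table), `truth` (id, stratum,
#'   true permanence label, observed label, flipped flag) and the echoed
#'   `spec`.
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "gutperm_benchmark_spec"))
  mix <- (1 - spec$separation) / 2
  # cross-grammar draws: part of the noFL stratum is built from the
  # traverser grammar and vice versa (labels keep the stratum)
  set.seed(spec$seed)
  n_swap_nofl <- stats::rbinom(1, spec$n_nofl, mix)
  n_swap_trav <- stats::rbinom(1, spec$n_traverser, mix)
  fl <- generate_fl_library(spec$n_fl, spec$chain_length_range,
                            seed = spec$seed + 1L)
  nofl <- rbind(
    generate_nofl_library(spec$n_nofl - n_swap_nofl, seed = spec$seed + 2L),
    generate_traverser_library(n_swap_nofl, seed = spec$seed + 3L))
  trav <- rbind(
    generate_traverser_library(spec$n_traverser - n_swap_trav,
                               seed = spec$seed + 4L),
    generate_nofl_library(n_swap_trav, seed = spec$seed + 5L))
  if (nrow(nofl)) nofl$stratum <- "noFL"
  if (nrow(trav)) trav$stratum <- "Traverser"
  all_ <- rbind(fl, nofl, trav)
  all_$id <- sprintf("BM%05d", seq_len(nrow(all_)))
  # traverser-grammar molecules relabelled into the noFL stratum keep
  # metabolite provenance (and vice versa drug provenance)
  all_$source <- ifelse(all_$stratum == "Traverser", "drugbank", "hmdb_gut")
  all_$in_gut <- all_$source != "drugbank"
  all_$in_serum <- FALSE
  true_label <- ifelse(all_$stratum == "Traverser", "Traverser", "Lingerer")
  set.seed(spec$seed + 6L)
  n_flip <- round(spec$label_noise * nrow(all_))
  flip_idx <- if (n_flip > 0) sample.int(nrow(all_), n_flip) else integer(0)
  observed <- true_label
  observed[flip_idx] <- ifelse(true_label[flip_idx] == "Lingerer",
                               "Traverser", "Lingerer")
  truth <- data.frame(id = all_$id, stratum = all_$stratum,
                      label_true = true_label, label_observed = observed,
                      flipped = seq_len(nrow(all_)) %in% flip_idx,
                      stringsAsFactors = FALSE)
  compounds <- all_[, c(COMPOUND_COLUMNS, "stratum")]
  list(compounds = compounds, truth = truth, spec = spec)
}
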