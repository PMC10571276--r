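# The ten physicochemical descriptors, QED, Bemis-Murcko scaffolds and
# per-set scaffold statistics.

DESCRIPTOR_NAMES <- c("tpsa", "logp", "rb", "hbd", "hba", "mw",
                      "nring", "naring", "qed", "fsp3")

# Reduced structural-alert set for the QED unwanted-substructure term:
# classical medicinal-chemistry alerts (reactive/unstable or promiscuous
# motifs). Written for this package; see the methods vignette.
QED_ALERT_SMARTS <- c(
  nitro            = "[N+](=O)[O-]",
  nitro_neutral    = "N(=O)=O",
  aldehyde         = "[CX3H1]=O",
  acyl_halide      = "C(=O)[F,Cl,Br,I]",
  anhydride        = "C(=O)OC(=O)",
  epoxide          = "C1OC1",
  aziridine        = "C1NC1",
  michael_acceptor = "C=CC(=O)[!O;!N]",
  alkyl_halide     = "[CX4][Cl,Br,I]",
  thiol            = "[SX2H]",
  hydrazine        = "[NX3][NX3]",
  azide            = "N=[N+]=[N-]",
  isocyanate       = "N=C=O",
  azo              = "[#6]N=N[#6]",
  quaternary_n     = "[NX4+]",
  peroxide         = "[OX2][OX2]",
  sulfonyl_halide  = "S(=O)(=O)[F,Cl,Br]",
  disulfide        = "[SX2][SX2]",
  long_chain       = "[CH2][CH2][CH2][CH2][CH2][CH2][CH2][CH2]"
)

# Asymmetric-double-sigmoid desirability parameters of the QED publication
# (Bickerton et al. 2012), one row (a, b, c, d, e, f, dmax) per property.
QED_ADS_PARAMS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  d <- (p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
          (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))) / p[7]
  pmin(pmax(d, 1e-12), 1)
}

# Weighted-geometric-mean QED from the eight sub-properties (vectorized).
qed_score <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts) {
  vals <- rbind(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd,
                PSA = psa, ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vals
  for (k in rownames(vals)) d[k, ] <- qed_ads(vals[k, ], QED_ADS_PARAMS[[k]])
  w <- QED_WEIGHTS[rownames(vals)]
  exp(colSums(w * log(d)) / sum(w))
}

# ring-membership flags for bonds: a bond is a ring bond iff both endpoints
# belong to one common inner ring (inner rings are chordless cycles).
ring_bond_flags <- function(g, rings) {
  if (!nrow(g$bonds) || length(rings) == 0L) {
    return(rep(FALSE, nrow(g$bonds)))
  }
  flags <- rep(FALSE, nrow(g$bonds))
  for (r in rings) {
    inr <- g$bonds$a1 %in% r & g$bonds$a2 %in% r
    flags <- flags | inr
  }
  flags
}

# rotatable bonds: non-ring single bonds between two non-terminal heavy
# atoms, amide C-N excluded.
count_rotatable <- function(g, ring_flags) {
  if (!nrow(g$bonds)) return(0L)
  deg <- atom_degree(g)
  # carbons carrying a double bond to oxygen (amide/acid carbonyl carbons)
  carbonyl_c <- rep(FALSE, g$n)
  for (i in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[i] == 2L) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      if (g$elem[a] == "C" && g$elem[b] == "O") carbonyl_c[a] <- TRUE
      if (g$elem[b] == "C" && g$elem[a] == "O") carbonyl_c[b] <- TRUE
    }
  }
  n_rot <- 0L
  for (i in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[i] != 1L || ring_flags[i]) next
    a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
    if (deg[a] < 2L || deg[b] < 2L) next
    amide <- (carbonyl_c[a] && g$elem[b] == "N") ||
             (carbonyl_c[b] && g$elem[a] == "N")
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

descriptor_row_from_graph <- function(g, rings_info, mw, logp, tpsa, alerts) {
  rings <- rings_info$rings
  ring_flags <- ring_bond_flags(g, rings)
  nring <- nrow(g$bonds) - g$n + n_components(g)
  naring <- sum(rings_info$aromatic)
  naring <- min(naring, nring)
  h <- implicit_h(g)
  is_no <- g$elem %in% c("N", "O")
  hba <- sum(is_no)
  hbd <- sum(is_no & h > 0)
  rb <- count_rotatable(g, ring_flags)
  is_c <- g$elem == "C"
  if (any(is_c)) {
    # sp3 carbon: no incident double/triple bond
    unsat <- rep(FALSE, g$n)
    if (nrow(g$bonds)) {
      hi <- g$bonds$order >= 2L
      unsat[g$bonds$a1[hi]] <- TRUE
      unsat[g$bonds$a2[hi]] <- TRUE
    }
    fsp3 <- sum(is_c & !unsat) / sum(is_c)
  } else {
    fsp3 <- 0
  }
  qed <- qed_score(mw, logp, hba, hbd, tpsa, rb, naring, alerts)
  data.frame(tpsa = tpsa, logp = logp, rb = rb, hbd = hbd, hba = hba,
             mw = mw, nring = nring, naring = naring, qed = unname(qed),
             fsp3 = fsp3)
}

#' Compute the ten physicochemical descriptors
#'
#' For each structure: topological polar surface area (`tpsa`, A^2),
#' octanol/water logP (`logp`), rotatable bonds (`rb`), Lipinski-style
#' hydrogen-bond donors and acceptors (`hbd`, `hba`; N/O-based counts),
#' molecular weight (`mw`, Da), ring and aromatic-ring counts (`nring`,
#' `naring`; smallest-set-of-smallest-rings convention), drug-likeness
#' (`qed`, in [0,1]) and fraction of sp3 carbons (`fsp3`). TPSA, logP and MW
#' come from OpenBabel; the remaining counts and QED are computed in-package
#' (see the methods vignette).
#'
#' @param smiles character vector of parseable (preferably normalized)
#'   SMILES. Unparseable input is an error.
#' @return data.frame with one row per structure and columns
#'   `DESCRIPTOR_NAMES`; a structure whose descriptor evaluation fails yields
#'   an all-`NA` row with a warning rather than an error.
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(is.na(can)), 10), collapse = ", "))
  }
  names(can) <- paste0("m", seq_along(can))
  sdf <- ob_sdfset(can)
  ids <- ChemmineR::cid(sdf)
  pr <- ChemmineR::propOB(sdf)
  alerts <- smarts_match_counts(can, QED_ALERT_SMARTS)
  out <- as.data.frame(matrix(NA_real_, nrow = length(can),
                              ncol = length(DESCRIPTOR_NAMES)))
  names(out) <- DESCRIPTOR_NAMES
  for (i in seq_along(can)) {
    j <- match(names(can)[i], ids)
    if (is.na(j)) {
      warning("descriptor computation failed for ", smiles[i])
      next
    }
    row <- tryCatch({
      g <- mol_graph(sdf[[j]])
      ri <- inner_rings(sdf[j], smiles = can[i])
      descriptor_row_from_graph(g, ri, mw = pr$MW[j], logp = pr$logP[j],
                                tpsa = pr$TPSA[j], alerts = alerts[i])
    }, error = function(e) {
      warning("descriptor computation failed for ", smiles[i], ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(row)) out[i, ] <- row
  }
  rownames(out) <- NULL
  out
}

#' Append descriptors to a compound table
#'
#' @param records compound table with normalized `smiles`.
#' @return the table with the ten descriptor columns appended.
#' @export
descriptor_table <- function(records) {
  cbind(records, compute_descriptors(records$smiles))
}

#' Bemis-Murcko scaffold (non-generic)
#'
#' Ring systems plus the linkers connecting them, side chains removed; atom
#' and bond types are retained ("non-generic"), and substituents attached to
#' the framework through a double or triple bond (e.g. exocyclic carbonyl
#' oxygens) are kept, following the usual framework convention.
#'
#' @param smiles character vector of parseable SMILES.
#' @return character vector of canonical scaffold SMILES; `NA` for ringless
#'   molecules.
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(is.na(can)), 10), collapse = ", "))
  }
  names(can) <- paste0("m", seq_along(can))
  sdf <- ob_sdfset(can)
  ids <- ChemmineR::cid(sdf)
  molfiles <- list()
  slot <- integer(0)
  out <- rep(NA_character_, length(can))
  for (i in seq_along(can)) {
    j <- match(names(can)[i], ids)
    if (is.na(j)) next
    g <- mol_graph(sdf[[j]])
    keep <- murcko_core(g)
    if (length(keep) == 0L) next
    molfiles[[length(molfiles) + 1L]] <- subgraph_molfile(g, keep,
                                                          title = names(can)[i])
    slot <- c(slot, i)
  }
  if (length(molfiles)) {
    out[slot] <- molfiles_to_smiles(molfiles)
  }
  out
}

# 2-core of the heavy-atom graph (rings + linkers), plus atoms attached to it
# by a bond of order >= 2. Returns integer atom indices (empty if ringless).
murcko_core <- function(g) {
  if (!nrow(g$bonds)) return(integer(0))
  alive <- rep(TRUE, g$n)
  repeat {
    deg <- integer(g$n)
    act <- g$bonds[alive[g$bonds$a1] & alive[g$bonds$a2], , drop = FALSE]
    if (nrow(act)) {
      deg <- tabulate(act$a1, g$n) + tabulate(act$a2, g$n)
    }
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
    if (!any(alive)) return(integer(0))
  }
  core <- which(alive)
  # re-attach multiply-bonded substituents of the core
  extra <- integer(0)
  hi <- g$bonds[g$bonds$order >= 2L, , drop = FALSE]
  if (nrow(hi)) {
    extra <- c(hi$a2[hi$a1 %in% core & !(hi$a2 %in% core)],
               hi$a1[hi$a2 %in% core & !(hi$a1 %in% core)])
  }
  sort(unique(c(core, extra)))
}

#' Per-set scaffold statistics
#'
#' Summary of the Bemis-Murcko scaffold population of one compound set:
#' molecule and unique-scaffold counts, unique scaffolds per molecule,
#' percentage of molecules carrying a scaffold, and mean/SD (over unique
#' scaffolds) of rings per scaffold and of the fractions of aromatic and of
#' heteroatom-containing rings. A heteroaromatic ring counts toward both
#' fractions.
#'
#' @param records compound table (or any data.frame with a `smiles` column);
#'   alternatively a character vector of SMILES.
#' @return one-row data.frame of class `gutperm_scaffold_stats`.
#' @export
scaffold_set_stats <- function(records) {
  smiles <- if (is.character(records)) records else records$smiles
  if (length(smiles) == 0L) stop("scaffold_set_stats needs at least 1 record")
  sc <- murcko_scaffold(smiles)
  uniq <- unique(sc[!is.na(sc)])
  n_mols <- length(smiles)
  if (length(uniq)) {
    rs <- scaffold_ring_profile(uniq)
    ring_mean <- mean(rs$nring); ring_sd <- stats::sd(rs$nring)
    ar_mean <- mean(rs$frac_aromatic); ar_sd <- stats::sd(rs$frac_aromatic)
    he_mean <- mean(rs$frac_hetero); he_sd <- stats::sd(rs$frac_hetero)
  } else {
    ring_mean <- ring_sd <- ar_mean <- ar_sd <- he_mean <- he_sd <- NA_real_
  }
  out <- data.frame(
    n_mols = n_mols,
    n_unique_scaffolds = length(uniq),
    scaff_per_mol = length(uniq) / n_mols,
    pct_mols_with_scaffold = 100 * mean(!is.na(sc)),
    rings_per_scaffold_mean = ring_mean,
    rings_per_scaffold_sd = ring_sd,
    frac_aromatic_rings_mean = ar_mean,
    frac_aromatic_rings_sd = ar_sd,
    frac_hetero_rings_mean = he_mean,
    frac_hetero_rings_sd = he_sd
  )
  class(out) <- c("gutperm_scaffold_stats", class(out))
  out
}

# ring count, aromatic-ring fraction and hetero-ring fraction for each
# (unique) scaffold SMILES.
scaffold_ring_profile <- function(scaffolds) {
  names(scaffolds) <- paste0("s", seq_along(scaffolds))
  sdf <- ob_sdfset(scaffolds)
  ids <- ChemmineR::cid(sdf)
  nring <- frac_ar <- frac_he <- rep(NA_real_, length(scaffolds))
  for (i in seq_along(scaffolds)) {
    j <- match(names(scaffolds)[i], ids)
    if (is.na(j)) next
    g <- mol_graph(sdf[[j]])
    ri <- inner_rings(sdf[j], smiles = scaffolds[i])
    k <- length(ri$rings)
    nring[i] <- k
    if (k > 0) {
      hetero <- vapply(ri$rings, function(r) any(g$elem[r] != "C"), logical(1))
      frac_ar[i] <- sum(ri$aromatic) / k
      frac_he[i] <- sum(hetero) / k
    } else {
      frac_ar[i] <- 0; frac_he[i] <- 0
    }
  }
  data.frame(scaffold = scaffolds, nring = nring,
             frac_aromatic = frac_ar, frac_hetero = frac_he)
}
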