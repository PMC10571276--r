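# Path-based binary fingerprints and Tanimoto similarity profiles.
#
# The fingerprint enumerates all linear atom/bond paths of 0..max_path bonds
# (a 0-bond path is a lone atom), writes each as an element/bond-label string
# read in its lexicographically smaller direction, and hashes every distinct
# path string to one of nbits positions. Deterministic by construction; not
# claimed to be bit-compatible with any other toolkit's path fingerprint.

FP_NBITS <- 2048L
FP_MAX_PATH <- 7L

# 31-ary rolling string hash onto [0, nbits)
fp_hash <- function(s, nbits) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% nbits)
}

# path strings for one molecular graph; bonds in aromatic rings are labelled
# "a" so that the two kekule forms of a ring hash identically.
fp_path_strings <- function(g, rings_info, max_path) {
  lab <- as.character(g$bonds$order)
  if (length(rings_info$rings) && any(rings_info$aromatic)) {
    arom_atoms <- unique(unlist(rings_info$rings[rings_info$aromatic]))
    in_ring <- ring_bond_flags(g, rings_info$rings[rings_info$aromatic])
    lab[in_ring & g$bonds$a1 %in% arom_atoms & g$bonds$a2 %in% arom_atoms] <- "a"
  }
  nb <- nrow(g$bonds)
  adj <- vector("list", g$n)
  if (nb) {
    for (i in seq_len(nb)) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      adj[[a]] <- rbind(adj[[a]], c(b, i))
      adj[[b]] <- rbind(adj[[b]], c(a, i))
    }
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  add_path <- function(atoms, bonds) {
    fwd <- paste0(g$elem[atoms], collapse = "")
    if (length(bonds)) {
      el <- g$elem[atoms]; bl <- lab[bonds]
      k <- length(el)
      fwd <- paste0(el[-k], bl, collapse = "")
      fwd <- paste0(fwd, el[k])
      rev_ <- paste0(rev(el)[-k], rev(bl), collapse = "")
      rev_ <- paste0(rev_, el[1])
      fwd <- if (fwd <= rev_) fwd else rev_
    }
    assign(fwd, TRUE, envir = seen)
  }
  dfs <- function(atoms, bonds) {
    add_path(atoms, bonds)
    if (length(bonds) >= max_path) return()
    tip <- atoms[length(atoms)]
    nb <- adj[[tip]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (nxt %in% atoms) next
      dfs(c(atoms, nxt), c(bonds, nb[r, 2]))
    }
  }
  for (a in seq_len(g$n)) dfs(a, integer(0))
  ls(seen)
}

#' Path fingerprint of a structure
#'
#' Deterministic 2048-bit binary fingerprint built from all linear paths of
#' up to 7 bonds (see file header for the encoding).
#'
#' @param smiles a single SMILES string.
#' @param nbits fingerprint length.
#' @param max_path maximum path length in bonds.
#' @return integer 0/1 vector of length `nbits`.
#' @export
path_fingerprint <- function(smiles, nbits = FP_NBITS, max_path = FP_MAX_PATH) {
  stopifnot(length(smiles) == 1L)
  fingerprint_matrix(smiles, nbits = nbits, max_path = max_path)[1L, ]
}

#' Fingerprint matrix for a set of structures
#'
#' @param smiles character vector of parseable SMILES.
#' @inheritParams path_fingerprint
#' @return integer matrix, one row per structure, `nbits` columns.
#' @export
fingerprint_matrix <- function(smiles, nbits = FP_NBITS, max_path = FP_MAX_PATH) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(is.na(can)), 10), collapse = ", "))
  }
  names(can) <- paste0("m", seq_along(can))
  sdf <- ob_sdfset(can)
  ids <- ChemmineR::cid(sdf)
  fp <- matrix(0L, nrow = length(can), ncol = nbits)
  for (i in seq_along(can)) {
    j <- match(names(can)[i], ids)
    if (is.na(j)) stop("fingerprint failed for ", smiles[i])
    g <- mol_graph(sdf[[j]])
    ri <- inner_rings(sdf[j], smiles = can[i])
    paths <- fp_path_strings(g, ri, max_path)
    bits <- vapply(paths, fp_hash, integer(1), nbits = nbits)
    fp[i, bits + 1L] <- 1L
  }
  rownames(fp) <- names(smiles)
  fp
}

#' Tanimoto similarity of two binary fingerprints
#'
#' |AND| / |OR|; two all-zero fingerprints have similarity 0 by convention.
#'
#' @param a,b integer/logical 0-1 vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Maximum Tanimoto similarity of each query to a reference set
#'
#' For every query molecule, the maximum Tanimoto similarity of its path
#' fingerprint to any molecule of the reference set.
#'
#' @param query,reference compound tables (data.frames with a `smiles`
#'   column), character vectors of SMILES, or precomputed fingerprint
#'   matrices from [fingerprint_matrix()].
#' @return numeric vector in [0, 1], one value per query molecule.
#' @export
max_tanimoto_profile <- function(query, reference) {
  as_fp <- function(x) {
    if (is.matrix(x)) return(x)
    smiles <- if (is.character(x)) x else x$smiles
    if (length(smiles) == 0L) return(matrix(0L, 0, FP_NBITS))
    fingerprint_matrix(smiles)
  }
  Q <- as_fp(query); R <- as_fp(reference)
  if (nrow(R) == 0L) stop("empty reference set")
  if (nrow(Q) == 0L) return(numeric(0))
  inter <- Q %*% t(R)
  uni <- outer(rowSums(Q), rowSums(R), "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  apply(sim, 1, max)
}
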