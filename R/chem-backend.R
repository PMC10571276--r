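# Internal interface to the OpenBabel backend (ChemmineOB in-process, plus the
# obabel CLI for SMARTS matching). Everything downstream works on canonical
# SMILES strings and on a light molecular-graph representation extracted from
# kekulized V2000 molfiles.

ob_opts <- function(names) {
  if (length(names) == 0L) return(NULL)
  data.frame(names = names, args = rep("", length(names)),
             stringsAsFactors = FALSE)
}

#' Canonicalize SMILES through OpenBabel
#'
#' Vectorized canonicalization; entries that fail to parse come back as `NA`.
#' Used internally for structure validation, normalization and scaffold
#' emission.
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize neutralize charges where chemically possible.
#' @param strip_fragments keep only the largest connected fragment
#'   (salt/solvent stripping).
#' @return character vector aligned with `smiles`; `NA` where parsing failed.
#' @keywords internal
ob_canonical <- function(smiles, neutralize = FALSE, strip_fragments = FALSE) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(paste0(smiles[idx], " x", idx), collapse = "\n")
  opts <- c("e",
            if (strip_fragments) "r",
            if (neutralize) "neutralize")
  res <- ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"),
                                   options = ob_opts(opts))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1))
  keep <- grepl("^x[0-9]+$", ids) & nzchar(can)
  out[as.integer(sub("^x", "", ids[keep]))] <- can[keep]
  out
}

# Convert pre-validated SMILES (named vector; names become compound ids) to a
# ChemmineR SDFset with 2D coordinates and kekulized bond orders.
ob_sdfset <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L, !is.null(names(smiles)))
  src <- paste0(paste0(smiles, " ", names(smiles)), collapse = "\n")
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", paste0(src, "\n"),
                                      options = ob_opts("e"))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdfstr, tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
  ChemmineR::cid(sdf) <- ChemmineR::sdfid(sdf)
  sdf
}

# Light molecular graph for one ChemmineR SDF object: element symbols, bond
# table (kekulized orders), 2D coordinates.
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  if (!is.null(bb) && is.null(dim(bb)) && length(bb) >= 3L) {
    bb <- matrix(bb, nrow = 1L)  # single-bond molecule
  }
  if (is.null(bb) || is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  list(elem = elem, bonds = bonds, n = length(elem),
       xy = ab[, 1:2, drop = FALSE])
}

# Sum of bond orders incident to each atom.
bond_order_sum <- function(g) {
  bs <- numeric(g$n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[i]
      bs[g$bonds$a1[i]] <- bs[g$bonds$a1[i]] + o
      bs[g$bonds$a2[i]] <- bs[g$bonds$a2[i]] + o
    }
  }
  bs
}

# Implicit hydrogen count per atom from standard valences (post-neutralization
# molecules; formal charges are not tracked, see vignette).
implicit_h <- function(g) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1,
               Cl = 1, Br = 1, I = 1, B = 3)
  v <- valence[g$elem]
  v[is.na(v)] <- 0
  pmax(0, v - bond_order_sum(g))
}

# Heavy-atom degree per atom.
atom_degree <- function(g) {
  d <- integer(g$n)
  if (nrow(g$bonds)) {
    t1 <- tabulate(g$bonds$a1, nbins = g$n)
    t2 <- tabulate(g$bonds$a2, nbins = g$n)
    d <- t1 + t2
  }
  d
}

# Number of connected components of the heavy-atom graph (union-find).
n_components <- function(g) {
  if (g$n == 0L) return(0L)
  parent <- seq_len(g$n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      r1 <- find(g$bonds$a1[i]); r2 <- find(g$bonds$a2[i])
      if (r1 != r2) parent[r1] <- r2
    }
  }
  length(unique(vapply(seq_len(g$n), find, integer(1))))
}

# Per-heavy-atom aromaticity flags read from a canonical (OpenBabel) SMILES:
# aromatic atoms are written lowercase. OpenBabel preserves the SMILES atom
# order when emitting the molfile, so the flags align with the SDF atom
# block.
smiles_atom_aromatic <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  arom <- logical(0)
  i <- 1L; n <- length(chars)
  organic_upper <- c("C", "N", "O", "P", "S", "B", "F", "I", "H")
  organic_lower <- c("c", "n", "o", "p", "s", "b")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      inside <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      elem <- sub("^[0-9]*", "", inside)         # strip isotope
      arom <- c(arom, substr(elem, 1, 1) %in% letters)
      i <- j + 1L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      arom <- c(arom, FALSE); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      arom <- c(arom, FALSE); i <- i + 2L
    } else if (ch %in% organic_upper) {
      arom <- c(arom, FALSE); i <- i + 1L
    } else if (ch %in% organic_lower) {
      arom <- c(arom, TRUE); i <- i + 1L
    } else {
      i <- i + 1L                                 # bonds, digits, branches
    }
  }
  arom
}

# Smallest set of smallest rings (as atom-index sets) with aromatic flags.
# Ring perception comes from ChemmineR's inner-ring search; aromaticity of a
# ring is decided from the canonical-SMILES atom flags (all ring atoms
# aromatic), falling back to ChemmineR's ring flags when no SMILES is
# supplied.
inner_rings <- function(sdf, smiles = NULL) {
  g <- mol_graph(sdf[[1]])
  if (nrow(g$bonds) - g$n + n_components(g) <= 0L) {
    return(list(rings = list(), aromatic = logical(0)))  # acyclic
  }
  r <- ChemmineR::rings(sdf, upper = Inf, type = "all", arom = TRUE,
                        inner = TRUE)
  # single-molecule call returns the flat list
  if (!is.null(names(r)) && all(c("RINGS", "AROMATIC") %in% names(r))) {
    rl <- r$RINGS; ar <- r$AROMATIC
  } else {
    rl <- r[[1]]$RINGS; ar <- r[[1]]$AROMATIC
  }
  if (is.null(rl) || length(rl) == 0L) {
    return(list(rings = list(), aromatic = logical(0)))
  }
  rings <- lapply(rl, function(v) as.integer(sub("^.*_", "", v)))
  aromatic <- as.logical(ar)
  if (!is.null(smiles)) {
    flags <- smiles_atom_aromatic(smiles)
    if (length(flags) == g$n) {
      aromatic <- vapply(rings, function(rr) all(flags[rr]), logical(1))
    }
  }
  list(rings = rings, aromatic = aromatic)
}

# Write a V2000 molfile for an induced subgraph of `g` (atom indices `keep`).
subgraph_molfile <- function(g, keep, title = "scaffold") {
  keep <- sort(unique(keep))
  idx <- match(seq_len(g$n), keep)   # old -> new
  b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  na <- length(keep); nb <- nrow(b)
  lines <- c(title, "  gutperm", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (a in keep) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              g$xy[a, 1], g$xy[a, 2], 0, g$elem[a]))
  }
  if (nb) {
    for (i in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                idx[b$a1[i]], idx[b$a2[i]], b$order[i]))
    }
  }
  c(lines, "M  END", "$$$$")
}

# Canonical SMILES for a list of molfile texts (character vectors of lines).
# Returns one SMILES per molfile, NA on failure.
molfiles_to_smiles <- function(molfiles) {
  if (length(molfiles) == 0L) return(character(0))
  src <- paste0(vapply(molfiles, paste, character(1), collapse = "\n"),
                collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(src, "\n"),
                                   options = ob_opts("e"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1L)
  ttl <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1))
  res <- rep(NA_character_, length(molfiles))
  titles <- vapply(molfiles, `[`, character(1), 1L)
  res[match(ttl, titles)] <- smi
  res
}

# Count, per molecule, how many SMARTS patterns match at least once, through
# the obabel CLI (`-s`); used by the QED structural-alert term.
smarts_match_counts <- function(smiles, patterns) {
  n <- length(smiles)
  counts <- integer(n)
  if (n == 0L || length(patterns) == 0L) return(counts)
  tf <- tempfile(fileext = ".smi")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste0(smiles, " x", seq_len(n)), tf)
  for (pat in patterns) {
    res <- suppressWarnings(
      system2("obabel", c(shQuote(tf), "-osmi", "-s", shQuote(pat)),
              stdout = TRUE, stderr = FALSE))
    if (length(res) == 0L) next
    hit <- sub("^.*\tx", "", res)
    hit <- suppressWarnings(as.integer(hit[grepl("^[0-9]+$", hit)]))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
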