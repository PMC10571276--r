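# Data splits: class-stratified fold assignment and structure-disjoint
# Butina sphere-exclusion cluster splits.

#' Stratified fold assignment
#'
#' Assigns each record to one of `k` folds so that, within every stratum
#' (chemical class), fold sizes differ by at most one. Deterministic under a
#' fixed seed.
#'
#' @param strata factor/character vector of stratum labels, one per record.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(strata, k, seed = 1L) {
  n <- length(strata)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of records")
  set.seed(seed)
  folds <- integer(n)
  for (s in unique(as.character(strata))) {
    idx <- which(as.character(strata) == s)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    folds[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  folds
}

#' Butina sphere-exclusion clustering
#'
#' Deterministic sphere-exclusion clustering on fingerprint Tanimoto
#' similarity: molecules are ranked by neighbour count (neighbour =
#' similarity >= `threshold`); the highest-ranked unassigned molecule seeds a
#' cluster containing its unassigned neighbours, repeatedly.
#'
#' @param fps fingerprint matrix from [fingerprint_matrix()].
#' @param threshold Tanimoto similarity threshold in (0, 1) (default 0.8).
#' @return integer vector of cluster ids (1 = first-formed cluster).
#' @export
butina_cluster <- function(fps, threshold = 0.8) {
  stopifnot(is.matrix(fps), threshold > 0, threshold < 1)
  n <- nrow(fps)
  inter <- tcrossprod(fps)
  pc <- rowSums(fps)
  uni <- outer(pc, pc, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  nb <- lapply(seq_len(n), function(i) which(sim[i, ] >= threshold & seq_len(n) != i))
  ord <- order(-lengths(nb), seq_len(n))
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    next_id <- next_id + 1L
    members <- c(i, nb[[i]][is.na(cluster[nb[[i]]])])
    cluster[members] <- next_id
  }
  cluster
}

#' Structure-disjoint train/test split from Butina clusters
#'
#' Whole clusters are assigned to the test side, in seeded random order,
#' until the requested test fraction is reached; no cluster ever spans both
#' sides.
#'
#' @param fps fingerprint matrix.
#' @param threshold Tanimoto threshold for clustering (default 0.8).
#' @param test_fraction target fraction of records in the test side
#'   (default 1/8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`, and the
#'   cluster id vector `clusters`.
#' @export
butina_split <- function(fps, threshold = 0.8, test_fraction = 0.125,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  cl <- butina_cluster(fps, threshold)
  ids <- unique(cl)
  if (length(ids) < 2L) {
    stop("all molecules fall in a single Butina cluster; ",
         "raise the similarity threshold to obtain a splittable clustering")
  }
  set.seed(seed)
  ids <- ids[sample.int(length(ids))]
  target <- test_fraction * length(cl)
  test_ids <- integer(0)
  size <- 0L
  for (id in ids) {
    if (size >= target) break
    if (length(test_ids) + 1L == length(unique(cl))) break  # keep train non-empty
    test_ids <- c(test_ids, id)
    size <- size + sum(cl == id)
  }
  test <- which(cl %in% test_ids)
  list(train = setdiff(seq_along(cl), test), test = test, clusters = cl)
}
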