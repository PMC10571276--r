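# Predictor-matrix construction for the permanence model: 10 descriptors,
# 4 ionization-class dummies and 17 chemical-class dummies ("Other" is the
# dropped reference level), 31 standardized columns in a fixed global order.

feature_column_names <- function() {
  c(DESCRIPTOR_NAMES,
    paste0("ion_", ION_CLASSES),
    paste0("class_", make.names(setdiff(CHEM_CLASSES, "Other"))))
}

#' Build the standardized 31-column feature matrix
#'
#' Records must carry the ten descriptor columns plus `ion_class` and
#' `chem_class`. Standardization (per-column center/scale) is fitted on the
#' training data and reused for new data by passing `training_stats`;
#' zero-variance columns are centered but left unscaled. Chemical-class
#' labels outside the closed vocabulary map to the all-zero reference block
#' with a warning.
#'
#' @param records compound table with descriptors, `ion_class`, `chem_class`.
#' @param training_stats `NULL` to fit standardization on `records`
#'   (training), or the `feature_stats` attribute of a previously built
#'   training matrix (prediction).
#' @return numeric matrix `n x 31` with attribute `feature_stats`
#'   (`list(center, scale)`).
#' @export
build_feature_matrix <- function(records, training_stats = NULL) {
  need <- c(DESCRIPTOR_NAMES, "ion_class", "chem_class")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  X <- as.matrix(records[, DESCRIPTOR_NAMES, drop = FALSE])
  ion <- factor(as.character(records$ion_class), levels = ION_CLASSES)
  if (anyNA(ion)) stop("ion_class outside ", paste(ION_CLASSES, collapse = "/"))
  ion_block <- stats::model.matrix(~ ion - 1)
  colnames(ion_block) <- paste0("ion_", ION_CLASSES)
  cls <- normalize_chem_class(records$chem_class)
  cls_levels <- setdiff(CHEM_CLASSES, "Other")
  cls_block <- matrix(0, n, length(cls_levels),
                      dimnames = list(NULL, paste0("class_", make.names(cls_levels))))
  hit <- match(as.character(cls), cls_levels)
  ok <- !is.na(hit)
  cls_block[cbind(which(ok), hit[ok])] <- 1
  M <- cbind(X, ion_block, cls_block)
  colnames(M) <- feature_column_names()
  if (is.null(training_stats)) {
    center <- colMeans(M)
    scale_ <- apply(M, 2, stats::sd)
    scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
    training_stats <- list(center = center, scale = scale_)
  } else {
    stopifnot(all(names(training_stats$center) == colnames(M)))
  }
  Ms <- sweep(sweep(M, 2, training_stats$center, "-"),
              2, training_stats$scale, "/")
  attr(Ms, "feature_stats") <- training_stats
  Ms
}

#' Invert feature standardization
#'
#' @param X standardized matrix from [build_feature_matrix()].
#' @param stats the `feature_stats` attribute (defaults to the one attached
#'   to `X`).
#' @return the unstandardized design matrix.
#' @export
unstandardize_features <- function(X, stats = attr(X, "feature_stats")) {
  sweep(sweep(X, 2, stats$scale, "*"), 2, stats$center, "+")
}
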