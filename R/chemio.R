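# Reading, normalizing, validating and deduplicating compound tables.
#
# A "compound table" is a plain data.frame with one row per molecule and the
# canonical column set in COMPOUND_COLUMNS. Downstream stages (set assembly,
# ionization, modeling) append derived columns to the same table.

#' Canonical compound-table columns
#'
#' @format character vector of the column names every curated compound table
#'   carries, in fixed order.
#' @export
COMPOUND_COLUMNS <- c("id", "smiles", "source", "in_gut", "in_serum",
                      "pka_strongest_acidic", "pka_strongest_basic",
                      "chem_class", "quant_status")

#' Allowed compound sources
#' @export
COMPOUND_SOURCES <- c("hmdb_gut", "hmdb_serum", "drugbank")

#' Allowed quantification statuses
#'
#' Metabolite records are kept only when their database status is "detected
#' and quantified" or "detected but not quantified"; other statuses
#' (e.g. "expected") are dropped at read time.
#' @export
QUANT_STATUSES <- c("quantified", "detected_not_quantified")

#' Default reader configuration
#'
#' Column-name mapping plus filter settings for [read_compound_table()]. The
#' `columns` element maps canonical names to the names used in the file, so
#' HMDB exports, the deposited curated dataset and synthetic fixtures all load
#' through one reader.
#'
#' @param columns named list: canonical column name -> file column name.
#' @param keep_quant_status quantification statuses to retain; rows with other
#'   statuses are dropped and counted. `NULL` keeps everything.
#' @param keep_stereo retain stereochemistry during normalization.
#' @return a list usable as the `config` argument of the reader.
#' @export
compound_read_config <- function(columns = NULL,
                                 keep_quant_status = QUANT_STATUSES,
                                 keep_stereo = TRUE) {
  base <- stats::setNames(as.list(COMPOUND_COLUMNS), COMPOUND_COLUMNS)
  if (!is.null(columns)) base[names(columns)] <- columns
  list(columns = base, keep_quant_status = keep_quant_status,
       keep_stereo = keep_stereo)
}

#' Read a delimited compound table
#'
#' Reads a CSV/TSV compound table, maps columns through the configuration,
#' applies the quantification-status filter, and validates every structure by
#' parsing it. Rows whose SMILES do not parse are dropped with a warning; the
#' skip log is attached as `attr(x, "skipped")`. Duplicate identifiers are
#' kept at read time and flagged in `attr(x, "dup_ids")` for the dedup stage.
#'
#' @param path file path (`.tsv`/`.tab`/`.txt` are read tab-separated,
#'   anything else comma-separated).
#' @param source one of [COMPOUND_SOURCES]; stamped on every row.
#' @param config see [compound_read_config()].
#' @return data.frame with columns [COMPOUND_COLUMNS], rows in file order.
#' @export
read_compound_table <- function(path, source = c("hmdb_gut", "hmdb_serum", "drugbank"),
                                config = compound_read_config()) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("compound table not found: ", path)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  cm <- config$columns
  if (!(cm$smiles %in% names(raw))) {
    stop("SMILES column '", cm$smiles, "' missing from ", path)
  }
  get_col <- function(canon, default) {
    file_col <- cm[[canon]]
    if (!is.null(file_col) && file_col %in% names(raw)) raw[[file_col]] else default
  }
  n <- nrow(raw)
  tbl <- data.frame(
    id = as.character(get_col("id", sprintf("row%06d", seq_len(n)))),
    smiles = as.character(raw[[cm$smiles]]),
    source = rep(source, n),
    in_gut = as.logical(get_col("in_gut", source == "hmdb_gut")),
    in_serum = as.logical(get_col("in_serum", source == "hmdb_serum")),
    pka_strongest_acidic = as.numeric(get_col("pka_strongest_acidic", NA_real_)),
    pka_strongest_basic = as.numeric(get_col("pka_strongest_basic", NA_real_)),
    chem_class = as.character(get_col("chem_class", NA_character_)),
    quant_status = as.character(get_col("quant_status", "quantified")),
    stringsAsFactors = FALSE
  )
  if (source == "drugbank") {
    tbl$in_gut <- FALSE
    tbl$in_serum <- FALSE
  }
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(config$keep_quant_status)) {
    bad <- !(tbl$quant_status %in% config$keep_quant_status)
    if (any(bad)) {
      skipped <- rbind(skipped, data.frame(id = tbl$id[bad],
                                           reason = "quant_status_filtered",
                                           stringsAsFactors = FALSE))
      tbl <- tbl[!bad, , drop = FALSE]
    }
  }
  can <- ob_canonical(tbl$smiles)
  bad <- is.na(can)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable SMILES skipped: ",
            paste(utils::head(tbl$id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    skipped <- rbind(skipped, data.frame(id = tbl$id[bad],
                                         reason = "unparseable_smiles",
                                         stringsAsFactors = FALSE))
    tbl <- tbl[!bad, , drop = FALSE]
  }
  rownames(tbl) <- NULL
  attr(tbl, "skipped") <- skipped
  dup <- unique(tbl$id[duplicated(tbl$id)])
  attr(tbl, "dup_ids") <- dup
  tbl
}

#' Read a compound table from an SDF file
#'
#' Structures come from the connection tables; the non-structural columns come
#' from the SDF data fields, mapped through the same configuration as the
#' delimited reader.
#'
#' @inheritParams read_compound_table
#' @return data.frame with columns [COMPOUND_COLUMNS].
#' @export
read_compound_sdf <- function(path, source = c("hmdb_gut", "hmdb_serum", "drugbank"),
                              config = compound_read_config()) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  db <- ChemmineR::datablock2ma(ChemmineR::datablock(sdf))
  get_field <- function(canon, default) {
    file_col <- config$columns[[canon]]
    if (!is.null(file_col) && !is.null(dim(db)) && file_col %in% colnames(db)) {
      db[, file_col]
    } else default
  }
  n <- length(smi)
  tbl <- data.frame(
    id = as.character(get_field("id", ChemmineR::sdfid(sdf))),
    smiles = smi,
    source = rep(source, n),
    in_gut = as.logical(get_field("in_gut", source == "hmdb_gut")),
    in_serum = as.logical(get_field("in_serum", source == "hmdb_serum")),
    pka_strongest_acidic = suppressWarnings(as.numeric(get_field("pka_strongest_acidic", NA))),
    pka_strongest_basic = suppressWarnings(as.numeric(get_field("pka_strongest_basic", NA))),
    chem_class = as.character(get_field("chem_class", NA_character_)),
    quant_status = as.character(get_field("quant_status", "quantified")),
    stringsAsFactors = FALSE
  )
  if (source == "drugbank") {
    tbl$in_gut <- FALSE; tbl$in_serum <- FALSE
  }
  rownames(tbl) <- NULL
  tbl
}

#' Normalize structures to canonical parent form
#'
#' The normalization contract: keep the largest connected fragment (salt and
#' solvent stripping), neutralize charges where chemically valid, and emit the
#' canonical SMILES. The operation is idempotent. Stereochemistry is retained
#' by default and can be stripped.
#'
#' @param smiles character vector of SMILES.
#' @param keep_stereo if `FALSE`, stereo descriptors are removed before
#'   canonicalization.
#' @return character vector of canonical parent SMILES; `NA` where the input
#'   did not parse.
#' @export
normalize_structures <- function(smiles, keep_stereo = TRUE) {
  s <- smiles
  if (!keep_stereo) {
    # drop bond-direction and tetrahedral markers, then recanonicalize
    s <- gsub("[/\\\\@]", "", s)
  }
  ob_canonical(s, neutralize = TRUE, strip_fragments = TRUE)
}

#' Normalize a single structure
#'
#' Scalar version of [normalize_structures()]; errors on unparseable input.
#'
#' @inheritParams normalize_structures
#' @return canonical parent SMILES string.
#' @export
normalize_structure <- function(smiles, keep_stereo = TRUE) {
  stopifnot(length(smiles) == 1L)
  out <- normalize_structures(smiles, keep_stereo = keep_stereo)
  if (is.na(out)) stop("invalid structure: ", smiles)
  out
}

#' Deduplicate records across compound sources
#'
#' Structure identity is canonical normalized SMILES equality. Molecules
#' shared between DrugBank and a metabolite source survive as the DrugBank
#' record; duplicates within the metabolite sources collapse to one record
#' whose biospecimen flags are the union of the group's flags. pKa values and
#' chemical class are taken from the first record (in survivor-priority
#' order) that has them.
#'
#' @param records compound table whose `smiles` column is already normalized.
#' @return deduplicated compound table; `attr(x, "dedup")` maps each surviving
#'   id to the ids it absorbed.
#' @export
deduplicate_across_sets <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 0)
  if (nrow(records) == 0L) return(records)
  prio <- match(records$source, c("drugbank", "hmdb_gut", "hmdb_serum"))
  ord <- order(prio, seq_len(nrow(records)))
  groups <- split(ord, records$smiles[ord])
  first_non_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else x[NA_integer_]
  }
  keep_rows <- integer(0)
  merged <- list()
  absorbed <- list()
  for (g in groups) {
    lead <- g[1]
    keep_rows <- c(keep_rows, lead)
    if (length(g) > 1L) {
      sub <- records[g, , drop = FALSE]
      merged[[as.character(lead)]] <- list(
        in_gut = any(sub$in_gut, na.rm = TRUE),
        in_serum = any(sub$in_serum, na.rm = TRUE),
        pka_a = first_non_na(sub$pka_strongest_acidic),
        pka_b = first_non_na(sub$pka_strongest_basic),
        chem_class = first_non_na(sub$chem_class)
      )
      absorbed[[records$id[lead]]] <- records$id[g[-1]]
    }
  }
  keep_rows <- sort(keep_rows)
  out <- records[keep_rows, , drop = FALSE]
  for (key in names(merged)) {
    i <- match(as.integer(key), keep_rows)
    m <- merged[[key]]
    if (out$source[i] != "drugbank") {
      out$in_gut[i] <- m$in_gut
      out$in_serum[i] <- m$in_serum
    }
    if (is.na(out$pka_strongest_acidic[i])) out$pka_strongest_acidic[i] <- m$pka_a
    if (is.na(out$pka_strongest_basic[i])) out$pka_strongest_basic[i] <- m$pka_b
    if (is.na(out$chem_class[i])) out$chem_class[i] <- m$chem_class
  }
  rownames(out) <- NULL
  attr(out, "dedup") <- absorbed
  out
}

#' Write a compound table with fixed column order
#'
#' @param records compound table.
#' @param path output CSV path.
#' @export
write_compound_table <- function(records, path) {
  cols <- c(COMPOUND_COLUMNS, setdiff(names(records), COMPOUND_COLUMNS))
  utils::write.csv(records[, intersect(cols, names(records)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the skip log accumulated by the reader
#'
#' @param records compound table returned by [read_compound_table()].
#' @param path output text path.
#' @export
write_skip_log <- function(records, path) {
  sk <- attr(records, "skipped")
  if (is.null(sk)) sk <- data.frame(id = character(0), reason = character(0))
  writeLines(sprintf("%s\t%s", sk$id, sk$reason), path)
  invisible(path)
}
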