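# Shared fixtures, all generated in code. Expensive objects are built once
# per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small curated-table CSV on disk
write_fixture_table <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

simple_compounds <- function() {
  data.frame(
    id = c("a1", "a2", "a3"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
    chem_class = c("Organic oxygen compounds", "Benzenoids",
                   "Organic acids and derivatives"),
    quant_status = c("quantified", "quantified", "detected_not_quantified"),
    stringsAsFactors = FALSE
  )
}

# descriptor table for a labelled mini-benchmark, computed once
mini_benchmark <- function() {
  memo("mini_benchmark", function() {
    bm <- generate_benchmark(benchmark_spec(n_fl = 60, n_nofl = 60,
                                            n_traverser = 60, seed = 11))
    rec <- descriptor_table(bm$compounds)
    rec <- ionize_table(rec)
    rec <- split_fl(rec)
    rec$permanence_label <- factor(bm$truth$label_observed,
                                   levels = c("Traverser", "Lingerer"))
    list(records = rec, truth = bm$truth)
  })
}

# toy two-feature separable dataset shaped like a 31-column feature matrix
separable_features <- function(n = 200, seed = 1, noise = 0.6) {
  set.seed(seed)
  y <- factor(rep(c("Traverser", "Lingerer"), length.out = n),
              levels = c("Traverser", "Lingerer"))
  mu <- ifelse(y == "Lingerer", 2, -2)
  rec <- data.frame(
    tpsa = rnorm(n, 60, 10), logp = mu + rnorm(n, 0, noise),
    rb = rpois(n, 4), hbd = rpois(n, 1), hba = rpois(n, 3),
    mw = 300 + 50 * mu + rnorm(n, 0, 30), nring = rpois(n, 1),
    naring = 0, qed = runif(n, 0.2, 0.8), fsp3 = runif(n),
    ion_class = sample(c("acid", "neutral"), n, replace = TRUE),
    chem_class = sample(c("Benzenoids", "Other"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(records = rec, y = y)
}
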