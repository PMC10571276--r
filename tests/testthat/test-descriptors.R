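# Physicochemical descriptors, scaffolds, scaffold statistics and
# fingerprints.

triolein <- paste0("CCCCCCCC/C=C\\CCCCCCCC(=O)OCC(OC(=O)CCCCCCC/C=C\\CCCCCCCC)",
                   "COC(=O)CCCCCCC/C=C\\CCCCCCCC")

test_that("descriptor values match known molecules", {
  d <- compute_descriptors(c("CC", "c1ccccc1", triolein))
  # ethane: saturated acyclic hydrocarbon
  expect_equal(d$rb[1], 0)
  expect_equal(d$nring[1], 0)
  expect_equal(d$naring[1], 0)
  expect_equal(d$hbd[1], 0)
  expect_equal(d$hba[1], 0)
  expect_equal(d$fsp3[1], 1.0)
  # benzene: one aromatic ring, no sp3 carbon
  expect_equal(d$nring[2], 1)
  expect_equal(d$naring[2], 1)
  expect_equal(d$fsp3[2], 0.0)
  # triolein: large ringless triester
  expect_equal(d$mw[3], 885.4, tolerance = 0.01)
  expect_gt(d$rb[3], 40)
  expect_equal(d$nring[3], 0)
  expect_equal(d$hbd[3], 0)
  expect_equal(d$hba[3], 6)
  # invariants
  expect_true(all(d$naring <= d$nring))
  expect_true(all(d$qed >= 0 & d$qed <= 1))
  expect_true(all(d$fsp3 >= 0 & d$fsp3 <= 1))
  expect_true(all(is.finite(as.matrix(d))))
  expect_error(compute_descriptors("not_a_smiles"), "unparseable")
})

test_that("descriptor computation is deterministic across runs", {
  smi <- c("CCO", "Cc1ccncc1", "OC(=O)c1ccccc1")
  expect_identical(compute_descriptors(smi), compute_descriptors(smi))
})

test_that("Murcko scaffolds follow the framework convention", {
  sc <- murcko_scaffold(c("CCCCCC", "Cc1ccccc1", "c1ccccc1",
                          "CC(=O)c1ccccc1", "O=C1CCCCC1",
                          "c1ccc(CCc2ccncc2)cc1"))
  expect_true(is.na(sc[1]))                 # ringless
  expect_equal(sc[2], sc[3])                # toluene -> benzene
  expect_equal(sc[3], murcko_scaffold(sc[3]))  # fixed point
  expect_equal(sc[4], sc[3])                # acyl side chain removed
  expect_false(is.na(sc[5]))                # exocyclic C=O retained
  expect_match(sc[5], "=O|O=")
  expect_match(sc[6], "n")                  # linker + both rings retained
})

test_that("scaffold set statistics match hand enumeration", {
  st <- scaffold_set_stats(c("c1ccccc1", "Cc1ccccc1", "CCCCCC"))
  expect_equal(st$n_mols, 3L)
  expect_equal(st$n_unique_scaffolds, 1L)
  expect_equal(st$scaff_per_mol, 1 / 3)
  expect_equal(st$pct_mols_with_scaffold, 100 * 2 / 3)
  expect_equal(st$rings_per_scaffold_mean, 1)
  expect_equal(st$frac_aromatic_rings_mean, 1)
  expect_equal(st$frac_hetero_rings_mean, 0)
  # ringless set
  st0 <- scaffold_set_stats(c("CC", "CCC"))
  expect_equal(st0$n_unique_scaffolds, 0L)
  expect_equal(st0$pct_mols_with_scaffold, 0)
  # duplicated scaffolds counted once; arithmetic invariants hold
  st2 <- scaffold_set_stats(c("c1ccccc1", "c1ccncc1", "Cc1ccncc1"))
  expect_equal(st2$n_unique_scaffolds, 2L)
  expect_equal(st2$scaff_per_mol, st2$n_unique_scaffolds / st2$n_mols)
  expect_equal(st2$frac_hetero_rings_mean, 0.5)  # pyridine yes, benzene no
  expect_error(scaffold_set_stats(character(0)), "at least 1")
})

test_that("path fingerprints are deterministic, 2048 bits, self-similar", {
  fp1 <- path_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  fp2 <- path_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(fp1, fp2)
  expect_length(fp1, 2048L)
  expect_true(all(fp1 %in% c(0L, 1L)))
  expect_gt(sum(fp1), 0)
  expect_equal(tanimoto(fp1, fp1), 1.0)
  # methane: a single-atom path still sets a bit
  expect_gt(sum(path_fingerprint("C")), 0)
  # tanimoto conventions
  expect_equal(tanimoto(integer(8), integer(8)), 0)
  a <- c(1L, 1L, 0L, 0L); b <- c(1L, 0L, 1L, 0L)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
})

test_that("max-Tanimoto profile equals the brute-force double loop", {
  qs <- c("CCO", "CCCO", "c1ccccc1", "Cc1ccccc1", "CC(=O)O")
  rs <- c("CCO", "CCN", "c1ccncc1", "CCCCO", "OC(=O)C")
  Q <- fingerprint_matrix(qs); R <- fingerprint_matrix(rs)
  prof <- max_tanimoto_profile(Q, R)
  brute <- vapply(seq_len(nrow(Q)), function(i) {
    max(vapply(seq_len(nrow(R)), function(j) tanimoto(Q[i, ], R[j, ]),
               numeric(1)))
  }, numeric(1))
  expect_equal(prof, brute)
  # query contained in reference -> exactly 1
  expect_equal(max_tanimoto_profile(Q[1, , drop = FALSE], Q), 1.0)
  # singleton reference equals the pairwise similarity
  expect_equal(max_tanimoto_profile(Q, R[2, , drop = FALSE]),
               vapply(seq_len(nrow(Q)), function(i) tanimoto(Q[i, ], R[2, ]),
                      numeric(1)))
  # growing the reference can only increase the profile
  expect_true(all(max_tanimoto_profile(Q, R[1:2, ]) <=
                  max_tanimoto_profile(Q, R)))
  expect_error(max_tanimoto_profile(Q, character(0)), "empty reference")
})
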