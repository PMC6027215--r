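test_that("sample_tir draws inside the motif with balanced alternatives", {
  withr::with_seed(14, {
    draws <- replicate(10000, sample_tir("[T/C]AGNGNNG", 8))
  })
  first <- substr(draws, 1, 1)
  expect_true(all(first %in% c("T", "C")))
  tf <- mean(first == "T")
  expect_gte(tf, 0.47)
  expect_lte(tf, 0.53)
  expect_true(all(substr(draws, 2, 3) == "AG"))
  # every draw matches its own motif perfectly
  mm <- vapply(draws[1:200], motif_mismatches, integer(1),
               motif = "[T/C]AGNGNNG")
  expect_true(all(mm == 0))
  expect_equal(sample_tir("A", 1), "A")
})

test_that("build_element plants the advertised layout", {
  cfg <- simulation_config(seed = 1)
  withr::with_seed(2, {
    built <- build_element(cfg, with_transposase = TRUE)
  })
  el <- built$element
  tr <- built$truth
  expect_equal(nchar(el$sequence), cfg$element_length)
  # TSD prefix equals TSD suffix, length in [4, 8]
  expect_gte(tr$tsd_length, 4)
  expect_lte(tr$tsd_length, 8)
  expect_equal(substr(el$sequence, 1, tr$tsd_length),
               substr(el$sequence, nchar(el$sequence) - tr$tsd_length + 1,
                      nchar(el$sequence)))
  # 3' TIR is the reverse complement of the 5' TIR at the planted coords
  tir5 <- substr(el$sequence, tr$tir5_start + 1, tr$tir5_end)
  tir3 <- substr(el$sequence, tr$tir3_start + 1, tr$tir3_end)
  expect_equal(revcomp(tir5), tir3)
  expect_equal(motif_mismatches(tir5, cfg$tir_motif), 0L)
  # the planted ORF translates to the reference protein
  orf_nt <- substr(el$sequence, tr$orf_start + 1, tr$orf_end)
  prot <- six_frame_translate(orf_nt)[["+1"]]
  expect_equal(prot, cfg$signature$reference_protein)
})

test_that("knockouts and deletions break the signature as planted", {
  cfg <- simulation_config(seed = 1)
  withr::with_seed(3, {
    ko <- build_element(cfg, with_transposase = TRUE, knockout = TRUE)
    expect_equal(ko$truth$signature_state, "knocked_out")
    expect_equal(call_transposase(ko$element$sequence,
                                  cfg$signature)$check$status, "truncated")

    parent <- build_element(cfg, with_transposase = TRUE,
                            element_id = "P")
    child <- derive_nonautonomous(parent, cfg)
    expect_equal(child$element$element_id, "P-N1")
    expect_equal(child$truth$parent_id, "P")
    expect_equal(child$truth$signature_state, "deleted")
    # TIRs survive the internal deletion
    s <- child$element$sequence
    t2 <- child$truth
    expect_equal(revcomp(substr(s, t2$tir5_start + 1, t2$tir5_end)),
                 substr(s, t2$tir3_start + 1, t2$tir3_end))
    # and the transposase no longer reads as active
    expect_true(call_transposase(s, cfg$signature)$check$status %in%
                  c("truncated", "absent"))
  })
})

test_that("generate_dataset is deterministic and honours its fractions", {
  cfg <- simulation_config(n_species = 4, elements_per_species = 25,
                           transposase_fraction = 0.5,
                           knockout_fraction = 0.2,
                           deletion_fraction = 0.3, seed = 99)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1, ds2)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  generate_dataset(cfg, out_fasta = f1, out_truth = t1)
  generate_dataset(cfg, out_fasta = f2, out_truth = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))

  base <- ds1$truth[is.na(ds1$truth$parent_id), ]
  n_base <- nrow(base)
  expect_equal(n_base, 100L)
  with_tp <- sum(base$signature_state != "none")
  # binomial 99% bounds around the configured fractions
  expect_gte(with_tp, qbinom(0.005, 100, 0.5))
  expect_lte(with_tp, qbinom(0.995, 100, 0.5))
  ko <- sum(base$signature_state == "knocked_out")
  expect_gte(ko, qbinom(0.005, with_tp, 0.2))
  expect_lte(ko, qbinom(0.995, with_tp, 0.2))
  # species codes assigned round-robin over the configured number
  expect_equal(sort(unique(ds1$elements$species_code)),
               sort(c("Os", "Zm", "At", "Ta")))
  # derivative bookkeeping is consistent
  deriv <- ds1$truth[!is.na(ds1$truth$parent_id), ]
  expect_true(all(deriv$parent_id %in% ds1$truth$element_id))
  expect_true(all(deriv$autonomy == "nonautonomous"))
})

test_that("radiation at rate zero copies the root everywhere", {
  withr::with_seed(15, {
    sim <- mutate_and_radiate(random_dna(500), tree_leaves = 6,
                              per_site_mutation_rate = 0)
  })
  expect_true(all(sim$leaves == sim$leaves[[1]]))
  expect_true(all(sim$tree$edge.length == 0))
})

test_that("pairwise divergence matches its closed-form expectation", {
  # two leaves on a cherry: each branch substitutes a site w.p. r, so the
  # expected p-distance is (3/4) (1 - (1 - 4 r / 3)^2)
  r <- 0.05
  n <- 10000
  tree <- ape::read.tree(text = sprintf("(L:%f,R:%f);", r, r))
  withr::with_seed(16, {
    sim <- mutate_and_radiate(random_dna(n), tree = tree)
  })
  p <- p_distance(sim$leaves[["L"]], sim$leaves[["R"]])
  expected <- 0.75 * (1 - (1 - 4 * r / 3)^2)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p - expected), 3 * se)
})

test_that("NJ on JC distances recovers the generating topology", {
  withr::with_seed(17, {
    hits <- vapply(1:10, function(i) {
      tr <- ape::rtree(8)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.1)
      sim <- mutate_and_radiate(random_dna(10000), tree = tr)
      est <- nj_tree(msa_distances(sim$leaves, model = "jc69"))
      ape::dist.topo(ape::unroot(est), ape::unroot(sim$tree)) == 0
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("classification accuracy degrades monotonically with mutation", {
  rates <- c(0, 0.01, 0.05, 0.15)
  set.seed(20)
  seeds <- sample.int(1e6, 20)
  acc <- vapply(rates, function(rate) {
    mean(vapply(seeds, function(sd) {
      cfg <- simulation_config(n_species = 1, elements_per_species = 6,
                               per_site_mutation_rate = rate, seed = sd)
      ds <- generate_dataset(cfg)
      res <- run_hat_pipeline(ds$elements, terminal_window = 16)
      cmp <- merge(res$calls, ds$truth[, c("element_id", "autonomy")],
                   by = "element_id")
      mean(cmp$status == cmp$autonomy)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(acc[1], 1)              # planted truth is exact at rate 0
  expect_true(all(diff(acc) <= 1e-12))     # averaged over 20 replicates
})
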