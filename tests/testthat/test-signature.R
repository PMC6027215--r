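test_that("both shipped presets pass their own signature", {
  for (nb in c("AC", "Hermes")) {
    spec <- hat_signature(nb)
    rc <- check_signature(spec$reference_protein, spec)
    expect_equal(rc$status, "active")
    expect_true(all(rc$sites$pass))
  }
})

test_that("every single-site alanine knockout is truncated", {
  for (nb in c("AC", "Hermes")) {
    spec <- hat_signature(nb)
    for (i in seq_len(nrow(spec$sites))) {
      p <- spec$reference_protein
      substr(p, spec$sites$position[i], spec$sites$position[i]) <- "A"
      rc <- check_signature(p, spec)
      expect_equal(rc$status, "truncated")
      expect_false(rc$sites$pass[i])
      expect_equal(sum(!rc$sites$pass), 1L)
    }
  }
})

test_that("a deletion spanning a signature site reads as a gap and fails", {
  spec <- hat_signature("AC")
  p <- spec$reference_protein
  # remove 50 residues around the third site (R463)
  del <- paste0(substr(p, 1, 440), substr(p, 491, nchar(p)))
  rc <- check_signature(del, spec)
  expect_equal(rc$status, "truncated")
  expect_equal(rc$sites$observed[3], "-")
  expect_false(rc$sites$pass[3])
})

test_that("signature status is monotone under additional knockouts", {
  spec <- hat_signature("AC")
  p <- spec$reference_protein
  seen_active_again <- FALSE
  for (i in seq_len(nrow(spec$sites))) {
    substr(p, spec$sites$position[i], spec$sites$position[i]) <- "A"
    rc <- check_signature(p, spec)
    if (i >= 1 && rc$status == "active") seen_active_again <- TRUE
  }
  expect_false(seen_active_again)
})

test_that("the aromatic site accepts both W and F", {
  spec <- hat_signature("AC")
  p <- spec$reference_protein
  substr(p, 464, 464) <- "F"
  expect_equal(check_signature(p, spec)$status, "active")
})

test_that("a reference failing its own signature is rejected", {
  expect_error(signature_spec("MAAA", positions = 2, allowed = list("D")),
               "fails its own signature")
})

test_that("call_transposase grades planted, deleted and absent ORFs", {
  spec <- hat_signature("AC")
  cfg <- simulation_config(seed = 5, signature = spec)
  withr::with_seed(5, {
    built <- build_element(cfg, with_transposase = TRUE)
    res <- call_transposase(built$element$sequence, spec)
    expect_equal(res$check$status, "active")
    expect_equal(res$orf$nt_start, built$truth$orf_start)
    expect_equal(res$orf$nt_end, built$truth$orf_end)

    # an element without the planted ORF: random kilobase-scale sequence
    # can still host chance stop-free runs above min_aa, so the status is
    # truncated (ORF without the residues) or absent -- never active
    none <- build_element(cfg, with_transposase = FALSE)
    res0 <- call_transposase(none$element$sequence, spec)
    expect_true(res0$check$status %in% c("truncated", "absent"))

    child <- derive_nonautonomous(built, cfg)
    resd <- call_transposase(child$element$sequence, spec)
    expect_true(resd$check$status %in% c("truncated", "absent"))
  })

  # an element far too short to host min_aa residues
  short <- call_transposase(strrep("ACGT", 30), spec, min_aa = 100)
  expect_equal(short$check$status, "absent")
})
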