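test_that("a planted perfect inverted repeat is found at its coordinates", {
  withr::with_seed(1, {
    el <- paste0("TAGGGTTG", random_dna(20), "CAACCCTA")
  })
  tt <- find_tirs(el, min_len = 8, max_len = 8, max_arm_mismatches = 0,
                  max_anchor_mismatches = 0, terminal_window = 1)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$five_prime_start, 0L)
  expect_equal(tt$five_prime_end, 8L)
  expect_equal(tt$three_prime_start, 28L)
  expect_equal(tt$three_prime_end, 36L)
  expect_equal(tt$arm_mismatches, 0L)
  expect_equal(tt$three_prime_arm, "CAACCCTA")
})

test_that("a sequence with no end-anchored complementarity yields nothing", {
  el <- paste0("TAGGG", strrep("A", 60))
  expect_equal(nrow(find_tirs(el, terminal_window = 10)), 0L)
})

test_that("configuration errors are caught", {
  expect_error(find_tirs(strrep("A", 50), min_len = 3), "anchor motif")
  expect_error(find_tirs("ACGTACGT"), "too short")
})

test_that("find_tirs agrees with the brute-force all-pairs oracle", {
  withr::with_seed(202, {
    for (i in 1:25) {
      n <- sample(60:120, 1)
      s <- random_dna(n)
      got <- find_tirs(s, min_len = 8, max_len = 15, max_arm_mismatches = 4,
                       max_anchor_mismatches = 2, terminal_window = 25)
      want <- oracle_find_tirs(s, min_len = 8, max_len = 15,
                               max_arm_mismatches = 4,
                               max_anchor_mismatches = 2,
                               terminal_window = 25)
      expect_equal(tir_key(got), tir_key(want))
    }
  })
})

test_that("reverse-complementing an element mirrors every arm pair", {
  withr::with_seed(303, {
    for (i in 1:10) {
      n <- sample(80:140, 1)
      s <- random_dna(n)
      fwd <- find_tirs(s, max_anchor_mismatches = 5, terminal_window = 20)
      rev <- find_tirs(revcomp(s), max_anchor_mismatches = 5,
                       terminal_window = 20)
      # under a fully permissive anchor the scan is strand-symmetric:
      # [a, b) on the forward strand maps to [n - b, n - a)
      mirrored <- tibble::tibble(
        five_prime_start = n - rev$three_prime_end,
        five_prime_end = n - rev$three_prime_start,
        three_prime_start = n - rev$five_prime_end,
        three_prime_end = n - rev$five_prime_start,
        arm_length = rev$arm_length,
        arm_mismatches = rev$arm_mismatches,
        motif_mismatches = 0L
      )
      fwd$motif_mismatches <- 0L
      expect_equal(tir_key(fwd), tir_key(mirrored))
    }
  })
})

test_that("every reported pair respects the configured budgets", {
  withr::with_seed(404, {
    for (i in 1:10) {
      s <- random_dna(150)
      tt <- find_tirs(s, min_len = 8, max_len = 20, max_arm_mismatches = 3,
                      max_anchor_mismatches = 2, terminal_window = 30)
      if (nrow(tt) == 0) next
      expect_true(all(tt$arm_mismatches <= 3))
      expect_true(all(tt$motif_mismatches <= 2))
      expect_true(all(tt$arm_length >= 8))
      expect_true(all(tt$five_prime_end <= tt$three_prime_start))
      # recompute the Hamming distance from the reported arms
      mm <- mapply(function(a, b) {
        ca <- strsplit(a, "")[[1]]
        cb <- strsplit(revcomp(b), "")[[1]]
        sum(ca != cb | ca == "N" | cb == "N")
      }, tt$five_prime_arm, tt$three_prime_arm)
      expect_equal(unname(mm), tt$arm_mismatches)
    }
  })
})

test_that("best_tir follows the length/mismatch/position sort key", {
  tt <- tibble::tibble(
    element_id = "e",
    five_prime_start = c(5L, 0L, 2L), five_prime_end = c(15L, 8L, 10L),
    three_prime_start = c(80L, 90L, 85L), three_prime_end = c(90L, 98L, 93L),
    arm_length = c(10L, 8L, 8L), arm_mismatches = c(2L, 0L, 2L),
    motif_mismatches = c(0L, 0L, 0L),
    five_prime_arm = c("a", "b", "c"), three_prime_arm = c("x", "y", "z")
  )
  expect_equal(best_tir(tt)$arm_length, 10L)
  expect_equal(best_tir(tt[-1, ])$arm_mismatches, 0L)
  expect_equal(nrow(best_tir(tt[0, ])), 0L)
})

test_that("dedupe_tirs keeps first occurrences only", {
  expect_equal(dedupe_tirs(c("TAGGGTTG", "TAGGGTTG")), "TAGGGTTG")
  expect_equal(dedupe_tirs(c("TAGGGTTG", "TAGGGTTC")),
               c("TAGGGTTG", "TAGGGTTC"))
  expect_equal(dedupe_tirs(character(0)), character(0))
})

test_that("scan_tirs skips too-short elements and labels rows", {
  els <- tibble::tibble(
    element_id = c("big", "tiny"),
    sequence = c(paste0("TAGGGTTG", strrep("G", 24), "CAACCCTA"), "ACGT")
  )
  tt <- scan_tirs(els, min_len = 8, max_len = 8, max_arm_mismatches = 0,
                  terminal_window = 1)
  expect_equal(unique(tt$element_id), "big")
})
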