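test_that("sequence generation is seeded and uniform", {
  a <- generate_sequences(50, seed = 4)
  b <- generate_sequences(50, seed = 4)
  expect_identical(a, b)
  expect_true(all(nchar(a$sequence) == 21L))

  big <- generate_sequences(1000, L = 21, seed = 5)
  toks <- do.call(rbind, strsplit(big$sequence, ""))
  # per-position frequency within 5 binomial standard deviations of 0.2
  bound <- 5 * sqrt(0.2 * 0.8 / 1000)
  for (p in c(1, 11, 21)) {
    freq <- table(factor(toks[, p], levels = c("A", "C", "G", "U", "T"))) / 1000
    expect_true(all(abs(freq - 0.2) < bound), label = paste("position", p))
  }
  expect_error(generate_sequences(5, alphabet = character()),
               class = "sibcut_error_input")
})

test_that("planted potencies follow the stated linear model", {
  tab <- natural_descriptor_table()
  rec <- generate_sequences(60, L = 6L, alphabet = tab$NT, seed = 6)
  beta <- c(nt1_BCUT_SMR_3 = 1, nt3_BCUT_PEOE_0 = -1)
  # noiseless: potency is an exact linear function of the encoding
  done <- generate_potencies(rec, tab, beta, noise_sd = 0, seed = 7)
  enc <- encode_dataset(done, tab)
  fit <- suppressWarnings(fit_pls(enc, n_components = "all"))
  expect_equal(fit$training_stats$r, 1, tolerance = 1e-6)
  # reproducibility and noise injection
  again <- generate_potencies(rec, tab, beta, noise_sd = 0, seed = 7)
  expect_identical(done$potency, again$potency)
  noisy <- generate_potencies(rec, tab, beta, noise_sd = 0.5, seed = 7)
  expect_false(identical(noisy$potency, done$potency))
  expect_error(generate_potencies(rec, tab, c(nt9_BCUT_SMR_3 = 1)),
               class = "sibcut_error_input")
})

test_that("synthetic modified alphabets respect the descriptor invariants", {
  tab <- synth_modified_alphabet(98, seed = 8)
  expect_equal(nrow(tab), 98L)
  expect_false(anyDuplicated(tab$NT) > 0)
  for (prop in c("PEOE", "SLOGP", "SMR")) {
    block <- as.matrix(tab[, paste0("BCUT_", prop, "_", 0:3)])
    expect_true(all(block[, -1] - block[, -4] >= 0))
  }
  expect_identical(synth_modified_alphabet(10, seed = 9),
                   synth_modified_alphabet(10, seed = 9))
  # zero perturbation duplicates natural rows under new tokens
  dup <- synth_modified_alphabet(1, seed = 10, perturb_sd = 0)
  nat <- natural_descriptor_table()
  match_row <- apply(nat[, -1], 1, function(r)
    isTRUE(all.equal(unname(unlist(dup[1, -1])), unname(r))))
  expect_true(any(match_row))
})

test_that("benchmarks are reproducible with known truth attached", {
  b1 <- synthetic_benchmark("small", seed = 3)
  b2 <- synthetic_benchmark("small", seed = 3)
  expect_identical(b1$records, b2$records)
  expect_equal(nrow(b1$records), 48L)
  expect_equal(ncol(b1$encoded) - 2L, 252L)
  expect_named(b1$beta)
  large <- synthetic_benchmark("large", seed = 3, n = 100)
  expect_equal(nrow(large$records), 100L)
})
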