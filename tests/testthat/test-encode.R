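test_that("the packaged natural table loads with its reference values", {
  tab <- natural_descriptor_table()
  expect_equal(tab$BCUT_PEOE_0[tab$NT == "A"], -2.08)
  expect_equal(tab$BCUT_SMR_3[tab$NT == "T"], 2.66)
  expect_equal(dim(tab), c(5L, 13L))
})

test_that("malformed descriptor tables are rejected with locations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- natural_descriptor_table()
  # missing a descriptor column
  readr::write_tsv(tab[, -4], path)
  expect_error(load_descriptor_table(path), class = "sibcut_error_format")
  # non-numeric cell
  bad <- tab; bad$BCUT_PEOE_1 <- as.character(bad$BCUT_PEOE_1)
  bad$BCUT_PEOE_1[3] <- "oops"
  readr::write_tsv(bad, path)
  expect_error(load_descriptor_table(path), "row 3")
  # duplicate symbol
  readr::write_tsv(rbind(tab, tab[1, ]), path)
  expect_error(load_descriptor_table(path), class = "sibcut_error_format")
})

test_that("tokenization handles both sequence dialects", {
  expect_equal(tokenize_sequence("AUGC"), c("A", "U", "G", "C"))
  expect_equal(tokenize_sequence("mA,fU,LG"), c("mA", "fU", "LG"))
  expect_error(tokenize_sequence("A,,C"), class = "sibcut_error_format")
  expect_error(tokenize_sequence("A,C,"), class = "sibcut_error_format")
  expect_error(tokenize_sequence(""), class = "sibcut_error_format")
})

test_that("encoding concatenates per-position descriptor blocks", {
  tab <- natural_descriptor_table()
  rowA <- c(-2.08, -0.62, 0.72, 2.13, -2.32, -0.60, 0.76, 2.19,
            -1.75, -0.40, 0.96, 2.45)
  vA <- encode_sirna("A", tab)
  expect_equal(unname(vA), rowA)
  expect_equal(names(vA), paste0("nt1_", names(tab)[-1]))
  vAC <- encode_sirna(c("A", "C"), tab)
  expect_equal(unname(vAC),
               c(rowA, unlist(tab[tab$NT == "C", -1], use.names = FALSE)))
  v21 <- encode_sirna(strrep("AUGCU", 5) |> substr(1, 21), tab)
  expect_length(v21, 252L)
  expect_error(encode_sirna(c("A", "X"), tab), "position 2",
               class = "sibcut_error_lookup")
})

test_that("encoding is a pure lookup and concatenation homomorphism", {
  tab <- natural_descriptor_table()
  s1 <- c("G", "U", "A"); s2 <- c("C", "T")
  expect_equal(unname(encode_sirna(c(s1, s2), tab)),
               c(unname(encode_sirna(s1, tab)), unname(encode_sirna(s2, tab))))
  expect_identical(encode_sirna("GUAC", tab), encode_sirna("GUAC", tab))
})

test_that("column labels round-trip position and descriptor", {
  tab <- natural_descriptor_table()
  v <- encode_sirna("AUG", tab)
  for (lab in names(v)) {
    parsed <- sibcut:::parse_column_label(lab)
    expect_equal(paste0("nt", parsed$position, "_", parsed$descriptor), lab)
  }
  expect_error(sibcut:::parse_column_label("widget"),
               class = "sibcut_error_format")
})

test_that("dataset encoding preserves order and validates lengths", {
  tab <- natural_descriptor_table()
  rec <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c(strrep("A", 21), strrep("U", 21),
                 paste(rep("G", 21), collapse = "")),
    potency = c(0.1, 0.5, 0.9)
  )
  enc <- encode_dataset(rec, tab)
  expect_equal(dim(enc), c(3L, 254L))
  expect_equal(enc$id, rec$id)
  expect_equal(enc$potency, rec$potency)
  expect_equal(attr(enc, "L"), 21L)

  empty <- encode_dataset(rec[0, ], tab)
  expect_equal(nrow(empty), 0L)

  rec$sequence[2] <- "AU"
  expect_error(encode_dataset(rec, tab), "b",
               class = "sibcut_error_input")
  rec$sequence[2] <- paste(c(rep("U", 20), "zz"), collapse = ",")
  expect_error(encode_dataset(rec, tab), class = "sibcut_error_lookup")
})

test_that("siRNA CSV reading enforces the id/sequence/potency contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = "s1", sequence = "AUGC",
                                  potency = 0.5), path)
  rec <- read_sirna_csv(path)
  expect_equal(rec$sequence, "AUGC")
  readr::write_csv(tibble::tibble(name = "s1", seq = "AUGC"), path)
  expect_error(read_sirna_csv(path), class = "sibcut_error_format")
})
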