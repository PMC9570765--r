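#' Load a nucleotide descriptor table
#'
#' Reads a TSV with header `NT` followed by the 12 BCUT column names and
#' validates it: unique symbols, numeric cells, per-property nondecreasing
#' `_0.._3` ordering is NOT enforced here (tables may be transcribed), but
#' missing columns and malformed cells are errors.
#'
#' @param path Path to the TSV file.
#' @return A descriptor-table tibble.
#' @export
load_descriptor_table <- function(path) {
  tab <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE,
                                          progress = FALSE))
  miss <- setdiff(c("NT", BCUT_NAMES), names(tab))
  if (length(miss)) {
    abort(paste0("descriptor table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "sibcut_error_format")
  }
  tab <- tab[, c("NT", BCUT_NAMES)]
  for (cn in BCUT_NAMES) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        abort(sprintf("non-numeric cell in column %s, row %d",
                      cn, which(is.na(vn))[1]),
              class = "sibcut_error_format")
      }
      tab[[cn]] <- vn
    }
    if (anyNA(tab[[cn]])) {
      abort(sprintf("missing value in column %s, row %d",
                    cn, which(is.na(tab[[cn]]))[1]),
            class = "sibcut_error_format")
    }
  }
  if (anyDuplicated(tab$NT)) {
    abort(sprintf("duplicate symbol %s in descriptor table",
                  tab$NT[duplicated(tab$NT)][1]),
          class = "sibcut_error_format")
  }
  tab
}

#' The packaged descriptor table for natural nucleotides
#'
#' The authoritative reference values for the five natural nucleotides
#' (A, C, G, U, T), shipped with the package.
#'
#' @return A 5-row descriptor-table tibble.
#' @export
natural_descriptor_table <- function() {
  load_descriptor_table(
    system.file("extdata", "bcut_natural_nt.tsv", package = "sibcut",
                mustWork = TRUE)
  )
}

#' Tokenize a sequence string
#'
#' Sequences of natural nucleotides are written one letter per position
#' (`"AUGC"`); alphabets with multi-character tokens (chemically modified
#' nucleotides) use comma separation (`"mA,fU,LG"`).
#'
#' @param raw A non-empty sequence string.
#' @return Character vector of tokens.
#' @export
tokenize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) {
    abort("empty sequence", class = "sibcut_error_format")
  }
  toks <- if (grepl(",", raw, fixed = TRUE)) {
    strsplit(raw, ",", fixed = TRUE)[[1]]
  } else {
    strsplit(raw, "", fixed = TRUE)[[1]]
  }
  if (any(!nzchar(toks)) || grepl(",$", raw)) {
    abort("empty token in sequence", class = "sibcut_error_format")
  }
  toks
}

# labels "nt{p}_{descriptor}" for positions 1..L
encode_column_labels <- function(L) {
  as.vector(vapply(seq_len(L),
                   function(p) paste0("nt", p, "_", BCUT_NAMES),
                   character(12)))
}

# inverse of encode_column_labels for one label
parse_column_label <- function(label) {
  m <- regmatches(label, regexec("^nt([0-9]+)_(BCUT_.+)$", label))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("malformed descriptor column label: %s", label),
          class = "sibcut_error_format")
  }
  list(position = as.integer(m[2]), descriptor = m[3])
}

#' Encode one siRNA sequence as a concatenated descriptor vector
#'
#' Position p of the sequence contributes elements `12(p-1)+1 .. 12p` of the
#' result: that nucleotide's 12 BCUT values in fixed column order. A 21-token
#' sequence therefore encodes to 252 numbers.
#'
#' @param tokens Character vector of nucleotide tokens (or a single string,
#'   which is passed through [tokenize_sequence()]).
#' @param table A descriptor-table tibble.
#' @return Named numeric vector of length `12 * length(tokens)`.
#' @export
encode_sirna <- function(tokens, table) {
  if (length(tokens) == 1L && (nchar(tokens) > 1L || grepl(",", tokens))) {
    tokens <- tokenize_sequence(tokens)
  }
  idx <- match(tokens, table$NT)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    abort(sprintf("unknown nucleotide token '%s' at position %d",
                  tokens[p], p),
          class = "sibcut_error_lookup")
  }
  M <- as.matrix(table[idx, BCUT_NAMES])
  out <- as.vector(t(M))
  names(out) <- encode_column_labels(length(tokens))
  out
}

#' Read a siRNA dataset CSV
#'
#' Expected columns: `id`, `sequence`, `potency` (header required). The
#' potency stays on its native scale; direction (higher-is-better vs
#' lower-is-better) is dataset metadata the caller tracks.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `id` (character), `sequence` (character),
#'   `potency` (numeric).
#' @export
read_sirna_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("id", "sequence", "potency"), names(df))
  if (length(miss)) {
    abort(paste0("siRNA dataset is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "sibcut_error_format")
  }
  tibble(id = as.character(df$id), sequence = as.character(df$sequence),
         potency = as.numeric(df$potency))
}

#' Encode a siRNA dataset
#'
#' Turns a records tibble (`id`, `sequence`, `potency`) into the PLS design:
#' one row per siRNA, 12 x L descriptor columns labeled `nt{p}_{descriptor}`,
#' with `id` and `potency` carried through. All sequences must have the same
#' length.
#'
#' @param records A tibble with columns `id`, `sequence`, `potency`.
#' @param table A descriptor-table tibble.
#' @return A tibble: `id`, `potency`, then the `12 * L` descriptor columns,
#'   with attribute `L` (sequence length).
#' @export
encode_dataset <- function(records, table) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    out <- tibble(id = character(), potency = numeric())
    attr(out, "L") <- 0L
    return(out)
  }
  token_lists <- map(records$sequence, tokenize_sequence)
  Ls <- lengths(token_lists)
  if (length(unique(Ls)) > 1L) {
    off <- records$id[Ls != Ls[1]]
    abort(paste0("sequences of mixed length; offending ids: ",
                 paste(head(off, 5), collapse = ", ")),
          class = "sibcut_error_input")
  }
  L <- Ls[1]
  X <- do.call(rbind, map(token_lists, encode_sirna, table = table))
  out <- bind_cols(
    tibble(id = records$id, potency = records$potency),
    as_tibble(X)
  )
  attr(out, "L") <- as.integer(L)
  out
}

# split an encoded tibble into list(X = matrix, y, ids, L)
encoded_parts <- function(encoded) {
  desc_cols <- setdiff(names(encoded), c("id", "potency"))
  X <- as.matrix(encoded[, desc_cols])
  storage.mode(X) <- "double"
  L <- attr(encoded, "L")
  if (is.null(L)) L <- length(desc_cols) %/% 12L
  list(X = X, y = encoded$potency, ids = encoded$id, L = L,
       labels = desc_cols)
}
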