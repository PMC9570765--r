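#' Burden connectivity matrix
#'
#' Builds the modified adjacency matrix whose eigenvalue summaries are the
#' BCUT descriptors: atomic property values on the diagonal, 0.1 x bond
#' order for bonded pairs (aromatic bonds count 1.5, plus 0.01 when either
#' atom is terminal), and 0.001 for all non-bonded pairs.
#'
#' @param mol A [mol_graph()].
#' @param diag Numeric vector of per-heavy-atom property values (the matrix
#'   diagonal); length must equal the heavy-atom count.
#' @return A symmetric numeric matrix.
#' @export
build_burden_matrix <- function(mol, diag) {
  n <- n_atoms(mol)
  if (length(diag) != n) {
    abort(sprintf("diagonal length %d != heavy-atom count %d", length(diag), n),
          class = "sibcut_error_contract")
  }
  B <- matrix(0.001, n, n)
  deg <- mol_degree(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    o <- if (isTRUE(mol$bonds$aromatic[k])) 1.5 else mol$bonds$order[k]
    v <- 0.1 * o + if (deg[i] == 1L || deg[j] == 1L) 0.01 else 0
    B[i, j] <- v; B[j, i] <- v
  }
  diag(B) <- as.numeric(diag)
  B
}

#' Eigenvalue summaries of a Burden matrix
#'
#' Returns the four BCUT summaries of a symmetric matrix: the smallest and
#' largest eigenvalues plus the lower- and upper-third order statistics of
#' the ascending eigenvalue sequence, with linear interpolation between
#' neighboring eigenvalues at the fractional ranks 1 + (n-1)/3 and
#' 1 + 2(n-1)/3 (equivalently, type-7 quantiles at 0, 1/3, 2/3, 1). A 1x1
#' matrix yields four copies of its single eigenvalue.
#'
#' @param B A symmetric numeric matrix.
#' @return Numeric vector of length 4, nondecreasing.
#' @export
bcut_from_matrix <- function(B) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B) || max(abs(B - t(B))) > 1e-8) {
    abort("Burden matrix must be symmetric", class = "sibcut_error_contract")
  }
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  unname(quantile(sort(ev), probs = c(0, 1 / 3, 2 / 3, 1), type = 7))
}

#' Twelve BCUT descriptors of a molecule
#'
#' Composes the three atomic weighting schemes (PEOE partial charges,
#' Wildman-Crippen logP contributions, Wildman-Crippen molar-refractivity
#' contributions) with the Burden matrix construction and eigenvalue
#' summaries. Field order is fixed: `BCUT_PEOE_0..3`, `BCUT_SLOGP_0..3`,
#' `BCUT_SMR_0..3`.
#'
#' @param mol A [mol_graph()].
#' @return A named numeric vector of length 12.
#' @export
bcut_vector <- function(mol) {
  peoe <- compute_peoe_charges(mol)
  cr <- compute_crippen_contributions(mol)
  out <- c(
    bcut_from_matrix(build_burden_matrix(mol, peoe)),
    bcut_from_matrix(build_burden_matrix(mol, cr$slogp)),
    bcut_from_matrix(build_burden_matrix(mol, cr$smr))
  )
  names(out) <- BCUT_NAMES
  out
}

#' Build a descriptor table for a monomer alphabet
#'
#' @param structures A data frame with columns `symbol` and `mol` (list of
#'   [mol_graph()] objects), e.g. from [read_structures()].
#' @return A descriptor-table tibble: column `NT` plus the 12 BCUT columns.
#' @export
build_descriptor_table <- function(structures) {
  structures <- as_tibble(structures)
  if (nrow(structures) == 0L) {
    return(as_tibble(c(list(NT = character()),
                       setNames(rep(list(numeric()), 12), BCUT_NAMES))))
  }
  if (anyDuplicated(structures$symbol)) {
    abort(sprintf("duplicate symbol: %s",
                  structures$symbol[duplicated(structures$symbol)][1]),
          class = "sibcut_error_input")
  }
  vals <- map(structures$mol, bcut_vector)
  out <- bind_cols(
    tibble(NT = structures$symbol),
    as_tibble(do.call(rbind, vals))
  )
  out
}

#' Write a descriptor table as TSV
#'
#' @param table A descriptor-table tibble (column `NT` + 12 BCUT columns).
#' @param path Output path.
#' @export
write_descriptor_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
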