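#' Molecular graphs
#'
#' A `mol_graph` is the minimal heavy-atom connection table the descriptor
#' engine works on: elements, formal charges, attached-hydrogen counts, and
#' bonds with orders. Hydrogens are never kept as explicit atoms; they are
#' folded into the `h_count` of their heavy neighbor when a structure is read.
#'
#' @param atoms A data frame with columns `element` (character), `charge`
#'   (integer formal charge) and `h_count` (integer attached hydrogens).
#' @param bonds A data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or the string/value for an aromatic bond; aromatic
#'   bonds may be given as `1.5` or marked later by perception).
#' @param perceive_aromaticity If `TRUE` (default) run the built-in ring
#'   perception and flag aromatic atoms/bonds from Kekule input.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, perceive_aromaticity = TRUE) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "charge", "h_count") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1L) abort("a molecule needs at least one heavy atom", class = "sibcut_error_structure")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- tibble(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- as_tibble(bonds)[, c("i", "j", "order")]
  }
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) {
      abort("self-bonds are not allowed", class = "sibcut_error_structure")
    }
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      abort("bond indices out of range", class = "sibcut_error_structure")
    }
  }
  atoms$charge <- as.integer(atoms$charge)
  atoms$h_count <- as.integer(atoms$h_count)
  mol <- structure(
    list(atoms = atoms, bonds = bonds),
    class = "mol_graph"
  )
  if (perceive_aromaticity) mol <- perceive_aromatic(mol)
  if (is.null(mol$atoms$aromatic)) mol$atoms$aromatic <- FALSE
  if (is.null(mol$bonds$aromatic)) mol$bonds$aromatic <- logical(nrow(mol$bonds))
  mol
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %d heavy atoms, %d bonds (%s)\n",
    nrow(x$atoms), nrow(x$bonds),
    paste0(names(sort(table(x$atoms$element), decreasing = TRUE)), collapse = "/")
  ))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list: for each atom, tibble-free list of (nbr, order, aromatic)
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    o <- mol$bonds$order[k]
    ar <- isTRUE(mol$bonds$aromatic[k])
    adj[[i]] <- rbind(adj[[i]], c(j, o, ar))
    adj[[j]] <- rbind(adj[[j]], c(i, o, ar))
  }
  adj
}

mol_degree <- function(mol) {
  n <- n_atoms(mol)
  tabulate(c(mol$bonds$i, mol$bonds$j), nbins = n)
}

# shortest cycle through each bond, by BFS on the graph minus that bond;
# returns a list of integer vectors (unique rings, sizes 3..7)
find_rings <- function(mol, max_size = 7L) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    # BFS from i to j avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue) && is.na(dist[j])) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (v == i && w == j) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j]) || dist[j] + 1L > max_size) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

# Simplified Hueckel perception on Kekule input: a 5-7 ring is aromatic when
# every member is sp2-capable and the pi-electron count is 4n+2. An atom with
# an exocyclic double bond to O contributes 0 electrons, any other double or
# triple bond contributes 1, and a lone-pair N/O/S with only single bonds
# contributes 2.
perceive_aromatic <- function(mol) {
  n <- n_atoms(mol)
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(mol$bonds))
  if (nrow(mol$bonds)) {
    # double/triple partners per atom
    dbl_partner <- vector("list", n)
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] >= 2) {
        i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
        dbl_partner[[i]] <- c(dbl_partner[[i]], j)
        dbl_partner[[j]] <- c(dbl_partner[[j]], i)
      }
    }
    rings <- find_rings(mol)
    for (ring in rings) {
      if (length(ring) < 5L || length(ring) > 7L) next
      pi <- 0L
      ok <- TRUE
      for (a in ring) {
        el <- mol$atoms$element[a]
        partners <- dbl_partner[[a]]
        if (length(partners)) {
          exo <- setdiff(partners, ring)
          if (length(exo) && all(mol$atoms$element[exo] == "O") &&
              !any(partners %in% ring)) {
            pi <- pi + 0L          # exocyclic carbonyl-like
          } else {
            pi <- pi + 1L
          }
        } else if (el %in% c("N", "O", "S")) {
          pi <- pi + 2L           # lone-pair donor
        } else {
          ok <- FALSE
          break
        }
      }
      if (ok && pi %% 4L == 2L) arom_atom[ring] <- TRUE
    }
    # an aromatic bond is a ring bond between two aromatic atoms
    if (any(arom_atom)) {
      ring_atoms_list <- find_rings(mol)
      in_arom_ring <- function(i, j) {
        for (ring in ring_atoms_list) {
          if (i %in% ring && j %in% ring && all(arom_atom[ring])) return(TRUE)
        }
        FALSE
      }
      for (k in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
        if (arom_atom[i] && arom_atom[j] && in_arom_ring(i, j)) arom_bond[k] <- TRUE
      }
    }
  }
  mol$atoms$aromatic <- arom_atom
  mol$bonds$aromatic <- arom_bond
  mol
}

# MDL old-style charge code -> formal charge
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Build a mol_graph from one ChemmineR SDF object (explicit or implicit H)
mol_from_sdf_object <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_[0-9]+$", "", rownames(ab))
  nall <- length(elements)
  charges <- rep(0L, nall)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charges <- unname(.mdl_charge[ifelse(code %in% names(.mdl_charge), code, "0")])
  }
  bonds <- tibble(
    i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
    order = as.numeric(bb[, 3])
  )
  # fold explicit hydrogens into heavy-atom h_count
  heavy <- which(elements != "H")
  if (length(heavy) == 0L) {
    abort("structure has no heavy atoms", class = "sibcut_error_structure")
  }
  hcount <- rep(0L, nall)
  keep_bond <- rep(TRUE, nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    hi <- elements[i] == "H"; hj <- elements[j] == "H"
    if (hi && hj) { keep_bond[k] <- FALSE; next }
    if (hi) { hcount[j] <- hcount[j] + 1L; keep_bond[k] <- FALSE }
    if (hj) { hcount[i] <- hcount[i] + 1L; keep_bond[k] <- FALSE }
  }
  remap <- match(seq_len(nall), heavy)
  bonds <- bonds[keep_bond, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  # aromatic bond type 4 in MOL files
  arom_in <- bonds$order == 4
  bonds$order[arom_in] <- 1.5
  mol <- mol_graph(
    atoms = tibble(
      element = elements[heavy],
      charge = charges[heavy],
      h_count = hcount[heavy]
    ),
    bonds = bonds
  )
  if (any(arom_in)) {
    mol$bonds$aromatic <- mol$bonds$aromatic | arom_in
    mol$atoms$aromatic[unique(c(mol$bonds$i[arom_in], mol$bonds$j[arom_in]))] <- TRUE
  }
  mol
}

#' Parse a SMILES string into a molecular graph
#'
#' Conversion (including explicit hydrogen placement) is delegated to Open
#' Babel via ChemmineOB; the resulting connection table is reduced to heavy
#' atoms with folded hydrogen counts, and aromaticity is re-perceived from
#' the Kekule structure.
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`.
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdfstr <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", smiles,
      options = data.frame(names = "h", args = "")
    )),
    error = function(e) NULL
  )
  if (is.null(sdfstr) || !nzchar(sdfstr) || !grepl("V2000", sdfstr)) {
    abort(paste0("could not parse SMILES: ", smiles),
          class = "sibcut_error_structure")
  }
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(sdfstr, "\n")[[1]]))
  mol_from_sdf_object(sdfset[[1]])
}

#' Read monomer structures from a SMILES table or SDF file
#'
#' SMILES input is a two-column text file, one `symbol<TAB>SMILES` record per
#' line (lines starting with `#` ignored). SDF input must carry the symbol in
#' the molecule title line or an `NT` data field.
#'
#' @param path Path to a `.smi`/`.tsv` SMILES table or an `.sdf` file.
#' @return A tibble with columns `symbol` and `mol` (list column of
#'   `mol_graph` objects).
#' @export
read_structures <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfset <- ChemmineR::read.SDFset(path)
    syms <- map_chr(seq_along(sdfset), function(k) {
      db <- ChemmineR::datablock(sdfset[[k]])
      if (length(db) && "NT" %in% names(db)) return(unname(db[["NT"]]))
      ChemmineR::sdfid(sdfset[k])
    })
    mols <- map(seq_along(sdfset), function(k) mol_from_sdf_object(sdfset[[k]]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(lines, "\t")
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      abort(sprintf("line %d is not 'symbol<TAB>SMILES'", bad[1]),
            class = "sibcut_error_format")
    }
    syms <- map_chr(parts, 1)
    mols <- map(map_chr(parts, 2), mol_from_smiles)
  }
  if (anyDuplicated(syms)) {
    abort(sprintf("duplicate symbol: %s", syms[duplicated(syms)][1]),
          class = "sibcut_error_input")
  }
  tibble(symbol = syms, mol = mols)
}
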